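#' Construct an expression dataset with ordered stage labels
#'
#' The central container of the package: a gene-by-sample matrix of
#' (log-scale) expression values together with an ordered assignment of
#' samples to disease stages, and optionally a table of per-sample numeric
#' clinical traits.
#'
#' @param values Numeric matrix, genes in rows and samples in columns; both
#'   dimensions must carry unique names.
#' @param stage_of Named character vector mapping sample identifiers to stage
#'   labels, or `NULL` for an unstaged dataset (staged operations will then
#'   refuse to run until [set_stages()] is called).
#' @param stage_order Character vector giving the stage labels in progression
#'   order (typically three stages, at least two). Every value of `stage_of`
#'   must be drawn from it.
#' @param traits Optional data frame of numeric traits with one row per
#'   sample (rownames = sample identifiers).
#' @param meta Optional list of free-form metadata (e.g. series-matrix
#'   characteristics lines).
#'
#' @return An object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(values, stage_of = NULL, stage_order = NULL,
                               traits = NULL, meta = list()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in `values`")
  if (!is.null(stage_of)) {
    if (is.null(stage_order))
      stop("`stage_order` is required when stages are given; it is never inferred")
    missing_stage <- setdiff(colnames(values), names(stage_of))
    if (length(missing_stage))
      stop("samples without a stage assignment: ",
           paste(missing_stage, collapse = ", "))
    stage_of <- stage_of[colnames(values)]
    bad <- setdiff(unique(stage_of), stage_order)
    if (length(bad))
      stop("stage labels not in `stage_order`: ", paste(bad, collapse = ", "))
  }
  if (!is.null(traits)) {
    traits <- as.data.frame(traits)
    if (is.null(rownames(traits)) || !all(colnames(values) %in% rownames(traits)))
      stop("`traits` must have one row per sample (rownames = sample ids)")
    traits <- traits[colnames(values), , drop = FALSE]
    if (!all(vapply(traits, is.numeric, logical(1))))
      stop("all trait columns must be numeric")
  }
  structure(list(values = values, stage_of = stage_of,
                 stage_order = stage_order, traits = traits, meta = meta),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  if (!is.null(x$stage_of)) {
    tab <- table(factor(x$stage_of, levels = x$stage_order))
    cat("  stages:", paste(sprintf("%s (n=%d)", names(tab), tab),
                           collapse = " -> "), "\n")
  } else cat("  stages: <unassigned>\n")
  if (!is.null(x$traits))
    cat("  traits:", paste(colnames(x$traits), collapse = ", "), "\n")
  invisible(x)
}

#' Attach stage labels to an unstaged dataset
#'
#' @param d An `ExpressionDataset` (e.g. from [read_series_matrix()]).
#' @inheritParams expression_dataset
#' @return A staged `ExpressionDataset` restricted to samples present in
#'   `stage_of`; samples without an assignment are dropped with a message.
#' @export
set_stages <- function(d, stage_of, stage_order) {
  stopifnot(inherits(d, "ExpressionDataset"))
  keep <- intersect(colnames(d$values), names(stage_of))
  dropped <- setdiff(colnames(d$values), keep)
  if (length(dropped))
    message(length(dropped), " sample(s) without a stage assignment dropped")
  if (!length(keep)) stop("no samples left after stage assignment")
  expression_dataset(d$values[, keep, drop = FALSE], stage_of[keep],
                     stage_order, d$traits, d$meta)
}

#' Samples belonging to one stage
#' @param d An `ExpressionDataset`.
#' @param stage A stage label from `d$stage_order`.
#' @return Character vector of sample identifiers.
#' @export
stage_samples <- function(d, stage) {
  stopifnot(inherits(d, "ExpressionDataset"))
  if (is.null(d$stage_of)) stop("dataset has no stage assignment")
  if (!stage %in% d$stage_order) stop("unknown stage label: ", stage)
  names(d$stage_of)[d$stage_of == stage]
}

#' Read a tab-separated expression matrix
#'
#' First column gene (or probe) identifiers, remaining columns one sample
#' each, numeric body. Stage labels come from `stage_map`, either a named
#' character vector or a path to a two-column TSV (sample, stage) with no
#' header.
#'
#' @param path Path to the TSV file.
#' @param stage_map Named character vector sample -> stage, or path to a
#'   two-column TSV.
#' @param stage_order Stage labels in progression order.
#' @param traits Optional trait table (see [expression_dataset()]).
#' @return An `ExpressionDataset`. Samples missing from `stage_map` are
#'   rejected (dropped with a message).
#' @export
read_expression_tsv <- function(path, stage_map, stage_order, traits = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("expression TSV needs an id column plus >=1 sample")
  ids <- raw[[1]]
  if (anyDuplicated(colnames(raw)[-1]))
    stop("duplicate sample identifier in header of ", path)
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(ids, colnames(body))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at gene '%s', sample '%s' in %s",
                 ids[bad[1]], colnames(num)[bad[2]], path))
  }
  if (is.character(stage_map) && length(stage_map) == 1 && file.exists(stage_map)) {
    sm <- utils::read.delim(stage_map, header = FALSE, sep = "\t",
                            colClasses = "character")
    stage_map <- stats::setNames(sm[[2]], sm[[1]])
  }
  keep <- intersect(colnames(num), names(stage_map))
  dropped <- setdiff(colnames(num), keep)
  if (length(dropped))
    message(length(dropped), " sample(s) without a stage assignment rejected: ",
            paste(dropped, collapse = ", "))
  if (!length(keep)) stop("no samples with a stage assignment in ", path)
  expression_dataset(num[, keep, drop = FALSE], stage_map[keep], stage_order,
                     traits)
}

#' Write an expression dataset to TSV
#'
#' Writes the value matrix as a TSV (first column `gene`) and, when the
#' dataset is staged, a two-column sample/stage sidecar next to it.
#'
#' @param d An `ExpressionDataset`.
#' @param path Output path for the matrix.
#' @param stage_path Optional path for the sample->stage sidecar.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(d, path, stage_path = NULL) {
  stopifnot(inherits(d, "ExpressionDataset"))
  df <- data.frame(gene = rownames(d$values), d$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(stage_path) && !is.null(d$stage_of))
    utils::write.table(data.frame(names(d$stage_of), unname(d$stage_of)),
                       stage_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GEO series-matrix file
#'
#' Parses the series-matrix dialect: metadata lines prefixed with `!`, the
#' numeric table enclosed between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`. Sample metadata lines (`!Sample_title`,
#' `!Sample_characteristics_ch1`, ...) are exposed in `$meta$characteristics`
#' so the caller can build a stage map and then call [set_stages()].
#'
#' @param path Path to an uncompressed series-matrix file.
#' @return An unstaged `ExpressionDataset`.
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1 || length(end) != 1 || end <= beg)
    stop("not a series-matrix file: missing table begin/end markers in ", path)
  dequote <- function(x) gsub('^"|"$', "", x)
  meta_lines <- grep("^!", lines[seq_len(beg - 1)], value = TRUE)
  meta <- lapply(strsplit(meta_lines, "\t"), dequote)
  keys <- sub("^!", "", vapply(meta, `[`, character(1), 1))
  chars <- lapply(meta, function(x) x[-1])
  names(chars) <- keys
  chars <- chars[grepl("^Sample_", keys)]
  tab <- lines[(beg + 1):(end - 1)]
  cells <- strsplit(tab, "\t")
  header <- dequote(cells[[1]])[-1]
  ids <- vapply(cells[-1], function(x) dequote(x[1]), character(1))
  num <- t(vapply(cells[-1],
                  function(x) suppressWarnings(as.numeric(x[-1])),
                  numeric(length(header))))
  dimnames(num) <- list(ids, header)
  expression_dataset(num, meta = list(characteristics = chars))
}
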