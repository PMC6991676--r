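#' Construct a canonical edge table
#'
#' Edges are unordered gene pairs. Canonical form: the lexicographically
#' smaller gene first, no self-loops, duplicates collapsed keeping the
#' maximum confidence and the union of source tags.
#'
#' @param geneA,geneB Character vectors of endpoint genes.
#' @param confidence Optional numeric confidence per edge (`NA` = unscored).
#' @param source Provenance label(s), recycled to the number of edges.
#' @return A data frame of class `EdgeTable` with columns `geneA`, `geneB`,
#'   `confidence`, `source`.
#' @export
edge_table <- function(geneA, geneB, confidence = NA_real_, source = "user") {
  stopifnot(length(geneA) == length(geneB))
  df <- data.frame(geneA = as.character(geneA), geneB = as.character(geneB),
                   confidence = as.numeric(confidence),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  df <- df[df$geneA != df$geneB, , drop = FALSE]
  swap <- df$geneA > df$geneB
  tmp <- df$geneA[swap]; df$geneA[swap] <- df$geneB[swap]; df$geneB[swap] <- tmp
  if (nrow(df)) {
    key <- paste(df$geneA, df$geneB, sep = "\r")
    conf <- tapply(df$confidence, key, function(x)
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
    src <- tapply(df$source, key, function(x)
      paste(sort(unique(x)), collapse = ";"))
    first <- !duplicated(key)
    df <- df[first, , drop = FALSE]
    key <- key[first]
    df$confidence <- as.numeric(conf[key])
    df$source <- as.character(src[key])
    df <- df[order(df$geneA, df$geneB), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("EdgeTable", "data.frame")
  df
}

edge_keys <- function(t) paste(t$geneA, t$geneB, sep = "\r")

#' Read a 2-3 column edge TSV
#'
#' Columns: geneA, geneB, optional numeric confidence. No header. The result
#' is canonicalized and deduplicated (see [edge_table()]).
#'
#' @param path Path to the TSV file.
#' @param source_tag Provenance label attached to every edge.
#' @return An `EdgeTable`.
#' @export
read_edge_table <- function(path, source_tag = basename(path)) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character",
                           blank.lines.skip = TRUE)
  if (ncol(raw) < 2)
    stop("edge table needs >=2 columns (geneA, geneB): ", path)
  conf <- if (ncol(raw) >= 3) suppressWarnings(as.numeric(raw[[3]])) else NA_real_
  edge_table(raw[[1]], raw[[2]], conf, source_tag)
}

#' Filter edges by interaction confidence
#'
#' Keeps edges whose confidence is strictly greater than `min_conf`,
#' mirroring the "score > 0.4" convention for medium-confidence
#' interactions. Edges with no confidence score (e.g. pathway-derived) are
#' kept: the filter only applies to scored sources.
#'
#' @param t An `EdgeTable`.
#' @param min_conf Minimum confidence in \[0, 1\].
#' @return The filtered `EdgeTable`.
#' @export
filter_edges_by_confidence <- function(t, min_conf = 0.4) {
  stopifnot(inherits(t, "EdgeTable"), min_conf >= 0, min_conf <= 1)
  keep <- is.na(t$confidence) | t$confidence > min_conf
  out <- t[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge several background interaction tables
#'
#' Union of canonical edges across sources (e.g. several interaction
#' databases merged into one background PPI); per edge the maximum
#' confidence and the concatenated source tags are retained.
#'
#' @param tables List of `EdgeTable` objects.
#' @return A single merged `EdgeTable`.
#' @export
merge_backgrounds <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  all <- do.call(rbind, lapply(tables, as.data.frame))
  out <- edge_table(all$geneA, all$geneB, all$confidence, all$source)
  if (!nrow(out)) stop("merged background PPI is empty")
  out
}
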