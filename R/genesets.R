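#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (set name -> member genes).
#' @param descriptions Optional named character vector of free-text
#'   descriptions; defaults to empty strings.
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names")
  if (any(!lengths(sets))) stop("empty gene set(s): ",
                                paste(names(sets)[!lengths(sets)], collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, descriptions = descriptions[names(sets)]),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection:", length(x$sets), "sets,",
      length(unique(unlist(x$sets))), "distinct genes\n")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path Path to the GMT file.
#' @return A `GeneSetCollection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t")
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields in ", path)
  names <- vapply(fields, `[`, character(1), 1)
  desc <- stats::setNames(vapply(fields, `[`, character(1), 2), names)
  sets <- stats::setNames(lapply(fields, function(x) x[-(1:2)]), names)
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection to GMT
#' @param x A `GeneSetCollection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "GeneSetCollection"))
  lines <- vapply(names(x$sets), function(nm)
    paste(c(nm, x$descriptions[[nm]], x$sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
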