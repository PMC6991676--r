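#' Export a dynamic network for external viewers
#'
#' Formats: `"sif"` (one `geneA <relation> geneB` line per edge, the
#' import format of common network viewers), `"graphml"` (via igraph, with
#' d-PCC edge attributes where present) and `"tsv"` (the full edge table).
#'
#' @param net A `DynamicNetwork`.
#' @param path Output path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @param relation Relation label used in SIF output.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("sif", "graphml", "tsv"),
                          relation = "dl") {
  stopifnot(inherits(net, "DynamicNetwork"))
  format <- match.arg(format)
  if (format == "sif") {
    writeLines(paste(net$edges$geneA, relation, net$edges$geneB), path)
  } else if (format == "graphml") {
    g <- net$graph
    for (col in setdiff(names(net$edges), c("geneA", "geneB")))
      if (is.numeric(net$edges[[col]]) || is.character(net$edges[[col]]))
        g <- igraph::set_edge_attr(g, col, value = net$edges[[col]])
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write_table(net$edges, path)
  }
  invisible(path)
}

#' Write a result table as TSV
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  utils::write.table(as.data.frame(rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
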