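#' Map dynamic links onto a background PPI network
#'
#' Projects dynamic differentially co-expressed links onto the merged
#' background interaction network. In `"edges"` mode (default) a dynamic DL
#' becomes a network edge only when the same unordered pair is itself a
#' background interaction; in `"nodes"` mode it suffices that both
#' endpoints occur in the background. Isolated nodes never arise (every
#' node comes from a retained edge).
#'
#' @param dls A `DynamicLinkTable` (its dynamic rows are used) or any data
#'   frame with `geneA`/`geneB` columns (all rows used).
#' @param background A merged background `EdgeTable`.
#' @param mode `"edges"` or `"nodes"`.
#' @return An object of class `DynamicNetwork`: list with `graph` (igraph),
#'   `nodes` (gene, degree) and `edges` (geneA, geneB, dpcc1, dpcc2,
#'   background sources where known).
#' @export
map_dls_to_ppi <- function(dls, background, mode = c("edges", "nodes")) {
  mode <- match.arg(mode)
  stopifnot(inherits(background, "EdgeTable"))
  df <- as.data.frame(dls)
  if ("is_dynamic_dl" %in% names(df)) df <- df[df$is_dynamic_dl, , drop = FALSE]
  if (!all(c("geneA", "geneB") %in% names(df)))
    stop("`dls` must have geneA/geneB columns")
  bg_key <- edge_keys(background)
  key <- paste(pmin(df$geneA, df$geneB), pmax(df$geneA, df$geneB), sep = "\r")
  keep <- if (mode == "edges") {
    key %in% bg_key
  } else {
    bg_nodes <- unique(c(background$geneA, background$geneB))
    df$geneA %in% bg_nodes & df$geneB %in% bg_nodes
  }
  edges <- df[keep, , drop = FALSE]
  edges$source <- background$source[match(key[keep], bg_key)]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges[, c("geneA", "geneB")],
                                     directed = FALSE)
  nodes <- data.frame(gene = igraph::V(g)$name,
                      degree = as.integer(igraph::degree(g)),
                      row.names = NULL)
  nodes <- nodes[order(nodes$gene), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(graph = g, nodes = nodes, edges = edges),
            class = "DynamicNetwork")
}

#' @export
print.DynamicNetwork <- function(x, ...) {
  cat("DynamicNetwork:", nrow(x$nodes), "genes,", nrow(x$edges),
      "dynamic links\n")
  invisible(x)
}

#' Shared-neighbour interconnection score for one gene pair
#'
#' Assesses how interconnected two genes are through the background PPI:
#' the number of common background neighbours, and the Jaccard index of
#' their neighbourhoods (both endpoints excluded from the union).
#'
#' @param background A background `EdgeTable`.
#' @param a,b Gene identifiers.
#' @return Named numeric vector `c(count, jaccard)`; both `NA` when either
#'   gene is absent from the background.
#' @export
shared_neighbour_score <- function(background, a, b) {
  stopifnot(inherits(background, "EdgeTable"))
  nb <- neighbour_list(background)
  if (!a %in% names(nb) || !b %in% names(nb))
    return(c(count = NA_real_, jaccard = NA_real_))
  na_ <- setdiff(nb[[a]], c(a, b))
  nb_ <- setdiff(nb[[b]], c(a, b))
  inter <- length(intersect(na_, nb_))
  uni <- length(union(na_, nb_))
  c(count = inter, jaccard = if (uni == 0) 0 else inter / uni)
}

neighbour_list <- function(background) {
  genes <- c(background$geneA, background$geneB)
  partners <- c(background$geneB, background$geneA)
  split(partners, genes)
}

#' Annotate a dynamic network's edges with shared-neighbour scores
#'
#' @param net A `DynamicNetwork`.
#' @param background The background `EdgeTable` used for neighbourhoods.
#' @return The network with `shared_count` and `shared_jaccard` edge
#'   columns.
#' @export
annotate_shared_neighbours <- function(net, background) {
  stopifnot(inherits(net, "DynamicNetwork"))
  nb <- neighbour_list(background)
  score <- function(a, b) {
    if (!a %in% names(nb) || !b %in% names(nb))
      return(c(NA_real_, NA_real_))
    na_ <- setdiff(nb[[a]], c(a, b))
    nb_ <- setdiff(nb[[b]], c(a, b))
    inter <- length(intersect(na_, nb_))
    uni <- length(union(na_, nb_))
    c(inter, if (uni == 0) 0 else inter / uni)
  }
  if (nrow(net$edges)) {
    s <- mapply(score, net$edges$geneA, net$edges$geneB)
    net$edges$shared_count <- as.numeric(s[1, ])
    net$edges$shared_jaccard <- as.numeric(s[2, ])
  } else {
    net$edges$shared_count <- numeric(0)
    net$edges$shared_jaccard <- numeric(0)
  }
  net
}

#' Degree-based hub ranking
#'
#' Nodes sorted by decreasing degree, ties broken lexicographically by gene
#' symbol. The node universe can be restricted (e.g. to strict dynamic DEGs
#' at FDR < 0.01, the convention for reporting hub proteins).
#'
#' @param net A `DynamicNetwork`.
#' @param top_k Number of rows to keep (default all).
#' @param genes Optional character vector restricting the universe.
#' @return Data frame `gene`, `degree`, ordered.
#' @export
hub_ranking <- function(net, top_k = Inf, genes = NULL) {
  stopifnot(inherits(net, "DynamicNetwork"))
  tab <- net$nodes
  if (!is.null(genes)) tab <- tab[tab$gene %in% genes, , drop = FALSE]
  tab <- tab[order(-tab$degree, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  utils::head(tab, top_k)
}

#' Gene overlap between two dynamic networks
#'
#' Intersection of node sets, e.g. to compare the networks built from a
#' discovery and a validation cohort.
#'
#' @param g1,g2 `DynamicNetwork` objects.
#' @return List with `count` and `genes`.
#' @export
network_gene_overlap <- function(g1, g2) {
  stopifnot(inherits(g1, "DynamicNetwork"), inherits(g2, "DynamicNetwork"))
  shared <- sort(intersect(g1$nodes$gene, g2$nodes$gene))
  list(count = length(shared), genes = shared)
}
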