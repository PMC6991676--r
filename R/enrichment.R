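#' Hypergeometric over-representation analysis
#'
#' One-sided (over-representation) exact test of each gene set against a
#' query list within a fixed gene universe:
#' `p = sum_{i >= k} C(K, i) C(N - K, n - i) / C(N, n)` with N the universe
#' size, K the set size within the universe, n the query size and k the
#' number of query genes in the set. P-values are BH-adjusted across all
#' tested sets. Sets with no member in the universe are skipped; query
#' genes outside the universe are dropped with a message.
#'
#' @param query Character vector of genes of interest.
#' @param sets A `GeneSetCollection`.
#' @param universe Character vector of background genes (conventionally all
#'   genes measured after probe collapsing, not the genome).
#' @param alpha Significance threshold echoed in the `significant` column.
#' @return Data frame with columns `set_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`, `significant`, `gene_hits`, ordered by p-value.
#' @export
hypergeom_enrich <- function(query, sets, universe, alpha = 0.05) {
  stopifnot(inherits(sets, "GeneSetCollection"), length(universe) >= 1)
  universe <- unique(as.character(universe))
  query0 <- unique(as.character(query))
  query <- intersect(query0, universe)
  if (length(query) < length(query0))
    message(length(query0) - length(query),
            " query gene(s) outside the universe dropped")
  if (!length(query)) stop("empty query after intersecting with the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    hits <- intersect(query, members)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, p_value = p,
               gene_hits = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene set overlaps the universe")
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$q_value < alpha
  out <- out[order(out$p_value, out$set_name),
             c("set_name", "k", "K", "n", "N", "p_value", "q_value",
               "significant", "gene_hits")]
  rownames(out) <- NULL
  out
}
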