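#' Per-stage Pearson correlation matrix
#'
#' Pearson correlation for every gene pair, computed from the samples of one
#' stage. Genes with zero variance within the stage are degenerate: their
#' rows and columns are `NA` and they are excluded from downstream pair
#' statistics.
#'
#' @param d A staged `ExpressionDataset`.
#' @param stage Stage label; must have >= 3 samples (a correlation from
#'   fewer carries no information for inference).
#' @param gene_subset Optional character vector restricting the pair
#'   universe.
#' @return A list of class `StageCorrelations` with elements `stage`, `pcc`
#'   (symmetric matrix, unit diagonal), `n_samples` and `degenerate_genes`.
#' @export
pcc_matrix <- function(d, stage, gene_subset = NULL) {
  stopifnot(inherits(d, "ExpressionDataset"))
  samples <- stage_samples(d, stage)
  if (length(samples) < 3)
    stop("stage '", stage, "' has fewer than 3 samples")
  x <- d$values[, samples, drop = FALSE]
  if (!is.null(gene_subset)) x <- x[gene_subset, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  degen <- rownames(x)[sds == 0 | is.na(sds)]
  r <- suppressWarnings(stats::cor(t(x)))
  r[degen, ] <- NA_real_
  r[, degen] <- NA_real_
  diag(r)[!rownames(r) %in% degen] <- 1
  structure(list(stage = stage, pcc = r, n_samples = length(samples),
                 degenerate_genes = degen),
            class = "StageCorrelations")
}

#' Difference of stage correlation matrices (d-PCC)
#'
#' Elementwise later minus earlier Pearson correlation; the statistic used
#' to call differentially co-expressed links between two successive disease
#' stages. Undefined wherever either input is undefined.
#'
#' @param c_earlier,c_later `StageCorrelations` over the same gene universe,
#'   in progression order.
#' @return Numeric matrix of d-PCC values in \[-2, 2\].
#' @export
dpcc <- function(c_earlier, c_later) {
  stopifnot(inherits(c_earlier, "StageCorrelations"),
            inherits(c_later, "StageCorrelations"))
  if (!identical(rownames(c_earlier$pcc), rownames(c_later$pcc)))
    stop("correlation matrices cover different gene universes")
  c_later$pcc - c_earlier$pcc
}

#' Select differentially co-expressed links from a d-PCC matrix
#'
#' A gene pair is a DL when |d-PCC| lies in the closed interval
#' \[`low`, `high`\]. Undefined entries are excluded.
#'
#' @param dp d-PCC matrix from [dpcc()].
#' @param low,high Interval bounds (defaults 0.8 and 2, both inclusive).
#' @return Data frame with columns `geneA`, `geneB` (canonical order) and
#'   `dpcc`.
#' @export
select_dls <- function(dp, low = 0.8, high = 2) {
  stopifnot(is.matrix(dp), low < high)
  idx <- which(upper.tri(dp) & !is.na(dp) & abs(dp) >= low & abs(dp) <= high,
               arr.ind = TRUE)
  a <- rownames(dp)[idx[, 1]]
  b <- colnames(dp)[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(geneA = a, geneB = b, dpcc = dp[idx], row.names = NULL)
  out[order(out$geneA, out$geneB), , drop = FALSE]
}

#' Dynamic differentially co-expressed links
#'
#' Pairs that are DLs in both the first and the second stage transition
#' (set intersection on the canonical pair). No sign consistency between
#' the two d-PCCs is required unless `require_sign_flip` is set.
#'
#' @param dl1,dl2 DL tables from [select_dls()] for the two transitions.
#' @param require_sign_flip If `TRUE`, keep only pairs whose two d-PCC
#'   values have opposite signs.
#' @return Data frame `geneA`, `geneB`, `dpcc1`, `dpcc2`.
#' @export
dynamic_dls <- function(dl1, dl2, require_sign_flip = FALSE) {
  k1 <- paste(dl1$geneA, dl1$geneB, sep = "\r")
  k2 <- paste(dl2$geneA, dl2$geneB, sep = "\r")
  common <- intersect(k1, k2)
  out <- data.frame(geneA = dl1$geneA[match(common, k1)],
                    geneB = dl1$geneB[match(common, k1)],
                    dpcc1 = dl1$dpcc[match(common, k1)],
                    dpcc2 = dl2$dpcc[match(common, k2)], row.names = NULL)
  if (require_sign_flip)
    out <- out[sign(out$dpcc1) != sign(out$dpcc2), , drop = FALSE]
  out[order(out$geneA, out$geneB), , drop = FALSE]
}

#' Full dynamic-link table across the three stages
#'
#' Convenience wrapper: per-stage correlations, both d-PCC matrices, DL
#' calls per transition and the dynamic-DL flag. Rows cover every pair that
#' is a DL in at least one transition (the all-pairs table would be O(G^2)
#' and almost entirely non-links).
#'
#' @param d A staged `ExpressionDataset` with >= 3 (typically exactly 3)
#'   ordered stages.
#' @param low,high Closed |d-PCC| selection interval.
#' @param gene_subset Optional pair-universe restriction (e.g. background
#'   PPI nodes).
#' @param require_sign_flip Stricter dynamic-DL rule, see [dynamic_dls()].
#' @return A data frame of class `DynamicLinkTable`: `geneA`, `geneB`,
#'   per-stage PCC columns, `dpcc1`, `dpcc2`, `is_dl1`, `is_dl2`,
#'   `is_dynamic_dl`.
#' @export
dynamic_link_table <- function(d, low = 0.8, high = 2, gene_subset = NULL,
                               require_sign_flip = FALSE) {
  stopifnot(inherits(d, "ExpressionDataset"), length(d$stage_order) >= 3)
  stages <- d$stage_order[1:3]
  if (is.null(gene_subset)) gene_subset <- rownames(d$values)
  cc <- lapply(stages, function(s) pcc_matrix(d, s, gene_subset))
  dp1 <- dpcc(cc[[1]], cc[[2]])
  dp2 <- dpcc(cc[[2]], cc[[3]])
  dl1 <- select_dls(dp1, low, high)
  dl2 <- select_dls(dp2, low, high)
  k1 <- paste(dl1$geneA, dl1$geneB, sep = "\r")
  k2 <- paste(dl2$geneA, dl2$geneB, sep = "\r")
  keys <- union(k1, k2)
  ab <- do.call(rbind, strsplit(keys, "\r"))
  a <- ab[, 1]; b <- ab[, 2]
  ij <- cbind(match(a, rownames(dp1)), match(b, colnames(dp1)))
  out <- data.frame(geneA = a, geneB = b,
                    pcc_stage1 = cc[[1]]$pcc[ij],
                    pcc_stage2 = cc[[2]]$pcc[ij],
                    pcc_stage3 = cc[[3]]$pcc[ij],
                    dpcc1 = dp1[ij], dpcc2 = dp2[ij],
                    is_dl1 = keys %in% k1, is_dl2 = keys %in% k2,
                    row.names = NULL)
  out$is_dynamic_dl <- out$is_dl1 & out$is_dl2
  if (require_sign_flip)
    out$is_dynamic_dl <- out$is_dynamic_dl &
      sign(out$dpcc1) != sign(out$dpcc2)
  out <- out[order(out$geneA, out$geneB), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("DynamicLinkTable", "data.frame")
  out
}
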