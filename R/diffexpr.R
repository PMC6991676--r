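#' Collapse probes to genes by averaging
#'
#' Replaces probe-level rows by one row per gene, the arithmetic mean of
#' that gene's probes per sample. Probes absent from `probe_map` are
#' dropped with a message.
#'
#' @param d An `ExpressionDataset` whose rows are probe identifiers.
#' @param probe_map Named character vector probe -> gene symbol.
#' @return An `ExpressionDataset` with one row per gene.
#' @export
collapse_probes_mean <- function(d, probe_map) {
  stopifnot(inherits(d, "ExpressionDataset"))
  probes <- intersect(rownames(d$values), names(probe_map))
  dropped <- nrow(d$values) - length(probes)
  if (dropped > 0)
    message(dropped, " unmapped probe(s) dropped during collapsing")
  if (!length(probes)) stop("no probes left after applying the probe map")
  gene <- probe_map[probes]
  sub <- d$values[probes, , drop = FALSE]
  collapsed <- rowsum(sub, group = gene, reorder = TRUE) /
    as.vector(table(gene)[sort(unique(gene))])
  expression_dataset(collapsed, d$stage_of, d$stage_order, d$traits, d$meta)
}

#' Z-score normalize each gene across all samples
#'
#' Per gene, across all samples jointly: `(x - mean) / sd` with the n-1
#' denominator. Scaling jointly (not per stage) preserves the between-stage
#' mean differences that the transition t-tests need. Zero-variance genes
#' are set to all-zero and recorded in the `"zero_variance_genes"`
#' attribute.
#'
#' @param d An `ExpressionDataset` with >= 2 samples.
#' @return A normalized `ExpressionDataset`.
#' @export
zscore_normalize <- function(d) {
  stopifnot(inherits(d, "ExpressionDataset"), ncol(d$values) >= 2)
  m <- rowMeans(d$values)
  s <- apply(d$values, 1, stats::sd)
  flat <- s == 0 | is.na(s)
  s[flat] <- 1
  z <- (d$values - m) / s
  z[flat, ] <- 0
  out <- expression_dataset(z, d$stage_of, d$stage_order, d$traits, d$meta)
  attr(out, "zero_variance_genes") <- rownames(d$values)[flat]
  out
}

#' Per-gene two-sample t-test for one stage transition
#'
#' Two-sided Student t-test (pooled variance by default; Welch optionally)
#' comparing the later stage against the earlier stage, gene by gene. The
#' t statistic is signed as later minus earlier. Degenerate genes with zero
#' pooled variance get p = 1 when the group means agree and p = 0 when they
#' differ.
#'
#' @param d A staged `ExpressionDataset`.
#' @param earlier,later Stage labels, in progression order.
#' @param welch Use Welch's unequal-variance statistic instead of the
#'   pooled-variance Student statistic.
#' @return A data frame of class `TransitionStats` with columns `gene`,
#'   `mean_earlier`, `mean_later`, `t_statistic`, `p_value`, `q_value`
#'   (Benjamini-Hochberg), and attribute `transition = c(earlier, later)`.
#' @export
ttest_transition <- function(d, earlier, later, welch = FALSE) {
  stopifnot(inherits(d, "ExpressionDataset"))
  x <- d$values[, stage_samples(d, earlier), drop = FALSE]
  y <- d$values[, stage_samples(d, later), drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2 || n2 < 2) stop("both stages need >= 2 samples")
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    tt <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tt <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(tt))
  }
  p <- 2 * stats::pt(-abs(tt), df)
  degen <- !is.finite(tt)
  tt[degen] <- ifelse(m2[degen] == m1[degen], 0, sign(m2 - m1)[degen] * Inf)
  p[degen] <- ifelse(m2[degen] == m1[degen], 1, 0)
  out <- data.frame(gene = rownames(d$values), mean_earlier = m1,
                    mean_later = m2, t_statistic = tt, p_value = p,
                    q_value = bh_fdr(p), row.names = NULL)
  attr(out, "transition") <- c(earlier, later)
  class(out) <- c("TransitionStats", "data.frame")
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of BH-adjusted q-values, original order preserved.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Dynamic differentially expressed genes
#'
#' A gene is a dynamic DEG when its BH q-value falls below `alpha` in BOTH
#' stage transitions. Per-transition direction codes come from the sign of
#' the mean difference (later minus earlier); no sign consistency between
#' transitions is required.
#'
#' @param s1,s2 `TransitionStats` for the first and second transition, over
#'   the same gene universe.
#' @param alpha FDR threshold.
#' @return A data frame of class `DynamicDegSet` with columns `gene`,
#'   `direction1`, `direction2` (`"up"`/`"down"`); attribute `alpha`.
#' @export
dynamic_degs <- function(s1, s2, alpha = 0.05) {
  stopifnot(inherits(s1, "TransitionStats"), inherits(s2, "TransitionStats"))
  if (!setequal(s1$gene, s2$gene))
    stop("transition statistics cover different gene universes")
  s2 <- s2[match(s1$gene, s2$gene), , drop = FALSE]
  hit <- s1$q_value < alpha & s2$q_value < alpha
  dir_of <- function(s) ifelse(s$mean_later >= s$mean_earlier, "up", "down")
  out <- data.frame(gene = s1$gene[hit],
                    direction1 = dir_of(s1)[hit],
                    direction2 = dir_of(s2)[hit], row.names = NULL)
  attr(out, "alpha") <- alpha
  class(out) <- c("DynamicDegSet", "data.frame")
  out
}
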