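# Weighted co-expression network core: soft-threshold scan, adjacency,
# topological overlap, module detection by tree cut with eigengene merging,
# module-trait statistics, GS/MM and intramodular connectivity.

module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")

#' Unsigned weighted adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta` across all samples; diagonal zeroed (a gene
#' contributes nothing to its own connectivity).
#'
#' @param d An `ExpressionDataset` or a gene-by-sample numeric matrix.
#' @param beta Soft-threshold power.
#' @return Symmetric adjacency matrix with entries in \[0, 1\].
#' @export
adjacency_matrix <- function(d, beta) {
  x <- if (inherits(d, "ExpressionDataset")) d$values else d
  a <- abs(stats::cor(t(x)))^beta
  diag(a) <- 0
  a
}

# Signed scale-free topology fit index: connectivities are split into
# equal-count bins, the empirical density p(k) per bin is regressed on mean
# k on log-log axes, and R^2 is signed by the negated slope so only a
# decreasing degree distribution scores high.
scale_free_fit <- function(k, n_breaks = 10) {
  k <- sort(k[k > 0])
  if (length(k) < 2 * n_breaks) return(NA_real_)
  bin <- ceiling(seq_along(k) / (length(k) / n_breaks))
  mean_k <- tapply(k, bin, mean)
  width <- tapply(k, bin, function(x) diff(range(x)))
  count <- tapply(k, bin, length)
  dens <- (count / length(k)) / width
  ok <- is.finite(dens) & dens > 0 & mean_k > 0
  if (sum(ok) < 3) return(NA_real_)
  fit <- stats::lm(log10(dens[ok]) ~ log10(mean_k[ok]))
  r2 <- summary(fit)$r.squared
  unname(-sign(stats::coef(fit)[2]) * r2)
}

#' Soft-threshold power scan for approximate scale-free topology
#'
#' For each candidate power the unsigned adjacency is formed, per-gene
#' connectivity `k_i = sum_j a_ij` computed, k binned into 10 equal-count
#' bins and the per-bin empirical density `log10 p(k)` regressed on
#' `log10 k`. The signed fit index is the regression R-squared times the
#' negated slope sign, so a high positive value means a decreasing,
#' approximately power-law degree distribution.
#' The chosen power is the lowest one whose fit reaches `target_r2`; if
#' none does, the power with maximal fit is chosen with a warning.
#'
#' @param d An `ExpressionDataset` (>= 20 genes, >= 4 samples).
#' @param powers Candidate powers (default 1..20).
#' @param target_r2 Scale-free fit target (default 0.9).
#' @return A data frame of class `SoftThresholdScan` with columns `power`,
#'   `fit_r2`, `mean_connectivity`; attribute `chosen_beta`.
#' @export
soft_threshold_scan <- function(d, powers = 1:20, target_r2 = 0.9) {
  x <- if (inherits(d, "ExpressionDataset")) d$values else d
  stopifnot(nrow(x) >= 20, ncol(x) >= 4)
  r <- abs(suppressWarnings(stats::cor(t(x))))
  if (all(is.na(r[upper.tri(r)])))
    stop("all genes are constant; correlations undefined")
  diag(r) <- 0
  rows <- lapply(powers, function(b) {
    a <- r^b
    k <- colSums(a)
    data.frame(power = b, fit_r2 = scale_free_fit(k),
               mean_connectivity = mean(k))
  })
  out <- do.call(rbind, rows)
  hit <- which(!is.na(out$fit_r2) & out$fit_r2 >= target_r2)
  if (length(hit)) {
    chosen <- out$power[hit[1]]
  } else {
    chosen <- out$power[which.max(out$fit_r2)]
    warning("no candidate power reached the scale-free fit target ",
            target_r2, "; using the best fit (power ", chosen, ")")
  }
  attr(out, "chosen_beta") <- chosen
  attr(out, "target_r2") <- target_r2
  class(out) <- c("SoftThresholdScan", "data.frame")
  out
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal; similarity of two genes' weighted neighbourhoods. The
#' corresponding dissimilarity is `1 - TOM`.
#'
#' @param adjacency Symmetric matrix with entries in \[0, 1\] (diagonal
#'   ignored).
#' @return TOM similarity matrix, entries in \[0, 1\], diagonal 1.
#' @export
tom_matrix <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (any(a < 0 | a > 1, na.rm = TRUE))
    stop("adjacency entries must lie in [0, 1]")
  if (max(abs(a - t(a))) > 1e-10) stop("adjacency must be symmetric")
  diag(a) <- 0
  k <- colSums(a)
  num <- a %*% a + a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- num / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules from a dissimilarity matrix
#'
#' Average-linkage hierarchical clustering of the dissimilarity (typically
#' `1 - TOM`), static tree cut at `cut_height`, clusters smaller than
#' `min_module_size` set to grey (unassigned). When expression data are
#' supplied, modules whose eigengene dissimilarity `1 - cor(ME_i, ME_j)`
#' falls below `merge_height` are merged iteratively (closest pair first).
#' Colour labels are assigned by decreasing module size following the
#' conventional ordered palette (turquoise, blue, brown, ...), grey last.
#'
#' @param diss Square dissimilarity matrix with gene dimnames.
#' @param min_module_size Minimum genes per module.
#' @param cut_height Static cut height on the dendrogram.
#' @param merge_height Eigengene-dissimilarity threshold below which two
#'   modules are merged; only applied when `exprs` is given.
#' @param exprs Optional `ExpressionDataset` (or matrix) used to compute
#'   eigengenes for the merge step.
#' @return A list of class `ModuleAssignment` with `module_of` (named
#'   character, `"grey"` = unassigned), `tree` (hclust) and `sizes`.
#' @export
detect_modules <- function(diss, min_module_size = 30, cut_height = 0.995,
                           merge_height = 0.25, exprs = NULL) {
  stopifnot(is.matrix(diss), nrow(diss) == ncol(diss))
  genes <- rownames(diss)
  tree <- stats::hclust(stats::as.dist(diss), method = "average")
  labels <- stats::cutree(tree, h = min(cut_height, max(tree$height)))
  sizes <- table(labels)
  labels[labels %in% names(sizes)[sizes < min_module_size]] <- 0L
  if (!is.null(exprs) && length(unique(labels[labels != 0])) > 1) {
    x <- if (inherits(exprs, "ExpressionDataset")) exprs$values else exprs
    repeat {
      ids <- sort(unique(labels[labels != 0]))
      if (length(ids) < 2) break
      me <- vapply(ids, function(i)
        eigengene_vector(x[genes[labels == i], , drop = FALSE]),
        numeric(ncol(x)))
      med <- 1 - stats::cor(me)
      diag(med) <- Inf
      if (min(med) >= merge_height) break
      pair <- which(med == min(med), arr.ind = TRUE)[1, ]
      labels[labels == ids[pair[2]]] <- ids[pair[1]]
    }
  }
  ids <- sort(unique(labels[labels != 0]))
  ord <- ids[order(-as.numeric(table(factor(labels, levels = ids))), ids)]
  colour <- stats::setNames(
    c(module_palette, paste0("module", seq_along(ord)))[seq_along(ord)], ord)
  module_of <- stats::setNames(rep("grey", length(labels)), genes)
  assigned <- labels != 0
  module_of[assigned] <- colour[as.character(labels[assigned])]
  sizes <- vapply(unname(colour), function(cl)
    sum(module_of == cl), integer(1))
  structure(list(module_of = module_of, tree = tree, sizes = sizes),
            class = "ModuleAssignment")
}

#' @export
print.ModuleAssignment <- function(x, ...) {
  cat("ModuleAssignment:", length(x$sizes), "modules,",
      sum(x$module_of == "grey"), "grey genes\n")
  if (length(x$sizes)) print(x$sizes)
  invisible(x)
}

eigengene_vector <- function(x) {
  z <- t(scale(t(x)))
  z[is.na(z)] <- 0
  v <- svd(z, nu = 0, nv = 1)$v[, 1]
  cors <- suppressWarnings(stats::cor(t(z), v))
  if (mean(cors, na.rm = TRUE) < 0) v <- -v
  v
}

#' Module eigengene
#'
#' First principal component (right singular vector) of the
#' gene-standardized module submatrix: the module's representative
#' expression profile over samples. Unit length; sign oriented so the
#' average correlation with member genes is positive.
#'
#' @param d An `ExpressionDataset`.
#' @param member_genes Genes of one module.
#' @return Named numeric vector over samples, unit norm.
#' @export
module_eigengene <- function(d, member_genes) {
  stopifnot(inherits(d, "ExpressionDataset"), length(member_genes) >= 1)
  v <- eigengene_vector(d$values[member_genes, , drop = FALSE])
  stats::setNames(v, colnames(d$values))
}

#' Eigengene matrix for all modules of an assignment
#'
#' @param d An `ExpressionDataset`.
#' @param assignment A `ModuleAssignment`.
#' @return Matrix samples x modules (grey excluded), columns named
#'   `ME<colour>`.
#' @export
module_eigengenes <- function(d, assignment) {
  stopifnot(inherits(assignment, "ModuleAssignment"))
  mods <- names(assignment$sizes)
  me <- vapply(mods, function(m)
    module_eigengene(d, names(assignment$module_of)[assignment$module_of == m]),
    numeric(ncol(d$values)))
  colnames(me) <- paste0("ME", mods)
  rownames(me) <- colnames(d$values)
  me
}

#' Module-trait correlation matrix
#'
#' Pearson correlation of each module eigengene with each numeric trait,
#' pairwise-complete over samples, with two-sided p-values from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on n - 2 degrees of freedom.
#' Zero-variance traits yield `NA`.
#'
#' @param me Eigengene matrix (samples x modules).
#' @param traits Data frame of numeric traits, rownames = samples.
#' @return List with matrices `r`, `p` and `n` (complete pairs per cell).
#' @export
module_trait_correlation <- function(me, traits) {
  traits <- as.matrix(traits[rownames(me), , drop = FALSE])
  r <- suppressWarnings(stats::cor(me, traits, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(me), !is.na(traits))
  if (any(n < 4)) stop("fewer than 4 complete sample pairs for some cell")
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  p[r^2 >= 1] <- 0
  list(r = r, p = p, n = n)
}

#' Gene significance and module membership
#'
#' GS = |cor(gene expression, trait)| per gene and trait; MM = cor(gene
#' expression, module eigengene) per gene and module.
#'
#' @param d An `ExpressionDataset`.
#' @param traits Numeric trait table (rownames = samples).
#' @param assignment A `ModuleAssignment`.
#' @return List with matrices `gs` (genes x traits, absolute values) and
#'   `mm` (genes x modules).
#' @export
gene_significance_and_mm <- function(d, traits, assignment) {
  stopifnot(inherits(d, "ExpressionDataset"))
  tr <- as.matrix(as.data.frame(traits)[colnames(d$values), , drop = FALSE])
  gs <- abs(suppressWarnings(
    stats::cor(t(d$values), tr, use = "pairwise.complete.obs")))
  me <- module_eigengenes(d, assignment)
  mm <- suppressWarnings(stats::cor(t(d$values), me))
  list(gs = gs, mm = mm)
}

#' Intramodular connectivity
#'
#' Per gene, the sum of its adjacency to the other members of its own
#' module; the standard way to rank module hub genes. Grey genes get `NA`.
#'
#' @param adjacency Adjacency matrix (genes x genes).
#' @param assignment A `ModuleAssignment` over the same genes.
#' @return Named numeric vector `k_im` per gene.
#' @export
intramodular_connectivity <- function(adjacency, assignment) {
  stopifnot(inherits(assignment, "ModuleAssignment"))
  genes <- rownames(adjacency)
  mod <- assignment$module_of[genes]
  k <- stats::setNames(rep(NA_real_, length(genes)), genes)
  for (m in setdiff(unique(mod), "grey")) {
    members <- genes[mod == m]
    a <- adjacency[members, members, drop = FALSE]
    diag(a) <- 0
    k[members] <- rowSums(a)
  }
  k
}

#' Top hub genes per module by intramodular connectivity
#'
#' @param adjacency Adjacency matrix.
#' @param assignment A `ModuleAssignment`.
#' @param top_n Rows per module.
#' @return Data frame `module`, `gene`, `k_im`, sorted within module.
#' @export
module_hub_table <- function(adjacency, assignment, top_n = 10) {
  k <- intramodular_connectivity(adjacency, assignment)
  mod <- assignment$module_of[names(k)]
  out <- do.call(rbind, lapply(names(assignment$sizes), function(m) {
    km <- sort(k[mod == m], decreasing = TRUE)
    utils::head(data.frame(module = m, gene = names(km), k_im = unname(km),
                           row.names = NULL), top_n)
  }))
  rownames(out) <- NULL
  out
}
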