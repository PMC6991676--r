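#' Configuration for the three-stage synthetic-data generator
#'
#' Defaults mirror the study design the pipeline targets: three ordered
#' stages with 10 / 18 / 18 samples, 500 genes, 30 dynamic-DE genes shifted
#' by 2 within-gene SD at each transition, 20 gene pairs whose correlation
#' is rewired from 0.8 to -0.6 to 0.6 across stages, four latent-factor
#' modules of 50 genes with residual noise SD 0.5, and one clinical trait
#' tracking the first module's factor with noise SD 0.5.
#'
#' Planted structures occupy disjoint gene pools (modules first, then
#' dynamic-DE genes, then rewired pairs) so each pipeline stage has an
#' unambiguous truth set.
#'
#' @param n_genes Total genes.
#' @param samples_per_stage Integer triple of samples per stage.
#' @param n_dynamic_de Genes with mean shifts in both transitions.
#' @param de_effect Shift per transition, in within-gene SD units.
#' @param n_rewired_pairs Gene pairs with stage-rewired correlation.
#' @param rho_by_stage Planted correlation triple per rewired pair.
#' @param n_modules,module_size,module_factor_sd,noise_sd Latent-factor
#'   module structure.
#' @param trait_module_index Module whose factor the trait tracks (0 = no
#'   trait).
#' @param trait_noise_sd Trait noise SD.
#' @param ppi_coverage Fraction of rewired pairs present in the synthetic
#'   background PPI.
#' @param ppi_n_random_edges Extra random background edges.
#' @param stage_labels Stage labels in progression order.
#' @param seed Integer seed governing all randomness.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 500,
                             samples_per_stage = c(10, 18, 18),
                             n_dynamic_de = 30, de_effect = 2,
                             n_rewired_pairs = 20,
                             rho_by_stage = c(0.8, -0.6, 0.6),
                             n_modules = 4, module_size = 50,
                             module_factor_sd = 1, noise_sd = 0.5,
                             trait_module_index = 1, trait_noise_sd = 0.5,
                             ppi_coverage = 1, ppi_n_random_edges = 200,
                             stage_labels = c("stage1", "stage2", "stage3"),
                             seed = 42L) {
  stopifnot(length(samples_per_stage) == 3, all(samples_per_stage >= 3),
            length(rho_by_stage) == 3, all(abs(rho_by_stage) < 1),
            ppi_coverage >= 0, ppi_coverage <= 1,
            n_dynamic_de >= 0, n_rewired_pairs >= 0, n_modules >= 0)
  reserved <- n_modules * module_size + n_dynamic_de + 2 * n_rewired_pairs
  if (reserved > n_genes)
    stop("gene budget overcommitted: ", reserved, " planted genes > ",
         n_genes, " total")
  structure(list(n_genes = n_genes, samples_per_stage = samples_per_stage,
                 n_dynamic_de = n_dynamic_de, de_effect = de_effect,
                 n_rewired_pairs = n_rewired_pairs,
                 rho_by_stage = rho_by_stage, n_modules = n_modules,
                 module_size = module_size,
                 module_factor_sd = module_factor_sd, noise_sd = noise_sd,
                 trait_module_index = trait_module_index,
                 trait_noise_sd = trait_noise_sd,
                 ppi_coverage = ppi_coverage,
                 ppi_n_random_edges = ppi_n_random_edges,
                 stage_labels = stage_labels, seed = as.integer(seed)),
            class = "generator_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate a three-stage expression dataset with planted truth
#'
#' Baseline expression is i.i.d. standard normal per gene and sample.
#' Planted structures: (a) module genes are `factor + N(0, noise_sd^2)`
#' with one factor per module per sample; (b) dynamic-DE genes receive a
#' signed `de_effect` shift at stage 2 and a further signed shift at stage
#' 3 (signs drawn per gene per transition); (c) each rewired gene pair is
#' redrawn per stage from a bivariate normal with that stage's planted
#' correlation, replacing the baseline values so marginals stay standard
#' normal; (d) the trait equals the designated module's factor plus noise.
#'
#' @param config A `generator_config`.
#' @return List with `dataset` (an `ExpressionDataset`, traits attached
#'   when a trait is planted) and `truth` (a `SyntheticTruth`: planted
#'   dynamic-DE genes with directions, rewired pairs with stage
#'   correlations, module membership, trait record).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    ns <- config$samples_per_stage
    n_total <- sum(ns)
    stage_of <- stats::setNames(rep(config$stage_labels, ns),
                                sprintf("sample%03d", seq_len(n_total)))
    stage_idx <- rep(1:3, ns)
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    x <- matrix(stats::rnorm(config$n_genes * n_total), config$n_genes,
                dimnames = list(genes, names(stage_of)))

    # latent-factor modules
    module_of <- stats::setNames(rep("none", config$n_genes), genes)
    factors <- NULL
    if (config$n_modules > 0) {
      factors <- matrix(stats::rnorm(config$n_modules * n_total,
                                     sd = config$module_factor_sd),
                        config$n_modules, n_total)
      for (m in seq_len(config$n_modules)) {
        idx <- ((m - 1) * config$module_size + 1):(m * config$module_size)
        module_of[idx] <- paste0("M", m)
        x[idx, ] <- matrix(rep(factors[m, ], each = length(idx)),
                           length(idx)) +
          stats::rnorm(length(idx) * n_total, sd = config$noise_sd)
      }
    }
    offset <- config$n_modules * config$module_size

    # dynamic-DE genes: cumulative signed shifts at stages 2 and 3
    de <- NULL
    if (config$n_dynamic_de > 0) {
      de_genes <- genes[offset + seq_len(config$n_dynamic_de)]
      sign1 <- sample(c(-1, 1), config$n_dynamic_de, replace = TRUE)
      sign2 <- sample(c(-1, 1), config$n_dynamic_de, replace = TRUE)
      shift <- cbind(0, sign1 * config$de_effect,
                     (sign1 + sign2) * config$de_effect)
      x[de_genes, ] <- x[de_genes, ] + shift[, stage_idx]
      de <- data.frame(gene = de_genes,
                       direction1 = ifelse(sign1 > 0, "up", "down"),
                       direction2 = ifelse(sign2 > 0, "up", "down"),
                       row.names = NULL)
    }
    offset <- offset + config$n_dynamic_de

    # rewired pairs: per-stage bivariate normal with planted rho
    pairs <- NULL
    if (config$n_rewired_pairs > 0) {
      a <- genes[offset + 2 * seq_len(config$n_rewired_pairs) - 1]
      b <- genes[offset + 2 * seq_len(config$n_rewired_pairs)]
      for (i in seq_len(config$n_rewired_pairs)) {
        for (s in 1:3) {
          cols <- which(stage_idx == s)
          rho <- config$rho_by_stage[s]
          z1 <- stats::rnorm(length(cols))
          z2 <- stats::rnorm(length(cols))
          x[a[i], cols] <- z1
          x[b[i], cols] <- rho * z1 + sqrt(1 - rho^2) * z2
        }
      }
      pairs <- data.frame(geneA = pmin(a, b), geneB = pmax(a, b),
                          rho_stage1 = config$rho_by_stage[1],
                          rho_stage2 = config$rho_by_stage[2],
                          rho_stage3 = config$rho_by_stage[3],
                          row.names = NULL)
    }

    traits <- NULL
    trait_record <- NULL
    if (config$trait_module_index > 0 && config$n_modules > 0) {
      tv <- factors[config$trait_module_index, ] +
        stats::rnorm(n_total, sd = config$trait_noise_sd)
      traits <- data.frame(module_trait = tv,
                           row.names = names(stage_of))
      trait_record <- list(module = paste0("M", config$trait_module_index),
                           noise_sd = config$trait_noise_sd)
    }

    truth <- structure(list(dynamic_de = de, rewired_pairs = pairs,
                            module_of = module_of, trait = trait_record,
                            config = config),
                       class = "SyntheticTruth")
    list(dataset = expression_dataset(x, stage_of, config$stage_labels,
                                      traits),
         truth = truth)
  })
}

#' Synthetic background interaction network for planted truth
#'
#' Contains a `ppi_coverage` fraction of the planted rewired pairs plus
#' `ppi_n_random_edges` Erdos-Renyi edges among all genes, each with a
#' Uniform(0.2, 1) confidence score so confidence filtering is exercised.
#'
#' @param truth A `SyntheticTruth` from [generate_dataset()].
#' @param config The `generator_config` used to generate it.
#' @return An `EdgeTable` tagged `"synthetic"`.
#' @export
generate_background_ppi <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  with_seed(config$seed + 1L, {
    genes <- names(truth$module_of)
    a <- character(0); b <- character(0)
    if (!is.null(truth$rewired_pairs) && config$ppi_coverage > 0) {
      n_keep <- round(config$ppi_coverage * nrow(truth$rewired_pairs))
      keep <- sample(nrow(truth$rewired_pairs), n_keep)
      a <- truth$rewired_pairs$geneA[keep]
      b <- truth$rewired_pairs$geneB[keep]
    }
    if (config$ppi_n_random_edges > 0) {
      ra <- sample(genes, config$ppi_n_random_edges, replace = TRUE)
      rb <- sample(genes, config$ppi_n_random_edges, replace = TRUE)
      ok <- ra != rb
      a <- c(a, ra[ok]); b <- c(b, rb[ok])
    }
    edge_table(a, b, stats::runif(length(a), 0.2, 1), "synthetic")
  })
}

#' Score recovery of planted structure
#'
#' Precision and recall of found dynamic DEGs and dynamic DLs against the
#' planted truth, and the adjusted Rand index of a module assignment
#' against the planted module membership.
#'
#' @param truth A `SyntheticTruth`.
#' @param found_degs Character vector of genes, or a `DynamicDegSet`.
#' @param found_dls Data frame with `geneA`/`geneB`, or `NULL`.
#' @param found_modules A `ModuleAssignment` or named module vector, or
#'   `NULL`.
#' @return Data frame `metric`, `value`.
#' @export
score_recovery <- function(truth, found_degs = NULL, found_dls = NULL,
                           found_modules = NULL) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  rows <- list()
  pr <- function(found, planted) {
    tp <- length(intersect(found, planted))
    c(precision = if (length(found)) tp / length(found) else NA_real_,
      recall = if (length(planted)) tp / length(planted) else NA_real_)
  }
  if (!is.null(found_degs)) {
    found <- if (is.data.frame(found_degs)) found_degs$gene else found_degs
    s <- pr(found, truth$dynamic_de$gene)
    rows$deg <- data.frame(metric = c("deg_precision", "deg_recall"),
                           value = unname(s))
  }
  if (!is.null(found_dls)) {
    fk <- paste(pmin(found_dls$geneA, found_dls$geneB),
                pmax(found_dls$geneA, found_dls$geneB))
    tk <- paste(truth$rewired_pairs$geneA, truth$rewired_pairs$geneB)
    s <- pr(fk, tk)
    rows$dl <- data.frame(metric = c("dl_precision", "dl_recall"),
                          value = unname(s))
  }
  if (!is.null(found_modules)) {
    found <- if (inherits(found_modules, "ModuleAssignment"))
      found_modules$module_of else found_modules
    genes <- intersect(names(found), names(truth$module_of))
    ari <- mclust::adjustedRandIndex(found[genes], truth$module_of[genes])
    rows$mod <- data.frame(metric = "module_ari", value = ari)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
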