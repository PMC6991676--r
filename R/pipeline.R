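#' Run the full staged-network workflow
#'
#' Executes, in order: z-score normalization; transition-wise differential
#' expression with BH control and the dynamic-DEG overlap at both FDR
#' levels; per-stage correlations, d-PCC and dynamic-DL selection;
#' background merging, confidence filtering and projection of dynamic DLs
#' onto the background PPI with shared-neighbour scoring and the hub table
#' (strict-DEG node universe); weighted co-expression module detection with
#' module-trait statistics when traits are present; and hypergeometric
#' over-representation of the dynamic DEGs when gene sets are supplied.
#' Any stage failure aborts with a stage-named error.
#'
#' @param dataset A staged `ExpressionDataset` (probe-collapsed).
#' @param backgrounds A single `EdgeTable` or list of them.
#' @param gene_sets Optional `GeneSetCollection` for enrichment.
#' @param config A [run_config()].
#' @return A list of class `stagenet_report` with sections `config`, `deg`,
#'   `dls`, `network`, `modules`, `enrichment` and `counts`.
#' @export
run_all <- function(dataset, backgrounds, gene_sets = NULL,
                    config = run_config()) {
  stopifnot(inherits(dataset, "ExpressionDataset"),
            inherits(config, "run_config"))
  if (inherits(backgrounds, "EdgeTable")) backgrounds <- list(backgrounds)
  stage_try <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  stages <- dataset$stage_order
  message("run_all: ", nrow(dataset$values), " genes, ",
          ncol(dataset$values), " samples, stages ",
          paste(stages, collapse = " -> "),
          "; fdr ", config$fdr_deg, "/", config$fdr_deg_strict,
          ", |d-PCC| in [", config$dpcc_low, ", ", config$dpcc_high,
          "], confidence > ", config$confidence_min,
          ", seed ", config$rng_seed)

  d <- stage_try("normalize", zscore_normalize(dataset))
  deg <- stage_try("deg", {
    td <- if (config$ttest_on == "zscore") d else dataset
    s1 <- ttest_transition(td, stages[1], stages[2], welch = config$welch)
    s2 <- ttest_transition(td, stages[2], stages[3], welch = config$welch)
    list(transition1 = s1, transition2 = s2,
         dynamic = dynamic_degs(s1, s2, config$fdr_deg),
         dynamic_strict = dynamic_degs(s1, s2, config$fdr_deg_strict))
  })
  message("deg: ", nrow(deg$dynamic), " dynamic DEGs at FDR<",
          config$fdr_deg, ", ", nrow(deg$dynamic_strict), " at FDR<",
          config$fdr_deg_strict)

  background <- stage_try("background", {
    merged <- merge_backgrounds(backgrounds)
    filter_edges_by_confidence(merged, config$confidence_min)
  })
  message("background: ", nrow(background), " edges after confidence filter")

  dls <- stage_try("dls", {
    subset <- if (config$genes_from_ppi)
      intersect(rownames(d$values),
                unique(c(background$geneA, background$geneB)))
    else NULL
    dynamic_link_table(d, config$dpcc_low, config$dpcc_high,
                       gene_subset = subset,
                       require_sign_flip = config$require_sign_flip)
  })
  n_dyn_dl <- sum(dls$is_dynamic_dl)
  message("dls: ", nrow(dls), " links in >=1 transition, ", n_dyn_dl,
          " dynamic DLs")

  network <- stage_try("network", {
    net <- map_dls_to_ppi(dls, background, mode = config$map_mode)
    annotate_shared_neighbours(net, background)
  })
  hubs <- stage_try("hubs",
                    hub_ranking(network, genes = deg$dynamic_strict$gene))
  message("network: ", nrow(network$nodes), " genes, ",
          nrow(network$edges), " dynamic links after PPI mapping")

  modules <- stage_try("modules", {
    scan <- soft_threshold_scan(d, config$soft_powers, config$target_r2)
    beta <- attr(scan, "chosen_beta")
    adj <- adjacency_matrix(d, beta)
    assignment <- detect_modules(1 - tom_matrix(adj),
                                 min_module_size = config$min_module_size,
                                 cut_height = config$cut_height,
                                 merge_height = config$merge_height,
                                 exprs = d)
    res <- list(scan = scan, beta = beta, assignment = assignment,
                k_im = intramodular_connectivity(adj, assignment))
    if (!is.null(dataset$traits) && length(assignment$sizes)) {
      me <- module_eigengenes(d, assignment)
      res$eigengenes <- me
      res$trait <- module_trait_correlation(me, dataset$traits)
      res$gs_mm <- gene_significance_and_mm(d, dataset$traits, assignment)
    }
    res
  })
  message("modules: beta=", modules$beta, ", ",
          length(modules$assignment$sizes), " modules")

  enrichment <- NULL
  if (!is.null(gene_sets) && nrow(deg$dynamic))
    enrichment <- stage_try("enrichment",
      hypergeom_enrich(deg$dynamic$gene, gene_sets,
                       universe = rownames(dataset$values),
                       alpha = config$fdr_deg))

  counts <- list(n_genes = nrow(dataset$values),
                 n_samples = ncol(dataset$values),
                 n_dynamic_degs = nrow(deg$dynamic),
                 n_dynamic_degs_strict = nrow(deg$dynamic_strict),
                 n_dynamic_dls = n_dyn_dl,
                 n_dynamic_dls_in_ppi = nrow(network$edges),
                 n_network_genes = nrow(network$nodes),
                 n_modules = length(modules$assignment$sizes))
  structure(list(config = config, deg = deg, background = background,
                 dls = dls, network = network, hubs = hubs,
                 modules = modules, enrichment = enrichment,
                 counts = counts),
            class = "stagenet_report")
}

#' @export
print.stagenet_report <- function(x, ...) {
  cat("Staged-network run report\n")
  cat("  seed:", x$config$rng_seed, "\n")
  with(x$counts, {
    cat("  dynamic DEGs: ", n_dynamic_degs, " (FDR<", x$config$fdr_deg,
        "), ", n_dynamic_degs_strict, " (FDR<", x$config$fdr_deg_strict,
        ")\n", sep = "")
    cat("  dynamic DLs:  ", n_dynamic_dls, " pre-PPI, ",
        n_dynamic_dls_in_ppi, " after PPI mapping (",
        n_network_genes, " genes)\n", sep = "")
    cat("  modules:      ", n_modules, " (soft power ", x$modules$beta,
        ")\n", sep = "")
  })
  if (!is.null(x$enrichment))
    cat("  enriched sets:", sum(x$enrichment$significant), "of",
        nrow(x$enrichment), "\n")
  if (nrow(x$hubs)) {
    cat("  top hubs:\n")
    print(utils::head(x$hubs, 5))
  }
  invisible(x)
}
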