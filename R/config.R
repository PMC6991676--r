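#' Pipeline run configuration
#'
#' Collects every tunable threshold of the staged-network workflow with the
#' defaults used throughout: FDR 0.05 (0.01 strict) for dynamic DEGs, the
#' closed interval \[0.8, 2\] on |d-PCC| for differentially co-expressed
#' links, a strict > 0.4 confidence filter for scored background edges, and
#' the weighted-network parameters (candidate soft powers 1..20, scale-free
#' fit target 0.9, minimum module size 30).
#'
#' @param fdr_deg FDR threshold defining dynamic DEGs.
#' @param fdr_deg_strict Stricter FDR used for the hub-table node universe.
#' @param dpcc_low,dpcc_high Closed |d-PCC| interval selecting DLs.
#' @param confidence_min Strict lower bound for scored background edges.
#' @param require_sign_flip If `TRUE`, a dynamic DL must have opposite-signed
#'   d-PCCs in the two transitions (stricter reading of "overlap").
#' @param map_mode `"edges"` (a DL must itself be a background interaction)
#'   or `"nodes"` (both endpoints must occur in the background).
#' @param genes_from_ppi Restrict the pair universe to background-PPI nodes.
#' @param soft_powers Candidate soft-threshold powers.
#' @param target_r2 Scale-free fit index target for choosing the power.
#' @param min_module_size,cut_height,merge_height Module-detection controls
#'   (see [detect_modules()]).
#' @param ttest_on `"zscore"` (default pipeline order) or `"raw"`.
#' @param welch Use Welch rather than pooled-variance t statistics.
#' @param rng_seed Integer seed echoed into reports.
#' @return A list of class `run_config`.
#' @export
run_config <- function(fdr_deg = 0.05, fdr_deg_strict = 0.01,
                       dpcc_low = 0.8, dpcc_high = 2,
                       confidence_min = 0.4,
                       require_sign_flip = FALSE,
                       map_mode = c("edges", "nodes"),
                       genes_from_ppi = FALSE,
                       soft_powers = 1:20, target_r2 = 0.9,
                       min_module_size = 30, cut_height = 0.995,
                       merge_height = 0.25,
                       ttest_on = c("zscore", "raw"), welch = FALSE,
                       rng_seed = 42L) {
  stopifnot(fdr_deg > 0, fdr_deg <= 1,
            fdr_deg_strict > 0, fdr_deg_strict <= fdr_deg,
            dpcc_low >= 0, dpcc_low < dpcc_high, dpcc_high <= 2,
            confidence_min >= 0, confidence_min <= 1)
  structure(list(fdr_deg = fdr_deg, fdr_deg_strict = fdr_deg_strict,
                 dpcc_low = dpcc_low, dpcc_high = dpcc_high,
                 confidence_min = confidence_min,
                 require_sign_flip = isTRUE(require_sign_flip),
                 map_mode = match.arg(map_mode),
                 genes_from_ppi = isTRUE(genes_from_ppi),
                 soft_powers = soft_powers, target_r2 = target_r2,
                 min_module_size = min_module_size, cut_height = cut_height,
                 merge_height = merge_height,
                 ttest_on = match.arg(ttest_on), welch = isTRUE(welch),
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}
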