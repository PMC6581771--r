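#' Filtering and testing parameters for the prioritization cascade
#'
#' Bundles every tunable threshold of the pipeline. Defaults follow the
#' published filtering protocol: variants are excluded when 3 or more fall
#' within a 10 bp window, when coverage depth is below 5, or when mapping or
#' genotype quality is below 30 (strict "less than" exclusions, so values at
#' the threshold are retained). The differential-expression stage flags genes
#' at Benjamini-Hochberg FDR 0.05 with at least a two-fold change, and
#' pathway enrichment is called significant at adjusted p <= 0.05 using the
#' EASE variant of the hypergeometric test by default.
#'
#' @param cluster_window_bp Window length in bp for the variant-cluster filter.
#' @param cluster_min_count Minimum number of variant positions within one
#'   window that triggers removal (must be >= 2).
#' @param min_depth Minimum per-genotype read depth retained.
#' @param min_site_mq Minimum site-level mapping quality retained.
#' @param min_gq Minimum genotype quality retained.
#' @param deg_fdr FDR threshold for calling a gene differentially expressed.
#' @param deg_min_abs_log2fc Minimum absolute log2 fold change for a DEG call.
#' @param enrich_alpha Adjusted-p threshold for calling a gene set enriched.
#' @param ease_mode Use the EASE score (hypergeometric tail with one hit
#'   removed) instead of the plain hypergeometric tail.
#' @param damaging_min_votes Minimum number of deleterious predictor calls for
#'   the predictor-consensus flag.
#' @param allow_hom Also accept homozygous-alt carriers in the affected
#'   parent-child sharing stage (off by default: strict heterozygous model).
#' @return A named list of class `famseg_params`.
#' @examples
#' filter_params(min_depth = 10)
#' @export
filter_params <- function(cluster_window_bp = 10L,
                          cluster_min_count = 3L,
                          min_depth = 5,
                          min_site_mq = 30,
                          min_gq = 30,
                          deg_fdr = 0.05,
                          deg_min_abs_log2fc = 1.0,
                          enrich_alpha = 0.05,
                          ease_mode = TRUE,
                          damaging_min_votes = 2L,
                          allow_hom = FALSE) {
  p <- list(
    cluster_window_bp = as.integer(cluster_window_bp),
    cluster_min_count = as.integer(cluster_min_count),
    min_depth = min_depth,
    min_site_mq = min_site_mq,
    min_gq = min_gq,
    deg_fdr = deg_fdr,
    deg_min_abs_log2fc = deg_min_abs_log2fc,
    enrich_alpha = enrich_alpha,
    ease_mode = isTRUE(ease_mode),
    damaging_min_votes = as.integer(damaging_min_votes),
    allow_hom = isTRUE(allow_hom)
  )
  num <- p[c("cluster_window_bp", "cluster_min_count", "min_depth",
             "min_site_mq", "min_gq", "deg_fdr", "deg_min_abs_log2fc",
             "enrich_alpha", "damaging_min_votes")]
  if (any(vapply(num, function(x) !is.finite(x) || x <= 0, logical(1)))) {
    abort("all famseg thresholds must be positive finite numbers")
  }
  if (p$cluster_min_count < 2L) abort("cluster_min_count must be >= 2")
  structure(p, class = c("famseg_params", "list"))
}
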