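# Site/genotype quality exclusions and the variant-cluster filter.

#' Remove variants falling in dense clusters
#'
#' A variant is removed when some fixed-length genomic window (positions
#' `x ... x + window_bp - 1` on one chromosome) contains at least
#' `min_count` distinct variant positions, that variant's position included.
#' Any qualifying window triggers removal, so the rule is order-independent
#' and removes whole dense regions, not only maximal clusters. Indels count
#' at their POS like SNVs.
#'
#' @param variants Variant tibble sorted by (chrom, pos); unsorted input is a
#'   contract error.
#' @param window_bp Window length in bp (default 10).
#' @param min_count Minimum variant positions per window triggering removal
#'   (default 3).
#' @return List with tibbles `kept` and `removed` (input order preserved;
#'   together they partition the input). `removed` carries a `reason`
#'   column set to `"cluster"`.
#' @examples
#' # three variants within 10 bp are all removed
#' @export
filter_cluster <- function(variants, window_bp = 10L, min_count = 3L) {
  assert_variants(variants)
  if (!is_sorted_variants(variants)) {
    abort("filter_cluster requires input sorted by (chrom, pos)")
  }
  window_bp <- as.integer(window_bp)
  min_count <- as.integer(min_count)
  if (window_bp < 1 || min_count < 2) {
    abort("window_bp must be >= 1 and min_count >= 2")
  }
  removed_flag <- logical(nrow(variants))
  for (chr in unique(variants$chrom)) {
    idx <- which(variants$chrom == chr)
    upos <- sort(unique(variants$pos[idx]))
    bad <- logical(length(upos))
    # a window containing >= min_count positions can be slid left until its
    # start coincides with its leftmost contained variant, so it suffices to
    # check windows starting at each variant position
    for (j in seq_along(upos)) {
      r <- findInterval(upos[j] + window_bp - 1, upos)
      if (r - j + 1 >= min_count) bad[j:r] <- TRUE
    }
    removed_flag[idx] <- variants$pos[idx] %in% upos[bad]
  }
  removed <- variants[removed_flag, ]
  if (nrow(removed) > 0) removed$reason <- "cluster"
  else removed$reason <- character()
  list(kept = variants[!removed_flag, ], removed = removed)
}

#' Remove low-quality variants
#'
#' A variant is kept iff its site mapping quality is at least `min_site_mq`
#' and every non-missing genotype among the analysed samples has depth at
#' least `min_depth` and genotype quality at least `min_gq`. Thresholds are
#' strict "less than" exclusions, so boundary values are retained. Missing
#' quality fields count as failures.
#'
#' @param variants Variant tibble.
#' @param params [filter_params()] list supplying `min_site_mq`, `min_depth`,
#'   `min_gq`.
#' @param samples Optional character vector restricting the genotypes
#'   evaluated (e.g. the members of the family being analysed); default all.
#' @return List with tibbles `kept` and `removed`; `removed` has a `reason`
#'   column with the failed criteria (`"mq"`, `"depth"`, `"gq"`, joined by
#'   `";"` when several fail).
#' @export
filter_quality <- function(variants, params = filter_params(), samples = NULL) {
  assert_variants(variants)
  reasons <- map_chr(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    g <- v$genotypes[[1]]
    if (!is.null(samples)) g <- g[g$sample_id %in% samples, , drop = FALSE]
    g <- g[!is.na(g$gt) & g$gt != "./.", , drop = FALSE]
    r <- character()
    if (is.na(v$site_mq) || v$site_mq < params$min_site_mq) r <- c(r, "mq")
    if (nrow(g) > 0) {
      if (any(is.na(g$dp) | g$dp < params$min_depth)) r <- c(r, "depth")
      if (any(is.na(g$gq) | g$gq < params$min_gq)) r <- c(r, "gq")
    }
    paste(r, collapse = ";")
  })
  keep <- !nzchar(reasons)
  removed <- variants[!keep, ]
  removed$reason <- reasons[!keep]
  list(kept = variants[keep, ], removed = removed)
}
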