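# Two-group differential-expression stage: per-gene Welch t-test on
# log2-scale intensities with Benjamini-Hochberg FDR control and a fold-
# change filter. A deliberately standard, dependency-light microarray-style
# analysis; moderated-variance methods are out of scope.

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up procedure (`stats::p.adjust(method = "BH")`), input
#' order preserved; p-values outside \[0, 1\] are an error.
#'
#' @param p Numeric vector of p-values.
#' @return Numeric vector of q-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Per-gene Welch two-sample test between cases and controls
#'
#' Computes, for every gene, the two-sided Welch t-test comparing case and
#' control samples (values assumed log2-scale), the log2 fold change (case
#' mean minus control mean), BH-adjusted q-values across all genes, and the
#' DEG flag `is_deg = (q <= deg_fdr) & (|log2FC| >= deg_min_abs_log2fc)`.
#' Genes with zero variance in both groups get p = 1 when the group means
#' are equal and p = 0 when they differ.
#'
#' @param expr Expression tibble (`gene` column + sample columns), as from
#'   [read_expression()].
#' @param groups Group tibble (`sample_id`, `group`), as from
#'   [read_groups()]; both groups need at least 2 samples present in `expr`.
#' @param params [filter_params()] list supplying `deg_fdr` and
#'   `deg_min_abs_log2fc`.
#' @return Tibble of class `famseg_deg`: `gene`, `log2_fold_change`,
#'   `t_stat`, `df`, `p_value`, `q_value`, `is_deg`.
#' @export
deg_test <- function(expr, groups, params = filter_params()) {
  assert_columns(expr, "gene", "expression matrix")
  assert_columns(groups, c("sample_id", "group"), "group map")
  cases <- intersect(groups$sample_id[groups$group == "case"], names(expr))
  ctrls <- intersect(groups$sample_id[groups$group == "control"], names(expr))
  if (length(cases) < 2 || length(ctrls) < 2) {
    abort("both groups need at least 2 samples present in the matrix")
  }
  x <- as.matrix(expr[, cases, drop = FALSE])
  y <- as.matrix(expr[, ctrls, drop = FALSE])
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m1 - m2
  tt <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tt), df = df, lower.tail = FALSE)
  # degenerate genes: no within-group variance at all
  degen <- se2 == 0
  p[degen & lfc == 0] <- 1
  p[degen & lfc != 0] <- 0
  tt[degen] <- ifelse(lfc[degen] == 0, 0, sign(lfc[degen]) * Inf)
  df[degen] <- NA_real_
  q <- bh_adjust(p)
  out <- tibble(
    gene = expr$gene, log2_fold_change = lfc, t_stat = tt, df = df,
    p_value = p, q_value = q,
    is_deg = q <= params$deg_fdr & abs(lfc) >= params$deg_min_abs_log2fc
  )
  class(out) <- c("famseg_deg", class(out))
  out
}

#' Genes flagged as differentially expressed
#' @param deg Result of [deg_test()].
#' @return Character vector of DEG gene symbols.
#' @export
deg_genes <- function(deg) {
  assert_columns(deg, c("gene", "is_deg"), "DEG result")
  deg$gene[deg$is_deg]
}
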