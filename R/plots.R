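# ggplot2 visualisations for the main result types.

#' Volcano plot of a differential-expression result
#' @param object A `famseg_deg` tibble from [deg_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot famseg_deg
#' @export
autoplot.famseg_deg <- function(object, ...) {
  df <- as_tibble(object)
  df$neglog10p <- -log10(pmax(df$p_value, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fold_change,
                                   y = .data$neglog10p,
                                   colour = .data$is_deg)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (case - control)",
                  y = "-log10 p", colour = "DEG") +
    ggplot2::theme_minimal()
}

#' Bar plot of gene-set enrichment results
#' @param object A `famseg_enrich` tibble from [enrich()].
#' @param alpha Significance line drawn at this adjusted-p level.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot famseg_enrich
#' @export
autoplot.famseg_enrich <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object)
  df$set_name <- stats::reorder(df$set_name, -df$q_value)
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(pmax(.data$q_value, 1e-300)),
                                   y = .data$set_name)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL) +
    ggplot2::theme_minimal()
}

#' Cascade plot of per-individual counts across pipeline stages
#' @param run A `famseg_run` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_cascade <- function(run) {
  stopifnot(inherits(run, "famseg_run"))
  df <- tidyr::pivot_longer(run$summary$per_individual,
                            c("quality_pass_carried", "nssi_novel",
                              "pair_shared_carried"),
                            names_to = "stage", values_to = "count")
  df$stage <- factor(df$stage, levels = c("quality_pass_carried",
                                          "nssi_novel",
                                          "pair_shared_carried"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$count,
                                   group = .data$individual_id,
                                   colour = .data$family_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = NULL, y = "variants carried", colour = "family") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}
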