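# Convenience plots over the influence tables; the tables are the
# contract, these are presentation only.

#' Forest plot of single-SNP Wald-ratio estimates
#'
#' @param report an `mr_report` (or a data frame shaped like
#'   `report$single_snp`).
#' @return A ggplot object.
#' @export
mr_forest_plot <- function(report) {
  tab <- if (inherits(report, "mr_report")) report$single_snp else report
  tab$snp <- factor(tab$snp, levels = rev(tab$snp))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$b, y = .data$snp)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant)) +
    ggplot2::labs(x = "causal log-odds estimate (Wald ratio, 95% CI)",
                  y = NULL, colour = "CI excludes 0") +
    ggplot2::theme_minimal()
}

#' Leave-one-out plot
#'
#' @param report an `mr_report` (or a data frame shaped like `report$loo`).
#' @return A ggplot object.
#' @export
mr_loo_plot <- function(report) {
  tab <- if (inherits(report, "mr_report")) report$loo else report
  tab$snp <- factor(tab$snp, levels = rev(tab$snp))
  all_b <- tab$b[tab$snp == "All"]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$b, y = .data$snp)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = all_b, colour = "steelblue") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "IVW estimate omitting one SNP (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
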