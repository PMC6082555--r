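# ggplot2 displays for the main result types.

#' @describeIn within_group_fpr Plot observed FPR (percent) against the
#'   |log2FC| cutoff grid, with mean +/- SD false-positive counts.
#' @param object An `fpr_report`.
#' @export
autoplot.fpr_report <- function(object, ...) {
  n_genes <- attr(object, "n_genes")
  df <- tibble::as_tibble(object)
  df$fpr_lo <- 100 * pmax(df$mean_fp - df$sd_fp, 0) / n_genes
  df$fpr_hi <- 100 * (df$mean_fp + df$sd_fp) / n_genes
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$fpr_percent)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$fpr_lo, ymax = .data$fpr_hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "|log2FC| cutoff",
                  y = "observed FPR (%)",
                  title = paste0("Within-group mock comparison (",
                                 attr(object, "route"), ", ",
                                 attr(object, "n_repeats"), " splits)")) +
    ggplot2::theme_minimal()
}

#' @describeIn nb_wald_two_group Volcano plot (log2 fold change against
#'   -log10 adjusted p).
#' @param object A `deg_result`.
#' @param fdr,lfc_cutoff Thresholds drawn as guide lines and used to color
#'   called genes.
#' @export
autoplot.deg_result <- function(object, fdr = 0.05, lfc_cutoff = 1, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$padj), ]
  df$called <- df$padj <= fdr & abs(df$log2fc) >= lfc_cutoff
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$called)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_vline(xintercept = c(-lfc_cutoff, lfc_cutoff),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(fdr), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Plot the dispersion trend and shrinkage
#'
#' Gene-wise, trend and final (shrunken) dispersions against the base mean,
#' on log10 axes.
#'
#' @param object A `dispersion_model`.
#' @param ... Unused.
#' @export
autoplot.dispersion_model <- function(object, ...) {
  df <- object$genes
  df <- df[df$base_mean > 0, ]
  long <- tidyr::pivot_longer(
    df[, c("base_mean", "disp_raw", "disp_map", "disp_trend")],
    cols = c("disp_raw", "disp_map", "disp_trend"),
    names_to = "kind", values_to = "dispersion")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$base_mean,
                                     y = .data$dispersion,
                                     colour = .data$kind)) +
    ggplot2::geom_point(data = function(d) d[d$kind != "disp_trend", ],
                        size = 0.3, alpha = 0.3) +
    ggplot2::geom_line(data = function(d) d[d$kind == "disp_trend", ]) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean of normalized counts", y = "dispersion") +
    ggplot2::theme_minimal()
}
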