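# --- Diagnostics plots ------------------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted pairwise IBD model
#'
#' Per-window proportion of differences along the genome with the Viterbi
#' IBD state as color and the emission level means as reference lines.
#'
#' @param object A `kin_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kin_fit
#' @export
autoplot.kin_fit <- function(object, ...) {
  d <- tidy(object)
  d$rate <- ifelse(d$N > 0, d$D / d$N, NA_real_)
  d$idx <- seq_len(nrow(d))
  p <- build_p_matrix(object$p0)$p
  ggplot2::ggplot(d, ggplot2::aes(x = .data$idx, y = .data$rate,
                                  colour = factor(.data$viterbi))) +
    ggplot2::geom_point(na.rm = TRUE, size = 0.9) +
    ggplot2::geom_hline(yintercept = p[c("0", "1", "2")], linetype = 3,
                        colour = "grey40") +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "window", y = "proportion of differences",
                  colour = "IBD state",
                  title = paste("model:", object$model)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing = ggplot2::unit(1, "pt"),
                   strip.text = ggplot2::element_blank())
}

#' Plot a fitted ROH model
#'
#' Per-window within-individual mismatch proportion with the posterior
#' probability of homozygosity.
#'
#' @param object A `roh_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roh_fit
#' @export
autoplot.roh_fit <- function(object, ...) {
  d <- tidy(object)
  d$rate <- ifelse(d$M > 0, d$Delta / d$M, NA_real_)
  d$idx <- seq_len(nrow(d))
  p <- build_p_matrix(object$p0)$p
  ggplot2::ggplot(d, ggplot2::aes(x = .data$idx)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$rate), na.rm = TRUE,
                        size = 0.9, colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$p_roh), colour = "firebrick") +
    ggplot2::geom_hline(yintercept = p[c("2", "4")], linetype = 3,
                        colour = "grey40") +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "window", y = "mismatch proportion / P(ROH)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing = ggplot2::unit(1, "pt"),
                   strip.text = ggplot2::element_blank())
}

#' Plot pairwise classification results
#'
#' Heatmap of the inferred category per pair with the confidence statistic
#' printed in each cell.
#'
#' @param results The `results` tibble of a [run_pipeline()] run.
#' @return A ggplot.
#' @export
plot_classification <- function(results) {
  d <- results
  d$best_group <- factor(d$best_group, levels = group_order)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$id_i, y = .data$id_j,
                                  fill = .data$best_group)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$delta_LL, 2)),
                       size = 2.6) +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "category") +
    ggplot2::theme_minimal()
}
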