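# ggplot2 views of study results.

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' Plot power curves of a study
#'
#' Fraction of replicates detecting at least `k` truly nonzero coefficients,
#' per method, as a function of the experiment index.
#'
#' @param study a `mine_study`.
#' @param k detection threshold (default 7, capped at the number of truly
#'   nonzero coefficients).
#' @return A ggplot object.
#' @export
plot_power <- function(study, k = NULL) {
  df <- summarize_power_fpr(study, k = k)
  ggplot2::ggplot(df, ggplot2::aes(.data$experiment, .data$power_pct,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "experiment", y = "power (%)",
                  colour = "method",
                  title = "Replicates detecting the truly nonzero coefficients") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot mean false-positive counts of a study
#'
#' @param study a `mine_study`.
#' @return A ggplot object.
#' @export
plot_false_positives <- function(study) {
  stopifnot(inherits(study, "mine_study"))
  df <- study$trajectories |>
    dplyr::group_by(.data$method, .data$experiment) |>
    dplyr::summarise(mean_fp = mean(.data$n_false_pos), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$experiment, .data$mean_fp,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "experiment", y = "mean false positives",
                  colour = "method") +
    ggplot2::theme_minimal()
}

#' Plot averaged posterior-mean trajectories of the tracked coefficients
#'
#' Truly nonzero coefficients are drawn in colour, truly zero ones in grey;
#' dashed lines mark the true values.
#'
#' @param study a `mine_study`.
#' @return A ggplot object.
#' @export
plot_tracked_means <- function(study) {
  df <- tracked_means(study) |>
    dplyr::mutate(truth = ifelse(.data$true_beta != 0, "nonzero", "zero"))
  ggplot2::ggplot(df, ggplot2::aes(.data$experiment, .data$mean_mu,
                                   group = .data$index,
                                   colour = .data$truth)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = unique(df$true_beta), linetype = 3,
                        colour = "grey60") +
    ggplot2::facet_wrap(~method) +
    ggplot2::scale_colour_manual(values = c(nonzero = "firebrick",
                                            zero = "steelblue")) +
    ggplot2::labs(x = "experiment", y = "mean posterior mean",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot method for study results
#'
#' @param object a `mine_study`.
#' @param type `"power"`, `"false_positives"` or `"tracked_means"`.
#' @param ... passed to the specific plot function.
#' @return A ggplot object.
#' @export
autoplot.mine_study <- function(object,
                                type = c("power", "false_positives",
                                         "tracked_means"), ...) {
  switch(match.arg(type),
         power = plot_power(object, ...),
         false_positives = plot_false_positives(object),
         tracked_means = plot_tracked_means(object))
}
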