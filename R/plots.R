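#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Coefficient plot of a Bayesian regression with the ROPE band
#'
#' Posterior medians and 95% credible intervals per coefficient, with the
#' region of practical equivalence shaded.
#'
#' @param object A [fit_bayes_lm()] object.
#' @param rope A [rope_halfwidth()] spec or numeric half-width; `NULL`
#'   derives it from the fitted outcome.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bayes_lm <- function(object, rope = NULL, ...) {
  if (is.null(rope)) rope <- rope_halfwidth(object$y)
  h <- if (inherits(rope, "rope_spec")) rope$halfwidth else abs(rope)
  td <- tidy(object)
  td <- td[!td$term %in% c("(Intercept)", "sigma"), ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$median, y = .data$term)) +
    ggplot2::annotate("rect", xmin = -h, xmax = h, ymin = -Inf, ymax = Inf,
                      alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "coefficient (PSPRS points)", y = NULL,
                  title = "Posterior medians and 95% credible intervals",
                  subtitle = sprintf("ROPE half-width %.2f", h)) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap of an evaluation report
#'
#' @param object An [evaluate_classification()] report.
#' @param ... Unused.
#' @return A ggplot object (row-percentage fill, count labels).
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  names(df) <- c("truth", "predicted", "n")
  pct <- as.data.frame(object$confusion_pct)
  df$pct <- pct$Freq
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = "% of truth row") +
    ggplot2::labs(x = "predicted", y = "truth",
                  title = sprintf("macro F1 = %.3f, kappa = %.3f",
                                  object$macro_f1, object$kappa)) +
    ggplot2::theme_minimal()
}

#' Regional tau density profile plot
#'
#' Log10 tau density by region and tau type, one panel per type. A plain
#' replacement for polar density plots.
#'
#' @param densities A [density_table()] result.
#' @param floor Zero-density floor passed to [log_density()].
#' @return A ggplot object.
#' @export
plot_density_profile <- function(densities, floor = NULL) {
  long <- tidyr::pivot_longer(
    densities,
    cols = dplyr::all_of(c("CB_density", "NFT_density", "TA_density",
                           "TF_density", "total_density",
                           "hallmark_density")),
    names_to = "tau_type", values_to = "density"
  )
  long$tau_type <- sub("_density$", "", long$tau_type)
  long$log10_density <- as.numeric(log_density(long$density, floor))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$region,
                                     y = .data$log10_density)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~tau_type) +
    ggplot2::labs(x = NULL, y = expression(log[10] ~ "objects /" ~ mu * m^2),
                  title = "Regional tau density by type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
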