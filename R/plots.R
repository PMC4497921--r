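#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot raw versus error-corrected VAF distributions
#'
#' Cumulative distribution of per-site VAFs for conventional per-read
#' observations and for consensus-corrected read families; the corrected
#' curve rising earlier reflects the reduced error floor.
#'
#' @param cdf tibble from [raw_vs_corrected_cdf()].
#' @return a ggplot.
#' @export
plot_error_cdf <- function(cdf) {
  long <- tidyr::pivot_longer(cdf, c("F_raw", "F_eccs"),
                              names_to = "pipeline", values_to = "F")
  long$pipeline <- ifelse(long$pipeline == "F_raw",
                          "conventional reads", "read families (ECCS)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$vaf, y = .data$F,
                                     colour = .data$pipeline)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "VAF at wild-type sites",
                  y = "cumulative fraction of sites", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the substitution-class spectrum of residual errors
#'
#' Strand-collapsed substitution classes with the number of alternate-allele
#' families observed at wild-type sites; an excess in C>A(G>T) is the
#' signature of oxidative guanine damage.
#'
#' @param profile an `ecs_error_profile` from [class_profile()].
#' @return a ggplot.
#' @export
plot_class_spectrum <- function(profile) {
  stopifnot(inherits(profile, "ecs_error_profile"))
  ggplot2::ggplot(profile$classes,
                  ggplot2::aes(x = .data$class6, y = .data$alt_families)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "variant read families at wild-type sites") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.ecs_error_profile <- function(object, ...) {
  plot_class_spectrum(object)
}

#' @export
autoplot.ecs_dilution_fit <- function(object, ...) {
  dat <- object$data
  eps <- min(dat$expected_vaf[dat$expected_vaf > 0]) / 10
  ggplot2::ggplot(dat, ggplot2::aes(x = pmax(.data$expected_vaf, eps),
                                    y = pmax(.data$estimated_vaf, eps))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "expected VAF (dilution x tumor VAF)",
      y = "estimated VAF (read families)",
      title = sprintf("Dilution series: r^2 = %.4f", object$r_squared)) +
    ggplot2::theme_minimal()
}
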