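# ggplot2 views of the package's result objects.

#' @describeIn run_calibration_loop Bar chart of coverage SD per
#'   calibration round (the run-quality series a calibration campaign is
#'   judged by).
#' @param object A `calibration_run`.
#' @param ... Ignored.
#' @export
autoplot.calibration_run <- function(object, ...) {
  ggplot(object$trace, aes(x = factor(.data$round), y = .data$sd)) +
    geom_col(fill = "steelblue") +
    labs(x = "Calibration round", y = "SD of per-amplicon coverage",
         title = "Coverage dispersion across calibration rounds") +
    theme_minimal()
}

#' Per-amplicon coverage bar chart
#'
#' @param profile A [coverage_profile()].
#' @return A ggplot object; the dashed line marks the mean coverage.
#' @export
plot_coverage_profile <- function(profile) {
  mu <- attr(profile, "mean")
  ggplot(as_tibble(profile), aes(x = .data$amplicon_id, y = .data$coverage)) +
    geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = mu, linetype = "dashed", colour = "red") +
    labs(x = NULL, y = "Mean coverage (reads/base/sample)",
         title = sprintf("Coverage profile (SD = %.1f, CV = %.2f)",
                         attr(profile, "sd"), attr(profile, "cv"))) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}

#' @describeIn summarize_cohort Bar chart of the four diagnostic
#'   categories (the yield breakdown of the screen).
#' @param object A `cohort_summary`.
#' @param ... Ignored.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  df <- tibble(
    category = factor(c("solved", "partially_solved", "one_AR_variant", "unsolved"),
                      levels = c("solved", "partially_solved", "one_AR_variant", "unsolved")),
    n = c(object$n_solved, object$n_partially, object$n_one_AR, object$n_unsolved)
  )
  ggplot(df, aes(x = .data$category, y = .data$n, fill = .data$category)) +
    geom_col(show.legend = FALSE) +
    labs(x = NULL, y = "Index cases",
         title = "Diagnostic categories") +
    theme_minimal()
}
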