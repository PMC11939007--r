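# ggplot2 layers for the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_line geom_point
#'   geom_histogram geom_vline geom_hline labs theme_minimal facet_wrap
NULL

#' Plot survival curves
#'
#' @param object A `bime_curves` tibble from [predict_survival()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bime_curves <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$surv,
                     group = .data$patient_id)) +
    geom_line(alpha = 0.4) +
    labs(x = "months", y = "S(t)",
         title = sprintf("Predicted survival, arm %d (%s)",
                         object$arm[1],
                         if (object$arm[1] == 0) "NSM" else "MRM")) +
    theme_minimal()
}

#' Plot a Kaplan-Meier curve
#'
#' @param object A `bime_km` tibble from [km_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bime_km <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$surv)) +
    geom_step() +
    labs(x = "months", y = "S(t)", title = "Kaplan-Meier estimate") +
    theme_minimal()
}

#' Plot the individual-treatment-effect distribution
#'
#' Histogram of estimated individual treatment effects (months of
#' time-at-risk gained under MRM), shaded by the recommended arm.
#'
#' @param object A `bime_recs` tibble from [recommend()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bime_recs <- function(object, ...) {
  ggplot(object, aes(x = .data$ite,
                     fill = factor(.data$recommended,
                                   labels = c("NSM", "MRM")[
                                     sort(unique(object$recommended)) + 1]))) +
    geom_histogram(bins = 40) +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = "ITE (months, TaR MRM - TaR NSM)", y = "patients",
         fill = "recommended") +
    theme_minimal()
}

#' Covariate balance (love) plot
#'
#' @param object A [balance_table()] tibble.
#' @param ref Balance threshold line (default 0.1).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_balance <- function(object, ref = 0.1, ...) {
  long <- tidyr::pivot_longer(object, dplyr::starts_with("smd"),
                              names_to = "adjusted", values_to = "value")
  long$adjusted <- ifelse(long$adjusted == "smd", "unweighted", "weighted")
  ggplot(long, aes(x = .data$value, y = .data$term,
                   colour = .data$adjusted)) +
    geom_point() +
    geom_vline(xintercept = ref, linetype = 2) +
    labs(x = "standardized mean difference", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Plot the training-loss decomposition
#'
#' One line per loss component over training iterations.
#'
#' @param object A `bime_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bime_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$history[, c("iter", "lcox0", "lcox1", "ipm", "q0", "q1",
                       "total")],
    -"iter", names_to = "component", values_to = "value")
  ggplot(long, aes(x = .data$iter, y = .data$value,
                   colour = .data$component)) +
    geom_line() +
    labs(x = "iteration", y = "loss") +
    theme_minimal()
}
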