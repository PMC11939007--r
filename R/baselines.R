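# Comparator recommendation models in the same T-learner interface as the
# mixture model: a linear Cox proportional-hazards T-learner, DeepSurv- and
# BITES-style constrained configurations, the NCCN-note eligibility rule,
# and a ground-truth oracle for synthetic cohorts. All emit the same
# recommendation schema, so the evaluation code is model-agnostic.

#' Cox proportional-hazards T-learner
#'
#' Fits one linear Cox model per treatment arm (in-package Newton-Raphson
#' on the Breslow partial likelihood) on covariates standardized with the
#' pooled training statistics; predictions flow through the same survival /
#' time-at-risk / treatment-effect path as the mixture model.
#'
#' @inheritParams bime_fit
#' @return An object of class `bime_cph` holding the per-arm fits and
#'   Breslow baselines.
#' @export
fit_tlearner_cph <- function(data, covariates = default_covariates(),
                             time = "followup_months",
                             event = "event_overall",
                             treatment = "treatment") {
  arm <- data[[treatment]]
  if (length(unique(arm)) < 2) {
    abort("fit_tlearner_cph: need both treatment arms")
  }
  dm <- design_matrix(data, covariates)
  fits <- lapply(0:1, function(a) {
    idx <- which(arm == a)
    if (sum(data[[event]][idx]) < 1) {
      abort(sprintf("fit_tlearner_cph: no events in arm %d", a))
    }
    coxph_breslow(dm$X[idx, , drop = FALSE], data[[time]][idx],
                  data[[event]][idx])
  })
  structure(list(fits = fits, covariates = covariates,
                 design_stats = dm$stats, time = time, event = event,
                 treatment = treatment, n = nrow(data)),
            class = "bime_cph")
}

#' @export
print.bime_cph <- function(x, ...) {
  cat("Cox PH T-learner (", x$n, "patients )\n")
  cat("arm 0 (NSM):\n"); print(tidy.bime_coxfit(x$fits[[1]]))
  cat("arm 1 (MRM):\n"); print(tidy.bime_coxfit(x$fits[[2]]))
  invisible(x)
}

#' @rdname fit_tlearner_cph
#' @param x A `bime_cph`.
#' @param ... Unused.
#' @export
tidy.bime_cph <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy.bime_coxfit(x$fits[[1]]), arm = 0L),
    dplyr::mutate(tidy.bime_coxfit(x$fits[[2]]), arm = 1L))
}

cph_surv_matrix <- function(object, X, arm, times) {
  fit <- object$fits[[arm + 1L]]
  Xk <- X[, names(fit$coef), drop = FALSE]
  eta <- drop(Xk %*% fit$coef)
  L <- eval_cumhaz(fit$baseline, times)
  exp(-outer(exp(eta), L))
}

#' @export
predict_survival.bime_cph <- function(object, data, arm, times = NULL,
                                      ...) {
  if (!arm %in% c(0, 1)) abort("predict_survival: arm must be 0 or 1")
  fit <- object$fits[[arm + 1L]]
  if (is.null(times)) {
    times <- sort(unique(c(0, fit$baseline$time)))
  }
  check_grid(times)
  X <- design_matrix(data, object$covariates, object$design_stats)$X
  as_curves(cph_surv_matrix(object, X, arm, times), times,
            curve_ids(data), arm)
}

#' @export
recommend.bime_cph <- function(object, data, threshold = 0.10, cap = 120,
                               ...) {
  X <- design_matrix(data, object$covariates, object$design_stats)$X
  tars <- lapply(0:1, function(a) {
    times <- sort(unique(c(0, object$fits[[a + 1L]]$baseline$time, cap)))
    times <- times[times <= cap]
    tar_from_matrix(cph_surv_matrix(object, X, a, times), times,
                    threshold, cap)
  })
  new_recs(curve_ids(data), tars[[1]], tars[[2]],
           received = if (object$treatment %in% names(data))
             data[[object$treatment]] else NULL)
}

#' NCCN-style eligibility rule for NSM
#'
#' Recommends NSM when any of the following holds: grade I or II, HER2
#' negative, N0 nodal stage, or axillary lymph-node negative; otherwise
#' MRM. (Disjunctive reading of the guideline note.)
#'
#' @param data Data frame with `grade`, `her2_positive`, `n_stage`,
#'   `aln_positive`.
#' @return Integer vector of recommended arms (0 = NSM, 1 = MRM).
#' @export
nccn_recommend <- function(data) {
  need <- c("grade", "her2_positive", "n_stage", "aln_positive")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste("nccn_recommend: missing field(s):",
                paste(miss, collapse = ", ")))
  }
  if (anyNA(data[need])) abort("nccn_recommend: missing values in rule fields")
  nsm <- data$grade %in% c("I", "II") | data$her2_positive == 0 |
    data$n_stage == "N0" | data$aln_positive == 0
  as.integer(!nsm)
}

#' @export
recommend.bime_nccn <- function(object, data, threshold = 0.10, cap = 120,
                                ...) {
  rec <- nccn_recommend(data)
  out <- new_recs(curve_ids(data), rep(NA_real_, nrow(data)),
                  rep(NA_real_, nrow(data)),
                  received = if ("treatment" %in% names(data))
                    data$treatment else NULL)
  out$ite <- NA_real_
  out$recommended <- rec
  out$consis <- if ("treatment" %in% names(data)) {
    as.integer(rec == data$treatment)
  } else NA_integer_
  out
}

#' Ground-truth oracle model for simulated cohorts
#'
#' Wraps the generating truth of [generate_cohort()] in the common model
#' interface: `recommend()` uses the true per-arm times-at-risk and
#' `predict_survival()` the closed-form Weibull curves. Used as a positive
#' control in evaluation tests.
#'
#' @param sim A `bime_sim`.
#' @return An object of class `bime_oracle`.
#' @export
make_oracle <- function(sim) {
  stopifnot(inherits(sim, "bime_sim"))
  structure(list(truth = sim$truth, treatment = "treatment"),
            class = "bime_oracle")
}

#' @export
recommend.bime_oracle <- function(object, data, threshold = 0.10,
                                  cap = 120, ...) {
  tt <- true_tar_ite(object$truth, data$patient_id, threshold, cap)
  new_recs(data$patient_id, tt$tar_nsm, tt$tar_mrm,
           received = if ("treatment" %in% names(data)) data$treatment
           else NULL)
}

#' @export
predict_survival.bime_oracle <- function(object, data, arm, times = NULL,
                                         ...) {
  if (is.null(times)) times <- seq(0, 120, by = 1)
  check_grid(times)
  tv <- true_survival(object$truth, data$patient_id, arm, times)
  S <- matrix(tv$surv, nrow = nrow(data), byrow = TRUE)
  as_curves(S, times, data$patient_id, arm)
}

#' Build a comparator model specification
#'
#' Returns a model object with the common `fit_model()` / `recommend()`
#' interface. Deep variants are constrained mixture configurations:
#' `"deepsurv"` forces K = 1, alpha = 0 and per-arm encoders; `"bites"`
#' forces K = 1 with a shared, transport-balanced encoder; `"cph"` is the
#' linear Cox T-learner; `"nccn"` is the guideline rule (no fitting).
#' `"rsf"` (random survival forest) is a declared external plug-in and
#' raises a not-implemented error.
#'
#' @param name One of `"cph"`, `"deepsurv"`, `"bites"`, `"nccn"`, `"bime"`.
#' @param control A [bime_control()] whose non-constrained settings carry
#'   over to the deep variants.
#' @return An object of class `bime_baseline`.
#' @export
make_baseline <- function(name, control = bime_control()) {
  if (identical(name, "rsf")) {
    abort(paste("random survival forest is not implemented in-package;",
                "fit one externally and evaluate it through the common",
                "recommend() interface"))
  }
  name <- match.arg(name, c("cph", "deepsurv", "bites", "nccn", "bime"))
  ctrl <- control
  if (name == "deepsurv") {
    ctrl$k <- 1; ctrl$alpha <- 0; ctrl$share_encoder <- FALSE
  } else if (name == "bites") {
    ctrl$k <- 1
    if (ctrl$alpha <= 0) ctrl$alpha <- 1
    ctrl$share_encoder <- TRUE
  }
  structure(list(name = name, control = ctrl), class = "bime_baseline")
}

#' Fit a model specification
#'
#' @param spec A `bime_baseline` from [make_baseline()].
#' @inheritParams bime_fit
#' @return A fitted model with `recommend()` (and, except for the NCCN
#'   rule, `predict_survival()`) methods.
#' @export
fit_model <- function(spec, data, covariates = default_covariates(),
                      time = "followup_months", event = "event_overall",
                      treatment = "treatment") {
  stopifnot(inherits(spec, "bime_baseline"))
  switch(spec$name,
    nccn = structure(list(treatment = treatment), class = "bime_nccn"),
    cph = fit_tlearner_cph(data, covariates, time, event, treatment),
    bime = ,
    deepsurv = ,
    bites = bime_fit(data, covariates, time, event, treatment,
                     control = spec$control))
}
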