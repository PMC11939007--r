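# Prediction surface of the fitted mixture: latent encodings, per-arm
# mixture log-hazards, survival curves, time-at-risk, and treatment
# recommendations (the T-learner contrast of per-arm times-at-risk).

#' Latent representation of patients under a fitted model
#'
#' Deterministic (dropout-free) encoder output for each row of `data`.
#'
#' @param object A [bime_fit()].
#' @param data Data frame with the model's covariates; if the treatment
#'   column is present and the model uses per-arm encoders, each row is
#'   encoded by its own arm's encoder.
#' @return A tibble of latent coordinates (`phi1`, `phi2`, ...).
#' @export
encode <- function(object, data) {
  stopifnot(inherits(object, "bime_fit"))
  X <- design_matrix(data, object$covariates, object$design_stats)$X
  Phi <- encode_matrix(object, X, data)
  colnames(Phi) <- paste0("phi", seq_len(ncol(Phi)))
  as_tibble(Phi)
}

encode_matrix <- function(object, X, data = NULL) {
  st <- object$state
  if (st$shared) {
    nn_forward(st$net, X)$out
  } else {
    arm <- if (!is.null(data) && object$treatment %in% names(data)) {
      data[[object$treatment]]
    } else rep(0, nrow(X))
    Phi <- matrix(0, nrow(X), object$control$latent_dim)
    r0 <- arm == 0; r1 <- arm == 1
    if (any(r0)) Phi[r0, ] <- nn_forward(st$net0, X[r0, , drop = FALSE])$out
    if (any(r1)) Phi[r1, ] <- nn_forward(st$net1, X[r1, , drop = FALSE])$out
    Phi
  }
}

arm_encode <- function(object, X, arm) {
  st <- object$state
  if (st$shared) nn_forward(st$net, X)$out
  else nn_forward(if (arm == 0) st$net0 else st$net1, X)$out
}

#' Mixture log-hazard components for one arm
#'
#' Returns the marginal log-hazard `eta = log sum_k g_k exp(f_k)` together
#' with per-component log-hazards and gate probabilities.
#'
#' @inheritParams encode
#' @param arm Treatment arm: 0 (NSM) or 1 (MRM).
#' @return A tibble with `eta` plus `f1..fK` and `gate1..gateK`.
#' @export
mixture_log_hazard <- function(object, data, arm) {
  stopifnot(inherits(object, "bime_fit"), arm %in% c(0, 1))
  X <- design_matrix(data, object$covariates, object$design_stats)$X
  Phi <- arm_encode(object, X, arm)
  hf <- head_forward(object$state$heads[[arm + 1L]], Phi)
  K <- ncol(hf$f)
  out <- tibble(eta = hf$eta)
  for (k in seq_len(K)) out[[paste0("f", k)]] <- hf$f[, k]
  for (k in seq_len(K)) out[[paste0("gate", k)]] <- hf$g[, k]
  out
}

default_time_grid <- function(object, arm = NULL, cap = 120) {
  arms <- if (is.null(arm)) 1:2 else arm + 1L
  ts <- unlist(lapply(object$baselines[arms],
                      function(bs) lapply(bs, function(b) b$time)))
  ts <- sort(unique(c(0, ts[ts <= cap], cap)))
  ts
}

# survival matrix (patients x times) for one arm
predict_surv_matrix <- function(object, X, arm, times) {
  Phi <- arm_encode(object, X, arm)
  hf <- head_forward(object$state$heads[[arm + 1L]], Phi)
  K <- ncol(hf$f)
  bs <- object$baselines[[arm + 1L]]
  S <- matrix(0, nrow(X), length(times))
  for (k in seq_len(K)) {
    Lk <- eval_cumhaz(bs[[k]], times)                 # length(times)
    S <- S + hf$g[, k] * exp(-outer(exp(hf$f[, k]), Lk))
  }
  S
}

#' Predicted survival curves
#'
#' Mixture survival `S(t | x, arm) = sum_k g_k exp(-Lambda_k(t) e^{f_k})`
#' under a fitted model. The curve starts at `S(0) = 1` and is
#' nonincreasing; beyond the last training event time it is flat.
#'
#' @param object A fitted model ([bime_fit()], [fit_tlearner_cph()] or an
#'   oracle from [make_oracle()]).
#' @param data Data frame of patients.
#' @param arm Treatment arm: 0 (NSM) or 1 (MRM).
#' @param times Ascending time grid starting at 0; default: the arm's
#'   training event times.
#' @param ... Passed to methods.
#' @return A tibble with `patient_id` (row number if absent), `arm`,
#'   `time`, `surv`, of class `bime_curves`.
#' @export
predict_survival <- function(object, data, arm, times = NULL, ...) {
  UseMethod("predict_survival")
}

check_grid <- function(times) {
  if (is.unsorted(times, strictly = FALSE) || times[1] != 0) {
    abort("predict_survival: `times` must be ascending and start at 0")
  }
  times
}

as_curves <- function(S, times, ids, arm) {
  out <- tibble(
    patient_id = rep(ids, each = length(times)),
    arm = arm,
    time = rep(times, length(ids)),
    surv = as.vector(t(S)))
  class(out) <- unique(c("bime_curves", class(out)))
  out
}

curve_ids <- function(data) {
  if ("patient_id" %in% names(data)) as.character(data$patient_id)
  else as.character(seq_len(nrow(data)))
}

#' @export
predict_survival.bime_fit <- function(object, data, arm, times = NULL, ...) {
  if (!arm %in% c(0, 1)) abort("predict_survival: arm must be 0 or 1")
  if (is.null(times)) times <- default_time_grid(object, arm)
  check_grid(times)
  X <- design_matrix(data, object$covariates, object$design_stats)$X
  S <- predict_surv_matrix(object, X, arm, times)
  stopifnot(all(diff(t(S)) <= 1e-12))   # nonincreasing in t, every call
  as_curves(S, times, curve_ids(data), arm)
}

# first time S(t) <= threshold with linear interpolation; cap when the
# curve stays above threshold on [0, cap]
tar_from_matrix <- function(S, times, threshold, cap) {
  keep <- times <= cap
  S <- S[, keep, drop = FALSE]
  times <- times[keep]
  apply(cbind(S), 1, function(s) {
    j <- which(s <= threshold)[1]
    if (is.na(j)) return(cap)
    if (j == 1) return(times[1])
    t0 <- times[j - 1]; t1 <- times[j]
    s0 <- s[j - 1]; s1 <- s[j]
    if (s0 == s1) return(t1)
    min(t0 + (s0 - threshold) / (s0 - s1) * (t1 - t0), cap)
  })
}

#' Time at risk of a survival curve
#'
#' First time the survival function falls to `threshold` (default 0.10,
#' i.e. 90% mortality), linearly interpolated between grid points and
#' capped at `cap` months when the curve never reaches the threshold
#' within the horizon (censored-at-cap convention).
#'
#' @param curve A tibble with `time` and `surv` columns (one curve), e.g.
#'   one patient's rows of [predict_survival()] output or a [km_curve()].
#' @param threshold Survival level (0 < threshold < 1).
#' @param cap Horizon in months.
#' @param interpolate Linearly interpolate between grid points (default;
#'   suits smooth model curves). With `FALSE` — or automatically for
#'   [km_curve()] input — the curve is treated as a right-continuous step
#'   function and the first grid time with `S <= threshold` is returned.
#' @return Time in months.
#' @export
time_at_risk <- function(curve, threshold = 0.10, cap = 120,
                         interpolate = !inherits(curve, "bime_km")) {
  stopifnot(threshold > 0, threshold < 1)
  ord <- order(curve$time)
  t <- curve$time[ord]; s <- curve$surv[ord]
  if (!interpolate) {
    j <- which(s <= threshold & t <= cap)[1]
    return(if (is.na(j)) cap else t[j])
  }
  tar_from_matrix(matrix(s, nrow = 1), t, threshold, cap)
}

#' Treatment recommendations from a fitted model
#'
#' Computes, per patient, the time-at-risk under each arm, their
#' difference (the individual treatment effect, in months), the
#' recommended arm (MRM when the effect is positive, NSM otherwise — ties
#' go to the less invasive NSM), and, when the received treatment is
#' available, the concordance flag `consis`.
#'
#' @param object A fitted model.
#' @param data Data frame of patients.
#' @param threshold Survival level defining time-at-risk.
#' @param cap Horizon cap (months).
#' @param ... Passed to methods.
#' @return A tibble of class `bime_recs`: `patient_id`, `tar_nsm`,
#'   `tar_mrm`, `ite`, `recommended`, and `consis` (NA without received
#'   treatment).
#' @export
recommend <- function(object, data, threshold = 0.10, cap = 120, ...) {
  UseMethod("recommend")
}

new_recs <- function(ids, tar_nsm, tar_mrm, received = NULL) {
  ite <- tar_mrm - tar_nsm
  recommended <- as.integer(ite > 0)
  consis <- if (is.null(received)) NA_integer_ else
    as.integer(recommended == received)
  out <- tibble(patient_id = ids, tar_nsm = tar_nsm, tar_mrm = tar_mrm,
                ite = ite, recommended = recommended, consis = consis)
  class(out) <- unique(c("bime_recs", class(out)))
  out
}

#' @export
recommend.bime_fit <- function(object, data, threshold = 0.10, cap = 120,
                               ...) {
  X <- design_matrix(data, object$covariates, object$design_stats)$X
  t0 <- default_time_grid(object, 0, cap)
  t1 <- default_time_grid(object, 1, cap)
  S0 <- predict_surv_matrix(object, X, 0, t0)
  S1 <- predict_surv_matrix(object, X, 1, t1)
  new_recs(curve_ids(data),
           tar_from_matrix(S0, t0, threshold, cap),
           tar_from_matrix(S1, t1, threshold, cap),
           received = if (object$treatment %in% names(data))
             data[[object$treatment]] else NULL)
}

#' Export a recommendation set as CSV
#'
#' @param recs A `bime_recs` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recommendations <- function(recs, path) {
  readr::write_csv(recs, path, progress = FALSE)
  invisible(path)
}
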