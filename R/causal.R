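# Recommendation-evaluation framework: propensity scores, inverse
# probability of treatment weighting, 1:1 nearest-neighbor matching,
# standardized-mean-difference balance diagnostics, (weighted) Kaplan-Meier
# and log-rank, restricted mean survival time, risk differences, weighted
# Cox hazard ratios with sandwich CIs, IPCW integrated Brier scores, and
# the Consis/Inconsis metrics report.

#' Fit a propensity model
#'
#' Maximum-likelihood logistic regression of a binary indicator on an
#' adjustment covariate set; scores are clipped to `[0.01, 0.99]`.
#'
#' @param data Data frame.
#' @param indicator Column name of the binary exposure/group indicator, or
#'   a 0/1 vector of length `nrow(data)`.
#' @param covariates Adjustment covariates; default
#'   [default_adjustment_covariates()].
#' @return An object of class `bime_propensity` with `coef`, `score`
#'   (clipped), `indicator`.
#' @export
fit_propensity <- function(data, indicator = "treatment",
                           covariates = default_adjustment_covariates()) {
  g <- if (is.character(indicator) && length(indicator) == 1) {
    data[[indicator]]
  } else indicator
  if (is.null(g) || !is_flag01(g)) {
    abort("fit_propensity: indicator must be 0/1")
  }
  if (length(unique(g)) < 2) {
    abort("fit_propensity: both indicator levels must be present")
  }
  X <- design_matrix(data, covariates)$X
  fit <- suppressWarnings(glm.fit(cbind(`(Intercept)` = 1, X), g,
                                  family = binomial()))
  cf <- fit$coefficients
  # a vanishing deviance means the indicator is perfectly predicted
  if (fit$deviance < 1e-6) {
    worst <- names(cf[-1])[which.max(abs(cf[-1]))]
    abort(paste0("fit_propensity: perfect separation on '", worst, "'"))
  }
  score <- clip(fit$fitted.values, 0.01, 0.99)
  structure(list(coef = cf, score = score, indicator = g,
                 covariates = covariates),
            class = "bime_propensity")
}

#' @importFrom stats glm.fit
NULL

#' @rdname fit_propensity
#' @param x A `bime_propensity`.
#' @param ... Unused.
#' @export
tidy.bime_propensity <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' Inverse-probability-of-treatment weights
#'
#' Unstabilized weights are `1/e` for the indicated group and `1/(1 - e)`
#' otherwise; stabilized weights multiply by the marginal prevalence of
#' the subject's own group, so they average about 1 per group.
#'
#' @param fit A [fit_propensity()] object.
#' @param stabilized Logical (default `TRUE`).
#' @param truncate Optional quantile (e.g. 0.99) at which the weights are
#'   symmetrically truncated.
#' @return Numeric weight vector.
#' @export
iptw_weights <- function(fit, stabilized = TRUE, truncate = NULL) {
  stopifnot(inherits(fit, "bime_propensity"))
  g <- fit$indicator
  e <- fit$score
  w <- ifelse(g == 1, 1 / e, 1 / (1 - e))
  if (stabilized) {
    pbar <- mean(g)
    w <- w * ifelse(g == 1, pbar, 1 - pbar)
  }
  if (!is.null(truncate)) {
    bounds <- quantile(w, c(1 - truncate, truncate))
    w <- clip(w, bounds[1], bounds[2])
  }
  w
}

#' 1:1 propensity-score matching
#'
#' Greedy nearest-neighbor matching without replacement on the logit
#' propensity scale. The smaller group is processed in descending
#' propensity order (ties broken by position) and each member takes its
#' nearest unused counterpart; with a `caliper`, pairs farther apart than
#' `caliper` standard deviations of the logit score are rejected.
#'
#' @param fit A [fit_propensity()] object.
#' @param caliper Optional caliper in SDs of the logit score.
#' @return A tibble of class `bime_match` with `index_1`, `index_0` (row
#'   indices of the indicated and reference group) and `distance`.
#' @export
psm_match <- function(fit, caliper = NULL) {
  stopifnot(inherits(fit, "bime_propensity"))
  lp <- qlogis(fit$score)
  i1 <- which(fit$indicator == 1)
  i0 <- which(fit$indicator == 0)
  if (length(i1) == 0 || length(i0) == 0) {
    abort("psm_match: both groups must be present")
  }
  cal <- if (is.null(caliper)) Inf else caliper * sd(lp)
  small_is_1 <- length(i1) <= length(i0)
  from <- if (small_is_1) i1 else i0
  pool <- if (small_is_1) i0 else i1
  from <- from[order(-lp[from], from)]
  used <- rep(FALSE, length(pool))
  res <- vector("list", length(from))
  for (j in seq_along(from)) {
    d <- abs(lp[pool] - lp[from[j]])
    d[used] <- Inf
    k <- which.min(d)
    if (is.finite(d[k]) && d[k] <= cal) {
      used[k] <- TRUE
      res[[j]] <- c(from[j], pool[k], d[k])
    }
  }
  res <- do.call(rbind, res)
  if (is.null(res)) abort("psm_match: no matches under the caliper")
  out <- tibble(index_1 = as.integer(if (small_is_1) res[, 1] else res[, 2]),
                index_0 = as.integer(if (small_is_1) res[, 2] else res[, 1]),
                distance = res[, 3])
  attr(out, "caliper") <- caliper
  class(out) <- unique(c("bime_match", class(out)))
  out
}

#' Standardized mean difference
#'
#' `|mean1 - mean0| / sqrt((var1 + var0) / 2)`, optionally with weighted
#' moments. Returns 0 with a warning when the pooled variance is zero.
#'
#' @param x Numeric (or 0/1) variable.
#' @param group 0/1 grouping vector.
#' @param weights Optional nonnegative weights.
#' @return The SMD (nonnegative scalar).
#' @export
smd <- function(x, group, weights = NULL) {
  stopifnot(is.numeric(x), all(group %in% c(0, 1)))
  w <- if (is.null(weights)) rep(1, length(x)) else weights
  mom <- function(g) {
    ww <- w[group == g]; xx <- x[group == g]
    m <- weighted.mean(xx, ww)
    v <- sum(ww * (xx - m)^2) / sum(ww)
    c(m, v)
  }
  m1 <- mom(1); m0 <- mom(0)
  pooled <- (m1[2] + m0[2]) / 2
  if (pooled <= 0) {
    warn("smd: zero pooled variance; returning 0")
    return(0)
  }
  abs(m1[1] - m0[1]) / sqrt(pooled)
}

#' Covariate balance table
#'
#' SMD of every column of the design matrix of `covariates`, unweighted
#' and (optionally) weighted.
#'
#' @param data Data frame.
#' @param group 0/1 group indicator (vector or column name).
#' @param covariates Covariate set.
#' @param weights Optional weights for the adjusted column.
#' @return A tibble with `term`, `smd` and, with weights, `smd_adj`.
#' @export
balance_table <- function(data, group = "treatment",
                          covariates = default_adjustment_covariates(),
                          weights = NULL) {
  g <- if (is.character(group) && length(group) == 1) data[[group]] else group
  X <- design_matrix(data, covariates)$X
  out <- tibble(term = colnames(X),
                smd = apply(X, 2, smd, group = g))
  if (!is.null(weights)) {
    out$smd_adj <- apply(X, 2, smd, group = g, weights = weights)
  }
  out
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with optional case weights (weighted risk and
#' event counts).
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @param weights Optional nonnegative weights.
#' @return A tibble of class `bime_km`: `time` (0 and the event times),
#'   `n_risk`, `n_event`, `surv`.
#' @export
km_curve <- function(times, events, weights = NULL) {
  if (length(times) == 0) abort("km_curve: empty input")
  stopifnot(all(times > 0), all(events %in% c(0, 1)))
  w <- if (is.null(weights)) rep(1, length(times)) else weights
  ut <- sort(unique(times[events == 1 & w > 0]))
  if (length(ut) == 0) {
    return(structure(tibble(time = 0, n_risk = sum(w), n_event = 0,
                            surv = 1),
                     class = c("bime_km", class(tibble()))))
  }
  n_risk <- vapply(ut, function(t) sum(w[times >= t]), numeric(1))
  n_event <- vapply(ut, function(t) sum(w[times == t & events == 1]),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- tibble(time = c(0, ut), n_risk = c(sum(w), n_risk),
                n_event = c(0, n_event), surv = c(1, surv))
  class(out) <- unique(c("bime_km", class(out)))
  out
}

# evaluate a right-continuous step curve (tibble time/surv) at times t,
# flat beyond the last point
surv_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  c(1, curve$surv)[idx + 1L]
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank chi-square, with optional case
#' weights (weighted risk/event counts).
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @param group 0/1 group labels.
#' @param weights Optional weights.
#' @return A tibble with `statistic`, `df`, `p_value`, `observed1`,
#'   `expected1`.
#' @export
logrank_test <- function(times, events, group, weights = NULL) {
  stopifnot(all(group %in% c(0, 1)))
  if (length(unique(group)) < 2) abort("logrank_test: need two groups")
  if (sum(events) < 1) abort("logrank_test: need at least one event")
  w <- if (is.null(weights)) rep(1, length(times)) else weights
  ut <- sort(unique(times[events == 1 & w > 0]))
  O1 <- E1 <- V <- 0
  for (t in ut) {
    at_risk <- times >= t
    n <- sum(w[at_risk])
    n1 <- sum(w[at_risk & group == 1])
    d <- sum(w[times == t & events == 1])
    d1 <- sum(w[times == t & events == 1 & group == 1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) {
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  stat <- if (V > 0) (O1 - E1)^2 / V else 0
  tibble(statistic = stat, df = 1,
         p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
         observed1 = O1, expected1 = E1)
}

#' Restricted mean survival time
#'
#' Area under a survival curve on `[0, tau]`. `method = "step"` (default)
#' integrates the curve as a right-continuous step function — exact for
#' Kaplan-Meier input; `"trapezoid"` suits smooth model curves on a fine
#' grid. Beyond the last grid point the curve is extrapolated flat, with a
#' warning.
#'
#' @param curve A tibble with `time` and `surv` (e.g. [km_curve()] or one
#'   patient's [predict_survival()] rows).
#' @param tau Horizon (months), > 0.
#' @param method `"step"` or `"trapezoid"`.
#' @return Months (scalar in `[0, tau]`).
#' @export
rmst <- function(curve, tau, method = c("step", "trapezoid")) {
  method <- match.arg(method)
  stopifnot(tau > 0)
  ord <- order(curve$time)
  t <- curve$time[ord]; s <- curve$surv[ord]
  if (t[1] > 0) { t <- c(0, t); s <- c(1, s) }
  if (max(t) < tau) {
    warn(sprintf("rmst: tau = %g beyond last grid point %g; flat extrapolation",
                 tau, max(t)),
         .frequency = "once", .frequency_id = "bime_rmst_flat")
    t <- c(t, tau); s <- c(s, s[length(s)])
  }
  keep <- t <= tau
  t2 <- c(t[keep], tau)
  s2 <- c(s[keep], s[sum(keep)])
  if (method == "step") {
    sum(diff(t2) * s2[-length(s2)])
  } else {
    sum(diff(t2) * (s2[-1] + s2[-length(s2)]) / 2)
  }
}

#' Survival risk difference at a horizon
#'
#' `100 * (S_A(tau) - S_B(tau))` in percentage points; by convention A is
#' the Consis (recommendation-concordant) curve, so positive values are
#' protective.
#'
#' @param curve_a,curve_b Survival curves (tibbles with `time`, `surv`).
#' @param tau Horizon (months).
#' @return Percentage points in `[-100, 100]`.
#' @export
risk_difference <- function(curve_a, curve_b, tau) {
  100 * (surv_at(curve_a, tau) - surv_at(curve_b, tau))
}

#' (Weighted) Cox hazard ratio for a group indicator
#'
#' In-package Newton-Raphson Cox fit of the indicator plus adjustment
#' covariates; with weights, the weighted partial likelihood is used and
#' the CI comes from the robust sandwich variance.
#'
#' @param data Data frame.
#' @param indicator 0/1 group indicator (vector or column name). The
#'   reported HR is for `indicator = 1` relative to `indicator = 0`.
#' @param covariates Adjustment covariates (`NULL` for unadjusted).
#' @param weights Optional case weights.
#' @param time,event Column names of follow-up and event.
#' @param level Confidence level.
#' @return A one-row tibble: `hr`, `lower`, `upper`, `coef`, `se`,
#'   `robust`.
#' @export
cox_hr <- function(data, indicator, covariates = NULL, weights = NULL,
                   time = "followup_months", event = "event_overall",
                   level = 0.95) {
  g <- if (is.character(indicator) && length(indicator) == 1) {
    data[[indicator]]
  } else indicator
  stopifnot(all(g %in% c(0, 1)))
  X <- cbind(.group = g)
  if (!is.null(covariates) && length(covariates) > 0) {
    X <- cbind(X, design_matrix(data, covariates)$X)
  }
  robust <- !is.null(weights)
  fit <- coxph_breslow(X, data[[time]], data[[event]], weights = weights,
                       robust = robust, diverge = "drop")
  V <- if (robust) fit$robust_vcov else fit$vcov
  i <- match(".group", names(fit$coef))
  if (is.na(i)) abort("cox_hr: indicator constant after exclusions")
  se <- sqrt(V[i, i])
  z <- qnorm(1 - (1 - level) / 2)
  tibble(hr = exp(fit$coef[i]),
         lower = exp(fit$coef[i] - z * se),
         upper = exp(fit$coef[i] + z * se),
         coef = unname(fit$coef[i]), se = se, robust = robust)
}

#' Integrated Brier score with IPCW
#'
#' Squared error of predicted survival probabilities, weighted by the
#' inverse probability of censoring (Kaplan-Meier of the censoring
#' distribution), integrated over `[0, tau]` by the trapezoid rule and
#' divided by `tau`.
#'
#' @param curves A `bime_curves` tibble of predicted survival for the same
#'   subjects (ids must match one curve per subject).
#' @param times Observed follow-up times, in the order of the distinct
#'   subjects of `curves`.
#' @param events 0/1 event indicators.
#' @param tau Integration horizon.
#' @return The integrated Brier score (scalar).
#' @export
integrated_brier <- function(curves, times, events, tau) {
  ids <- unique(curves$patient_id)
  n <- length(ids)
  stopifnot(length(times) == n, length(events) == n)
  grid <- sort(unique(curves$time))
  grid <- grid[grid <= tau]
  if (max(grid) < tau) grid <- c(grid, tau)
  # predicted survival matrix n x grid (flat step extrapolation)
  S <- matrix(NA_real_, n, length(grid))
  sp <- split(seq_len(nrow(curves)), factor(curves$patient_id, levels = ids))
  for (i in seq_len(n)) {
    rows <- sp[[i]]
    cv <- curves[rows, ]
    ord <- order(cv$time)
    S[i, ] <- surv_at(tibble(time = cv$time[ord], surv = cv$surv[ord]), grid)
  }
  # censoring distribution: K-M of the censoring indicator
  Gkm <- km_curve(times, 1 - events)
  G_at <- function(t) pmax(surv_at(Gkm, t), 1e-12)
  Gt <- surv_at(Gkm, grid)
  if (any(Gt <= 0)) {
    warn("integrated_brier: censoring survival reaches 0 inside the grid; truncating",
         .frequency = "once", .frequency_id = "bime_ibs_truncate")
    grid <- grid[Gt > 0]
    S <- S[, Gt > 0, drop = FALSE]
    Gt <- Gt[Gt > 0]
  }
  Gminus <- G_at(times - 1e-9)
  bs <- vapply(seq_along(grid), function(j) {
    t <- grid[j]
    died <- times <= t & events == 1
    alive <- times > t
    mean(S[, j]^2 * died / Gminus + (1 - S[, j])^2 * alive / Gt[j])
  }, numeric(1))
  sum(diff(grid) * (bs[-1] + bs[-length(bs)]) / 2) / max(grid)
}

#' Evaluate a model's treatment recommendations
#'
#' Stratifies patients by concordance between the received and recommended
#' arm (Consis vs Inconsis) and reports the Table-2-style metric set: Cox
#' hazard ratio (Consis relative to Inconsis, so HR < 1 is protective),
#' survival risk difference and restricted-mean-survival-time difference
#' at the horizon — each raw and IPTW-adjusted — plus IPCW integrated
#' Brier scores per treatment arm. RD and dRMST CIs are nonparametric
#' bootstrap; HR CIs are model-based (robust sandwich under weights).
#'
#' @param model A fitted model with a [recommend()] method (and optionally
#'   [predict_survival()], for the Brier scores). May be `NULL` when
#'   `recs` is supplied.
#' @param data The evaluation cohort (disjoint from training).
#' @param adjust_covariates Covariates for the propensity/adjustment set.
#' @param tau Horizon in months (default 120).
#' @param threshold,cap Time-at-risk parameters passed to [recommend()].
#' @param n_boot Bootstrap resamples for RD/dRMST CIs.
#' @param seed Bootstrap seed.
#' @param recs Optional precomputed recommendation tibble (must contain
#'   `recommended`; `consis` is recomputed against `data`).
#' @param level Confidence level.
#' @return An object of class `bime_metrics`; `tidy()` returns the metric
#'   table.
#' @export
evaluate_recommendation <- function(model, data,
                                    adjust_covariates =
                                      default_adjustment_covariates(),
                                    tau = 120, threshold = 0.10, cap = 120,
                                    n_boot = 500, seed = 1, recs = NULL,
                                    level = 0.95) {
  if (is.null(recs)) recs <- recommend(model, data, threshold, cap)
  stopifnot(nrow(recs) == nrow(data))
  consis <- as.integer(recs$recommended == data$treatment)
  if (sum(consis) == 0) abort("evaluate_recommendation: Consis group empty")
  if (sum(1 - consis) == 0) {
    abort("evaluate_recommendation: Inconsis group empty")
  }
  tt <- data$followup_months; ev <- data$event_overall
  z <- qnorm(1 - (1 - level) / 2)

  ps <- fit_propensity(data, consis, adjust_covariates)
  wts <- iptw_weights(ps, stabilized = TRUE)

  km_pair <- function(w = NULL) {
    list(c1 = km_curve(tt[consis == 1], ev[consis == 1],
                       if (is.null(w)) NULL else w[consis == 1]),
         c0 = km_curve(tt[consis == 0], ev[consis == 0],
                       if (is.null(w)) NULL else w[consis == 0]))
  }
  pair_raw <- km_pair()
  pair_adj <- km_pair(wts)
  rd_raw <- risk_difference(pair_raw$c1, pair_raw$c0, tau)
  rd_adj <- risk_difference(pair_adj$c1, pair_adj$c0, tau)
  drmst_raw <- rmst(pair_raw$c1, tau) - rmst(pair_raw$c0, tau)
  drmst_adj <- rmst(pair_adj$c1, tau) - rmst(pair_adj$c0, tau)

  hr_raw <- cox_hr(data, consis, adjust_covariates, level = level)
  hr_adj <- cox_hr(data, consis, adjust_covariates, weights = wts,
                   level = level)

  # joint bootstrap for RD / dRMST CIs (propensity refit per resample)
  boot <- with_seed(substream_seed(seed, "evalboot"), {
    replicate(n_boot, {
      idx <- sample.int(nrow(data), replace = TRUE)
      cs <- consis[idx]
      if (sum(cs) < 2 || sum(1 - cs) < 2) return(rep(NA_real_, 4))
      w_b <- tryCatch(
        iptw_weights(fit_propensity(data[idx, ], cs, adjust_covariates)),
        error = function(e) rep(1, length(idx)))
      t_b <- tt[idx]; e_b <- ev[idx]
      k1 <- km_curve(t_b[cs == 1], e_b[cs == 1])
      k0 <- km_curve(t_b[cs == 0], e_b[cs == 0])
      k1w <- km_curve(t_b[cs == 1], e_b[cs == 1], w_b[cs == 1])
      k0w <- km_curve(t_b[cs == 0], e_b[cs == 0], w_b[cs == 0])
      c(risk_difference(k1, k0, tau),
        risk_difference(k1w, k0w, tau),
        rmst(k1, tau) - rmst(k0, tau),
        rmst(k1w, tau) - rmst(k0w, tau))
    })
  })
  qs <- apply(boot, 1, quantile, probs = c((1 - level) / 2,
                                           1 - (1 - level) / 2),
              na.rm = TRUE)

  # IBS per received-treatment arm, when the model predicts curves
  ibs <- c(nsm = NA_real_, mrm = NA_real_)
  if (!is.null(model) && inherits(model, c("bime_fit", "bime_cph",
                                           "bime_oracle"))) {
    for (a in 0:1) {
      idx <- which(data$treatment == a)
      if (length(idx) == 0) next
      cv <- predict_survival(model, data[idx, ], arm = a)
      ibs[a + 1L] <- integrated_brier(cv, tt[idx], ev[idx], tau)
    }
  }

  metrics <- tibble(
    metric = c("hr", "hr_adj", "rd", "rd_adj", "drmst", "drmst_adj",
               "ibs_nsm", "ibs_mrm"),
    estimate = c(hr_raw$hr, hr_adj$hr, rd_raw, rd_adj, drmst_raw,
                 drmst_adj, ibs[1], ibs[2]),
    lower = c(hr_raw$lower, hr_adj$lower, qs[1, 1], qs[1, 2], qs[1, 3],
              qs[1, 4], NA, NA),
    upper = c(hr_raw$upper, hr_adj$upper, qs[2, 1], qs[2, 2], qs[2, 3],
              qs[2, 4], NA, NA))

  structure(list(metrics = metrics, tau = tau, level = level,
                 n_consis = sum(consis), n_inconsis = sum(1 - consis),
                 consis = consis, weights = wts, propensity = ps,
                 recs = recs, n_boot = n_boot, seed = seed),
            class = "bime_metrics")
}

#' @export
print.bime_metrics <- function(x, ...) {
  cat(sprintf(
    "Recommendation evaluation (tau = %g months): %d Consis / %d Inconsis\n",
    x$tau, x$n_consis, x$n_inconsis))
  print(x$metrics)
  invisible(x)
}

#' @rdname evaluate_recommendation
#' @param x A `bime_metrics`.
#' @param ... Unused.
#' @export
tidy.bime_metrics <- function(x, ...) x$metrics

#' @rdname evaluate_recommendation
#' @export
glance.bime_metrics <- function(x, ...) {
  tibble(n.consis = x$n_consis, n.inconsis = x$n_inconsis, tau = x$tau,
         n.boot = x$n_boot, level = x$level)
}

#' Export a metrics report
#'
#' Writes the metric table as JSON and, optionally, a wide CSV shaped like
#' a model-performance table row.
#'
#' @param x A `bime_metrics`.
#' @param path JSON output path.
#' @param csv Optional CSV output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(x, path, csv = NULL) {
  stopifnot(inherits(x, "bime_metrics"))
  jsonlite::write_json(
    list(tau = x$tau, n_consis = x$n_consis, n_inconsis = x$n_inconsis,
         metrics = x$metrics),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv)) {
    wide <- tidyr::pivot_wider(x$metrics, names_from = "metric",
                               values_from = c("estimate", "lower", "upper"))
    readr::write_csv(wide, csv, progress = FALSE)
  }
  invisible(path)
}
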