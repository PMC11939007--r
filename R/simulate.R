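# Synthetic SEER-like breast-cancer cohorts with known ground truth.
#
# The generator emulates the structure an observational mastectomy cohort
# needs for treatment-effect work: confounded assignment to NSM (T = 0) or
# MRM (T = 1), right-censored overall and cause-specific survival, and
# latent-subgroup treatment-effect heterogeneity. Event times are Weibull
# per latent subgroup and arm, so each arm violates proportional hazards
# marginally while satisfying it within a subgroup — the setting a Cox
# mixture targets.

default_weibull_components <- function() {
  list(
    list(nsm = c(shape = 1.3, scale = 100), mrm = c(shape = 1.1, scale = 35)),
    list(nsm = c(shape = 1.1, scale = 35), mrm = c(shape = 1.3, scale = 100))
  )
}

#' Simulation configuration
#'
#' Builds the configuration for [generate_cohort()]. The defaults define the
#' package's "strong heterogeneity" scenario: n = 4000 patients, two latent
#' subgroups (60/40) with opposite arm benefits, confounded treatment
#' assignment, and roughly one-third censoring over a 120-month horizon.
#'
#' @param n Number of patients (>= 10).
#' @param seed Master seed; all random draws derive from it.
#' @param k_true Number of latent subgroups.
#' @param subgroup_probs Target marginal subgroup proportions (simplex).
#' @param weibull List of length `k_true`; element k is
#'   `list(nsm = c(shape, scale), mrm = c(shape, scale))` in months.
#' @param beta_hazard Named numeric vector of covariate effects on the
#'   log-hazard (shared by arms and subgroups). Names refer to the internal
#'   simulation design columns.
#' @param treat_coef Named numeric vector of treatment-assignment log-odds
#'   coefficients (MRM = 1); the intercept is calibrated so that the mean
#'   assignment probability equals `treated_frac`.
#' @param treated_frac Target marginal fraction assigned to MRM.
#' @param subgroup_coef Named numeric vector driving latent subgroup
#'   membership (log-odds of subgroup 2 for `k_true = 2`); intercept
#'   calibrated against `subgroup_probs`.
#' @param censor_horizon Administrative censoring time (months).
#' @param censor_rate Rate of the independent exponential censoring time.
#' @param nst_effect List with `assign` (log-odds shift of MRM assignment
#'   for NST recipients) and `log_hazard_mrm` (log hazard multiplier that
#'   NST adds in the MRM arm only).
#' @param bcss_prob Probability that a death is breast-cancer-specific.
#' @return A list of class `bime_sim_config`.
#' @export
sim_config <- function(n = 4000, seed = 1, k_true = 2,
                       subgroup_probs = c(0.6, 0.4),
                       weibull = default_weibull_components(),
                       beta_hazard = c(age_z = 0.30, size_z = 0.25,
                                       aln = 0.40, grade3 = 0.30,
                                       m1 = 0.80, er = -0.30),
                       treat_coef = c(age_z = 0.50, size_z = 0.60,
                                      aln = 0.90, grade3 = 0.30,
                                      her2 = 0.20),
                       treated_frac = 0.55,
                       subgroup_coef = c(age_z = 12, size_z = 12,
                                         her2 = 9, grade3 = 6,
                                         aln = 4.5, er = -4.5),
                       censor_horizon = 120, censor_rate = 1 / 130,
                       nst_effect = list(assign = -0.3, log_hazard_mrm = 0.35),
                       bcss_prob = 0.72) {
  if (n < 10) abort("sim_config: n must be >= 10 (degenerate cohort)")
  stopifnot(abs(sum(subgroup_probs) - 1) < 1e-8, length(weibull) == k_true,
            length(subgroup_probs) == k_true,
            censor_horizon > 0, censor_rate >= 0)
  for (w in weibull) {
    stopifnot(all(w$nsm > 0), all(w$mrm > 0))
  }
  structure(list(n = n, seed = seed, k_true = k_true,
                 subgroup_probs = subgroup_probs, weibull = weibull,
                 beta_hazard = beta_hazard, treat_coef = treat_coef,
                 treated_frac = treated_frac, subgroup_coef = subgroup_coef,
                 censor_horizon = censor_horizon, censor_rate = censor_rate,
                 nst_effect = nst_effect, bcss_prob = bcss_prob),
            class = "bime_sim_config")
}

# calibrate an intercept b so that mean(plogis(score + b)) = target
calibrate_intercept <- function(score, target) {
  f <- function(b) mean(plogis(score + b)) - target
  stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
}

# AJCC-7-style stage from T/N/M (IB handled as a small slice of T1N0)
tnm_from_tn <- function(t_stage, n_stage, m_stage, ib_draw) {
  dplyr::case_when(
    m_stage == "M1" ~ "IV",
    n_stage == "N3" ~ "IIIC",
    t_stage == "T4" ~ "IIIB",
    n_stage == "N2" ~ "IIIA",
    t_stage == "T3" & n_stage == "N1" ~ "IIIA",
    t_stage == "T3" & n_stage == "N0" ~ "IIB",
    t_stage == "T2" & n_stage == "N1" ~ "IIB",
    t_stage == "T2" & n_stage == "N0" ~ "IIA",
    t_stage == "T1" & n_stage == "N1" ~ "IIA",
    ib_draw ~ "IB",
    TRUE ~ "IA"
  )
}

# internal design columns used by the generative model
sim_design <- function(d) {
  cbind(age_z = (d$age - 56) / 13,
        size_z = (log(d$tumor_size) - log(28)) / 0.55,
        aln = d$aln_positive,
        grade3 = as.numeric(d$grade %in% c("III", "IV")),
        her2 = d$her2_positive,
        er = d$er_positive,
        m1 = as.numeric(d$m_stage == "M1"))
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws covariates from documented marginals, assigns each patient a
#' latent subgroup (covariate-driven), a confounded treatment arm, and a
#' right-censored Weibull event time per the configured per-subgroup,
#' per-arm components. Returns both the observable cohort table and the
#' generating truth (latent subgroup, propensity, per-arm survival
#' parameters, true time-at-risk and individual treatment effect).
#'
#' @param config A [sim_config()].
#' @param tar_threshold Survival level defining time-at-risk (default 0.10,
#'   i.e. 90% mortality).
#' @param tar_cap Horizon (months) at which time-at-risk is capped.
#' @return A list of class `bime_sim` with elements `cohort` (validated
#'   cohort tibble) and `truth` (tibble; one row per patient).
#' @export
generate_cohort <- function(config = sim_config(), tar_threshold = 0.10,
                            tar_cap = 120) {
  stopifnot(inherits(config, "bime_sim_config"))
  n <- config$n

  d <- with_seed(substream_seed(config$seed, "covariates"), {
    age <- clip(rnorm(n, 56, 13), 20, 95)
    tumor_size <- clip(exp(rnorm(n, log(28), 0.55)), 1, 150)
    married <- rbinom(n, 1, 0.56)
    race <- sample(cohort_levels$race, n, TRUE, prob = c(0.76, 0.12, 0.12))
    income_high <- rbinom(n, 1, 0.32)
    grade <- sample(cohort_levels$grade, n, TRUE,
                    prob = c(0.12, 0.42, 0.455, 0.005))
    location <- sample(cohort_levels$location, n, TRUE,
                       prob = c(0.32, 0.09, 0.07, 0.04, 0.29, 0.01, 0.18))
    t_stage <- ifelse(tumor_size <= 20, "T1",
                      ifelse(tumor_size <= 50, "T2", "T3"))
    t_stage[runif(n) < 0.05] <- "T4"
    size_sc <- (tumor_size - 30) / 30
    n_logits <- cbind(0.0 - 0.5 * size_sc, 0.31 + 0.1 * size_sc,
                      -0.6 + 0.25 * size_sc, -1.1 + 0.35 * size_sc)
    n_probs <- exp(n_logits) / rowSums(exp(n_logits))
    n_stage <- cohort_levels$n_stage[
      vapply(seq_len(n), function(i) sample.int(4, 1, prob = n_probs[i, ]),
             integer(1))]
    m_stage <- ifelse(runif(n) < 0.03 + 0.05 * (n_stage == "N3"), "M1", "M0")
    ib_draw <- runif(n) < 0.05
    tnm_stage <- tnm_from_tn(t_stage, n_stage, m_stage, ib_draw)
    aln_positive <- as.numeric(n_stage != "N0")
    aln_positive[aln_positive == 0] <- rbinom(sum(aln_positive == 0), 1, 0.05)
    er_positive <- rbinom(n, 1, 0.78)
    pr_positive <- rbinom(n, 1, plogis(qlogis(0.66) + 1.2 * (er_positive - 0.5)))
    her2_positive <- rbinom(n, 1, 0.21)
    nst <- rbinom(n, 1, plogis(-1.4 + 0.8 * (n_stage != "N0") +
                                 0.5 * (t_stage %in% c("T3", "T4"))))
    tibble(patient_id = sprintf("P%05d", seq_len(n)),
           age, tumor_size, married, race, income_high, grade, location,
           t_stage, n_stage, m_stage, tnm_stage,
           iib_t3n0 = as.numeric(tnm_stage == "IIB" & t_stage == "T3" &
                                   n_stage == "N0"),
           aln_positive, er_positive, pr_positive, her2_positive, nst)
  })

  X <- sim_design(d)

  # latent subgroup: covariate-driven, intercept calibrated to the target
  # marginal proportions (two subgroups; additional subgroups split the
  # remainder uniformly at random)
  z <- with_seed(substream_seed(config$seed, "subgroup"), {
    sc <- drop(X[, names(config$subgroup_coef), drop = FALSE] %*%
                 config$subgroup_coef)
    if (config$k_true == 1) {
      rep(1L, n)
    } else {
      b <- calibrate_intercept(sc, sum(config$subgroup_probs[-1]))
      p2 <- plogis(sc + b)
      z2 <- rbinom(n, 1, p2)
      if (config$k_true == 2) {
        z2 + 1L
      } else {
        out <- rep(1L, n)
        rest <- config$subgroup_probs[-1] / sum(config$subgroup_probs[-1])
        out[z2 == 1] <- 1L + sample.int(config$k_true - 1, sum(z2 == 1),
                                        TRUE, prob = rest)
        out
      }
    }
  })

  # confounded treatment assignment (T = 1 is MRM)
  trt <- with_seed(substream_seed(config$seed, "treatment"), {
    sc <- drop(X[, names(config$treat_coef), drop = FALSE] %*%
                 config$treat_coef) + config$nst_effect$assign * d$nst
    b <- calibrate_intercept(sc, config$treated_frac)
    e <- plogis(sc + b)
    list(propensity = e, treatment = rbinom(n, 1, e))
  })

  # per-patient effective Weibull parameters per arm: covariate effects act
  # as a proportional-hazards multiplier exp(beta'x), i.e. scale divided by
  # exp(beta'x / shape); NST multiplies the MRM-arm hazard
  bx <- drop(X[, names(config$beta_hazard), drop = FALSE] %*%
               config$beta_hazard)
  shp <- matrix(NA_real_, n, 2)  # cols: arm 0 (NSM), arm 1 (MRM)
  scl <- matrix(NA_real_, n, 2)
  for (k in seq_len(config$k_true)) {
    idx <- z == k
    w <- config$weibull[[k]]
    shp[idx, 1] <- w$nsm["shape"]; shp[idx, 2] <- w$mrm["shape"]
    scl[idx, 1] <- w$nsm["scale"] / exp(bx[idx] / w$nsm["shape"])
    scl[idx, 2] <- w$mrm["scale"] /
      exp((bx[idx] + config$nst_effect$log_hazard_mrm * d$nst[idx]) /
            w$mrm["shape"])
  }

  obs <- with_seed(substream_seed(config$seed, "outcome"), {
    arm_col <- trt$treatment + 1L
    tt <- rweibull(n, shape = shp[cbind(seq_len(n), arm_col)],
                   scale = scl[cbind(seq_len(n), arm_col)])
    cens <- if (config$censor_rate > 0) rexp(n, config$censor_rate) else
      rep(Inf, n)
    cens <- pmin(cens, config$censor_horizon)
    event <- as.numeric(tt <= cens)
    followup <- pmax(pmin(tt, cens), 1 / 30)  # at least one day
    bcss <- event * rbinom(n, 1, config$bcss_prob)
    tibble(followup_months = followup, event_overall = event,
           event_bcss = bcss)
  })

  cohort <- validate_cohort(dplyr::bind_cols(
    d, tibble(treatment = trt$treatment), obs
  )[, cohort_columns()])

  tar <- function(arm) {
    pmin(scl[, arm + 1L] * (-log(tar_threshold))^(1 / shp[, arm + 1L]),
         tar_cap)
  }
  tar0 <- tar(0); tar1 <- tar(1)
  truth <- tibble(
    patient_id = d$patient_id, subgroup = z,
    propensity = trt$propensity,
    shape_nsm = shp[, 1], scale_nsm = scl[, 1],
    shape_mrm = shp[, 2], scale_mrm = scl[, 2],
    tar_nsm = tar0, tar_mrm = tar1,
    ite = tar1 - tar0,
    recommended = as.integer(tar1 - tar0 > 0)  # 1 = MRM better
  )

  structure(list(cohort = cohort, truth = truth, config = config,
                 tar_threshold = tar_threshold, tar_cap = tar_cap),
            class = "bime_sim")
}

#' True survival function of simulated patients
#'
#' Closed-form Weibull survival for given patients under a chosen arm,
#' conditional on their (known) latent subgroup.
#'
#' @param sim A `bime_sim` from [generate_cohort()], or its `truth` tibble.
#' @param patient_id Character vector of patient ids.
#' @param arm 0 (NSM) or 1 (MRM).
#' @param times Numeric vector of times (months, >= 0).
#' @return A tibble with columns `patient_id`, `time`, `surv`.
#' @export
true_survival <- function(sim, patient_id, arm, times) {
  truth <- if (inherits(sim, "bime_sim")) sim$truth else sim
  stopifnot(arm %in% c(0, 1), all(times >= 0))
  ix <- match(patient_id, truth$patient_id)
  if (anyNA(ix)) abort("true_survival: unknown patient_id")
  shape <- if (arm == 0) truth$shape_nsm[ix] else truth$shape_mrm[ix]
  scale <- if (arm == 0) truth$scale_nsm[ix] else truth$scale_mrm[ix]
  tidyr::crossing(i = seq_along(ix), time = times) |>
    dplyr::mutate(patient_id = patient_id[.data$i],
                  surv = exp(-(.data$time / scale[.data$i])^shape[.data$i])) |>
    dplyr::select("patient_id", "time", "surv")
}

#' True time-at-risk and individual treatment effect
#'
#' Inverts the closed-form per-arm survival at the configured threshold and
#' caps at the horizon; the individual treatment effect is
#' `TaR(MRM) - TaR(NSM)` in months.
#'
#' @inheritParams true_survival
#' @param threshold Survival level defining time-at-risk.
#' @param cap Horizon cap in months.
#' @return A tibble with `patient_id`, `tar_mrm`, `tar_nsm`, `ite`.
#' @export
true_tar_ite <- function(sim, patient_id = NULL, threshold = 0.10,
                         cap = 120) {
  stopifnot(threshold > 0, threshold < 1)
  truth <- if (inherits(sim, "bime_sim")) sim$truth else sim
  if (is.null(patient_id)) patient_id <- truth$patient_id
  ix <- match(patient_id, truth$patient_id)
  if (anyNA(ix)) abort("true_tar_ite: unknown patient_id")
  q <- (-log(threshold))
  tar_nsm <- pmin(truth$scale_nsm[ix] * q^(1 / truth$shape_nsm[ix]), cap)
  tar_mrm <- pmin(truth$scale_mrm[ix] * q^(1 / truth$shape_mrm[ix]), cap)
  tibble(patient_id = patient_id, tar_mrm = tar_mrm, tar_nsm = tar_nsm,
         ite = tar_mrm - tar_nsm)
}

#' Write the pieces of a simulated cohort to disk
#'
#' @param sim A `bime_sim`.
#' @param dir Output directory (created if needed); writes `cohort.csv`,
#'   `truth.csv` and `sim_config.yaml`.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "bime_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(sim$cohort, file.path(dir, "cohort.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"), progress = FALSE)
  cfg <- unclass(sim$config)
  cfg$weibull <- lapply(cfg$weibull, function(w) lapply(w, as.list))
  yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
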