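make_two_group_cohort <- function(n_per_arm = 2000, seed = 1) {
  # one binary covariate doubling the hazard; exponential event times,
  # no censoring
  withr::with_seed(seed, {
    x <- rbinom(2 * n_per_arm, 1, 0.5)
    arm <- rep(0:1, each = n_per_arm)
    rate <- ifelse(x == 1, 0.04, 0.02)
    tibble::tibble(
      patient_id = sprintf("A%05d", seq_len(2 * n_per_arm)),
      xbin = x, treatment = arm,
      followup_months = rexp(2 * n_per_arm, rate) + 1e-3,
      event_overall = 1L)
  })
}

test_that("the Cox T-learner recovers a known log-hazard ratio", {
  d <- make_two_group_cohort()
  fit <- fit_tlearner_cph(d, covariates = "xbin")
  for (a in 1:2) {
    expect_lt(abs(fit$fits[[a]]$coef[["xbin"]] - log(2)), 0.1)
  }
  # and matches a brute-force maximizer on the same data
  idx <- which(d$treatment == 0)[1:50]
  brute <- brute_cox_fit(cbind(d$xbin[idx]), d$followup_months[idx],
                         d$event_overall[idx])
  small <- coxph_breslow(cbind(xbin = d$xbin[idx]),
                         d$followup_months[idx], d$event_overall[idx])
  expect_lt(abs(small$coef - brute), 1e-6)
})

test_that("degenerate and permuted designs behave predictably", {
  d <- make_two_group_cohort(150, seed = 2)
  d$flat <- 1
  expect_warning(fit <- fit_tlearner_cph(d, covariates = c("xbin", "flat")),
                 "constant column")
  expect_false("flat" %in% names(fit$fits[[1]]$coef))
  pm <- sample(nrow(d))
  f1 <- fit_tlearner_cph(d, covariates = "xbin")
  f2 <- fit_tlearner_cph(d[pm, ], covariates = "xbin")
  expect_lt(abs(f1$fits[[1]]$coef - f2$fits[[1]]$coef), 1e-8)
  expect_error(fit_tlearner_cph(d[d$treatment == 0, ], covariates = "xbin"),
               "both treatment arms")
})

test_that("T-learner predictions flow through the shared survival path", {
  d <- make_two_group_cohort(400, seed = 3)
  fit <- fit_tlearner_cph(d, covariates = "xbin")
  cv <- predict_survival(fit, d[1:4, ], arm = 0)
  expect_true(all(cv$surv[cv$time == 0] == 1))
  one <- cv[cv$patient_id == cv$patient_id[1], ]
  expect_true(all(diff(one$surv) <= 1e-12))
  r <- recommend(fit, d[1:10, ])
  expect_named(r, c("patient_id", "tar_nsm", "tar_mrm", "ite",
                    "recommended", "consis"))
})

test_that("baseline specs apply the documented constraints", {
  b <- make_baseline("deepsurv")
  expect_equal(b$control$k, 1)
  expect_equal(b$control$alpha, 0)
  expect_false(b$control$share_encoder)
  b2 <- make_baseline("bites")
  expect_equal(b2$control$k, 1)
  expect_gt(b2$control$alpha, 0)
  expect_true(b2$control$share_encoder)
  expect_error(make_baseline("rsf"), "not implemented")
  expect_error(make_baseline("what"))
})

test_that("the NCCN rule reads as a disjunction of printed criteria", {
  d <- tibble::tibble(
    grade = c("II", "III", "IV", "III"),
    her2_positive = c(1, 1, 0, 1),
    n_stage = c("N1", "N1", "N2", "N0"),
    aln_positive = c(1, 1, 1, 1))
  # grade criterion; none; HER2 criterion; N0 criterion
  expect_equal(nccn_recommend(d), c(0L, 1L, 0L, 0L))
  expect_error(nccn_recommend(d[, -1]), "missing field")
  model <- fit_model(make_baseline("nccn"), d)
  d$treatment <- c(0, 0, 1, 1)
  r <- recommend(model, d)
  expect_equal(r$recommended, c(0L, 1L, 0L, 0L))
  expect_equal(r$consis, c(1L, 0L, 0L, 0L))
  expect_named(r, c("patient_id", "tar_nsm", "tar_mrm", "ite",
                    "recommended", "consis"))
})

test_that("the oracle model reproduces the generating truth", {
  sim <- generate_cohort(sim_config(n = 200, seed = 12))
  oracle <- make_oracle(sim)
  r <- recommend(oracle, sim$cohort)
  expect_equal(r$ite, sim$truth$ite)
  expect_equal(r$recommended, as.integer(sim$truth$ite > 0))
  cv <- predict_survival(oracle, sim$cohort[3, ], arm = 1,
                         times = c(0, 24, 60))
  tv <- true_survival(sim, sim$cohort$patient_id[3], 1, c(0, 24, 60))
  expect_equal(cv$surv, tv$surv)
})
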