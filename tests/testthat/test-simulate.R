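test_that("generation is reproducible and validates its own output", {
  cfg <- sim_config(n = 300, seed = 9)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$truth, s2$truth)
  expect_s3_class(s1$cohort, "bime_cohort")
  expect_error(sim_config(n = 5), "degenerate")
})

test_that("unconfounded assignment hits the target treated fraction", {
  cfg <- sim_config(n = 4000, seed = 21,
                    treat_coef = c(age_z = 0, size_z = 0, aln = 0,
                                   grade3 = 0, her2 = 0),
                    nst_effect = list(assign = 0, log_hazard_mrm = 0),
                    treated_frac = 0.35)
  sim <- generate_cohort(cfg)
  mc_se <- sqrt(0.35 * 0.65 / 4000)
  expect_lt(abs(mean(sim$cohort$treatment) - 0.35), 3 * mc_se)
  expect_equal(unique(round(sim$truth$propensity, 10)), 0.35)
})

test_that("the default scenario is confounded (some SMD above 0.1)", {
  sim <- generate_cohort(sim_config(n = 2000, seed = 4))
  bt <- balance_table(sim$cohort, covariates = default_covariates())
  expect_gt(max(bt$smd), 0.1)
  # and the treated fraction matches the mean true propensity within MC error
  expect_lt(abs(mean(sim$cohort$treatment) - mean(sim$truth$propensity)),
            3 * sqrt(0.25 / 2000))
})

test_that("true survival has its closed forms", {
  sim <- generate_cohort(sim_config(n = 50, seed = 3))
  ids <- sim$truth$patient_id[1:4]
  s0 <- true_survival(sim, ids, arm = 0, times = 0)
  expect_equal(s0$surv, rep(1, 4))
  # exponential case: shape 1 -> S(t) = exp(-t / scale)
  cfg <- sim_config(n = 20, seed = 5, k_true = 1, subgroup_probs = 1,
                    weibull = list(list(nsm = c(shape = 1, scale = 80),
                                        mrm = c(shape = 1, scale = 40))),
                    beta_hazard = c(age_z = 0, size_z = 0, aln = 0,
                                    grade3 = 0, m1 = 0, er = 0),
                    nst_effect = list(assign = 0, log_hazard_mrm = 0))
  se <- generate_cohort(cfg)
  sv <- true_survival(se, se$truth$patient_id[1], 0, c(0, 40, 80, 4000))
  expect_equal(sv$surv, exp(-c(0, 40, 80, 4000) / 80))
  expect_lt(sv$surv[4], 1e-20)
  expect_error(true_survival(se, "nope", 0, 1), "unknown patient")
})

test_that("true time-at-risk inverts the survival function and caps", {
  # exponential with S(120) = 0.10 => scale = 120 / log(10)
  sc <- 120 / log(10)
  cfg <- sim_config(n = 20, seed = 5, k_true = 1, subgroup_probs = 1,
                    weibull = list(list(nsm = c(shape = 1, scale = sc),
                                        mrm = c(shape = 1, scale = sc))),
                    beta_hazard = c(age_z = 0, size_z = 0, aln = 0,
                                    grade3 = 0, m1 = 0, er = 0),
                    nst_effect = list(assign = 0, log_hazard_mrm = 0))
  se <- generate_cohort(cfg)
  tt <- true_tar_ite(se, threshold = 0.10, cap = 240)
  expect_equal(tt$tar_nsm, rep(120, 20))
  expect_equal(tt$ite, rep(0, 20))        # identical arms -> zero effect
  # curves above threshold before the cap return the cap
  tt2 <- true_tar_ite(se, threshold = 0.10, cap = 60)
  expect_equal(tt2$tar_mrm, rep(60, 20))
  # invariant: ite recomputes exactly from the per-arm times
  sim <- generate_cohort(sim_config(n = 500, seed = 6))
  expect_equal(sim$truth$ite, sim$truth$tar_mrm - sim$truth$tar_nsm)
})

test_that("pooled Kaplan-Meier converges to the average true survival", {
  cfg <- sim_config(n = 20000, seed = 13, censor_rate = 0,
                    censor_horizon = 1e6)
  sim <- generate_cohort(cfg)
  co <- sim$cohort
  grid <- seq(1, 360, by = 3)
  for (a in 0:1) {
    idx <- which(co$treatment == a)
    km <- km_curve(co$followup_months[idx], co$event_overall[idx])
    km_s <- sapply(grid, function(t) {
      i <- findInterval(t, km$time); c(1, km$surv)[i + 1]
    })
    truth <- sim$truth[match(co$patient_id[idx], sim$truth$patient_id), ]
    shape <- if (a == 0) truth$shape_nsm else truth$shape_mrm
    scale <- if (a == 0) truth$scale_nsm else truth$scale_mrm
    true_s <- sapply(grid, function(t) mean(exp(-(t / scale)^shape)))
    expect_lt(max(abs(km_s - true_s)), 0.02)
  }
})

test_that("the default scenario has opposite-benefit subgroups", {
  sim <- generate_cohort(sim_config(n = 4000, seed = 8))
  ite <- sim$truth$ite
  z <- sim$truth$subgroup
  expect_gt(mean(ite[z == 2] > 0), 0.9)
  expect_gt(mean(ite[z == 1] < 0), 0.9)
  # both modes carry substantial mass (bimodal treatment-effect law)
  expect_gt(mean(ite > 10), 0.25)
  expect_gt(mean(ite < -10), 0.35)
})

test_that("simulated artifacts round-trip through disk", {
  sim <- generate_cohort(sim_config(n = 60, seed = 2))
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  back <- read_cohort(file.path(dir, "cohort.csv"))
  expect_equal(nrow(back), 60)
  cfg <- yaml::read_yaml(file.path(dir, "sim_config.yaml"))
  expect_equal(cfg$n, 60)
  expect_equal(cfg$seed, 2)
})
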