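test_that("propensity scores recover simple closed forms", {
  # indicator independent of covariates: scores ~ group prevalence
  set.seed(1)
  d <- tibble::tibble(age = rnorm(800, 50, 10), xb = rbinom(800, 1, 0.5),
                      g = rbinom(800, 1, 0.3))
  ps <- fit_propensity(d, "g", covariates = c("age", "xb"))
  se <- sqrt(0.3 * 0.7 / 800)
  expect_lt(abs(mean(ps$score) - mean(d$g)), 1e-6)  # logistic MLE property
  expect_lt(abs(mean(ps$score) - 0.3), 3 * se)
  # hand-computable 2x2 instance: logit of cell proportions
  d2 <- tibble::tibble(x = c(0, 0, 0, 0, 1, 1, 1, 1),
                       g = c(0, 0, 0, 1, 0, 1, 1, 1))
  ps2 <- fit_propensity(d2, "g", covariates = "x")
  expect_equal(unname(ps2$coef[1]), qlogis(1 / 4), tolerance = 1e-6)
  expect_equal(unname(ps2$coef[2]), qlogis(3 / 4) - qlogis(1 / 4),
               tolerance = 1e-6)
  # duplicated rows get identical scores
  d3 <- d2[c(1, 1, 5, 5, 4, 8), ]
  ps3 <- fit_propensity(d3, "g", covariates = "x")
  expect_equal(ps3$score[1], ps3$score[2])
  # perfect separation is refused with the covariate named
  d4 <- tibble::tibble(x = c(rep(0, 20), rep(1, 20)),
                       g = c(rep(0, 20), rep(1, 20)))
  expect_error(fit_propensity(d4, "g", covariates = "x"), "separation")
})

test_that("IPTW weights follow the inverse-propensity arithmetic", {
  set.seed(2)
  d <- tibble::tibble(x = rnorm(400), g = rbinom(400, 1, 0.5))
  ps <- fit_propensity(d, "g", covariates = "x")
  # all scores 0.5 -> unstabilized weights all 2
  ps5 <- ps; ps5$score <- rep(0.5, 400)
  expect_equal(iptw_weights(ps5, stabilized = FALSE), rep(2, 400))
  # score 0.8, indicator 1 -> 1.25
  ps8 <- ps; ps8$score <- rep(0.8, 400); ps8$indicator <- rep(1L, 400)
  expect_equal(iptw_weights(ps8, stabilized = FALSE), rep(1.25, 400))
  # stabilized weights sum to about n
  w <- iptw_weights(ps, stabilized = TRUE)
  expect_lt(abs(sum(w) - 400) / 400, 0.05)
  expect_true(all(is.finite(w)) && all(w > 0))
})

test_that("greedy 1:1 matching is deterministic and respects calipers", {
  mk <- function(s1, s0) {
    f <- list(score = c(s1, s0),
              indicator = c(rep(1L, length(s1)), rep(0L, length(s0))),
              coef = c(0), covariates = character(0))
    class(f) <- "bime_propensity"
    f
  }
  # scores {0.2, 0.9} vs {0.25, 0.5}: 0.9 matches 0.5, then 0.2 <-> 0.25
  m <- psm_match(mk(c(0.2, 0.9), c(0.25, 0.5)))
  pairs <- m[order(m$index_1), ]
  expect_equal(pairs$index_1, c(1L, 2L))
  expect_equal(pairs$index_0, c(3L, 4L))
  # identical distributions, equal sizes -> everyone matched, zero distance
  m2 <- psm_match(mk(c(0.3, 0.6, 0.8), c(0.3, 0.6, 0.8)))
  expect_equal(nrow(m2), 3)
  expect_equal(max(m2$distance), 0)
  expect_false(any(duplicated(m2$index_0)))
  # disjoint ranges under a tight caliper
  expect_error(psm_match(mk(c(0.9, 0.95), c(0.05, 0.1)), caliper = 0.01),
               "no matches")
})

test_that("standardized mean differences follow the pooled-variance formula", {
  g <- c(rep(1, 100), rep(0, 100))
  x <- c(rep(1, 60), rep(0, 40), rep(1, 40), rep(0, 60))
  expect_equal(smd(x, g), 0.2 / sqrt((0.24 + 0.24) / 2), tolerance = 1e-12)
  expect_equal(smd(rep(c(1, 0), 100), rep(c(1, 0), 100)), 0)
  expect_warning(v <- smd(rep(2, 200), g), "zero pooled variance")
  expect_equal(v, 0)
  # weights that equalize the means drive the SMD to ~0
  w <- ifelse(g == 1, ifelse(x == 1, 2 / 3, 3 / 2), 1)
  expect_lt(smd(x, g, weights = w), 1e-10)
})

test_that("Kaplan-Meier matches the hand product-limit and survfit", {
  k <- km_curve(c(2, 3, 3, 5), c(1, 1, 0, 1))
  expect_equal(k$time, c(0, 2, 3, 5))
  expect_equal(k$surv, c(1, 0.75, 0.5, 0))
  # all censored -> flat at 1
  expect_equal(km_curve(c(1, 5, 9), c(0, 0, 0))$surv, 1)
  # unit weights equal unweighted (to numerical identity)
  set.seed(3)
  tt <- rexp(60, 0.1) + 0.1; ev <- rbinom(60, 1, 0.6)
  expect_equal(km_curve(tt, ev), km_curve(tt, ev, weights = rep(1, 60)),
               tolerance = 1e-12)
  sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  k2 <- km_curve(tt, ev)
  expect_equal(k2$surv[-1], sf$surv[sf$n.event > 0], tolerance = 1e-12)
})

test_that("the log-rank test matches hand computation and survdiff", {
  # six-subject worked instance
  tt <- c(1, 2, 3, 4, 5, 6); ev <- c(1, 1, 1, 0, 1, 1)
  g <- c(1, 0, 1, 0, 0, 1)
  lr <- logrank_test(tt, ev, g)
  sd_ <- survival::survdiff(survival::Surv(tt, ev) ~ g)
  expect_equal(lr$statistic, sd_$chisq, tolerance = 1e-10)
  expect_equal(lr$observed1, sd_$obs[2])
  expect_equal(lr$expected1, sd_$exp[2], tolerance = 1e-10)
  # identical groups duplicated -> statistic 0, p = 1
  lr0 <- logrank_test(c(tt, tt), c(ev, ev), rep(c(0, 1), each = 6))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)
  # label swap leaves the statistic unchanged
  expect_equal(logrank_test(tt, ev, 1 - g)$statistic, lr$statistic,
               tolerance = 1e-12)
  expect_error(logrank_test(tt, ev, rep(1, 6)), "two groups")
})

test_that("restricted mean survival integrates steps exactly", {
  k <- km_curve(c(2, 3, 3, 5), c(1, 1, 0, 1))
  expect_equal(rmst(k, 5), 2 * 1 + 1 * 0.75 + 2 * 0.5)
  flat <- tibble::tibble(time = c(0, 10), surv = c(1, 1))
  expect_equal(rmst(flat, 7), 7)
  # exponential closed form on a fine grid (trapezoid)
  lam <- 0.05
  tg <- seq(0, 80, by = 0.01)
  cv <- tibble::tibble(time = tg, surv = exp(-lam * tg))
  expect_equal(rmst(cv, 60, method = "trapezoid"),
               (1 - exp(-lam * 60)) / lam, tolerance = 1e-6)
  # additivity of the step integral
  expect_equal(rmst(k, 3) + (rmst(k, 5) - rmst(k, 3)), rmst(k, 5))
  rlang::reset_warning_verbosity("bime_rmst_flat")  # warning is once-per-session
  expect_warning(rmst(k, 50), "flat extrapolation")
})

test_that("risk differences are bounded percentage-point contrasts", {
  a <- tibble::tibble(time = c(0, 50), surv = c(1, 0.8))
  b <- tibble::tibble(time = c(0, 50), surv = c(1, 0.6))
  expect_equal(risk_difference(a, b, 60), 20)
  expect_equal(risk_difference(a, a, 60), 0)
  worst <- tibble::tibble(time = 0, surv = 1)
  dead <- tibble::tibble(time = c(0, 1), surv = c(1, 0))
  expect_equal(risk_difference(worst, dead, 10), 100)
  expect_equal(risk_difference(dead, worst, 10), -100)
})

test_that("hazard-ratio estimation is symmetric and oracle-exact", {
  set.seed(5)
  n <- 50
  d <- tibble::tibble(followup_months = rexp(n, 0.05) + 0.01,
                      event_overall = rbinom(n, 1, 0.8),
                      g = rbinom(n, 1, 0.5))
  hr <- cox_hr(d, "g")
  brute <- brute_cox_fit(cbind(d$g), d$followup_months, d$event_overall)
  expect_lt(abs(hr$coef - brute), 1e-6)
  hr_sw <- cox_hr(d, 1 - d$g)
  expect_equal(hr_sw$hr, 1 / hr$hr, tolerance = 1e-8)
  expect_true(hr$lower < hr$hr & hr$hr < hr$upper)
  # unit weights equal the unweighted estimator (robust variance aside)
  hr_w <- cox_hr(d, "g", weights = rep(1, n))
  expect_equal(hr_w$coef, hr$coef, tolerance = 1e-10)
})

test_that("the integrated Brier score matches hand-computed IPCW sums", {
  # perfect prediction, no censoring -> 0
  tt <- c(2, 4, 6); ev <- c(1, 1, 1)
  grid <- seq(0, 8, by = 0.5)
  perfect <- purrr::map_dfr(1:3, function(i) {
    tibble::tibble(patient_id = as.character(i), arm = 0, time = grid,
                   surv = as.numeric(grid < tt[i]))
  })
  class(perfect) <- c("bime_curves", class(perfect))
  expect_equal(integrated_brier(perfect, tt, ev, 8), 0)
  # constant 0.5, no censoring -> 0.25
  const <- perfect; const$surv <- 0.5
  expect_equal(integrated_brier(const, tt, ev, 8), 0.25)
  # five-subject censored toy against an independent loop
  tt5 <- c(1, 2, 3, 4, 5); ev5 <- c(1, 0, 1, 0, 1)
  g5 <- seq(0, 5, by = 0.25)
  set.seed(6)
  cv5 <- purrr::map_dfr(1:5, function(i) {
    tibble::tibble(patient_id = as.character(i), arm = 0, time = g5,
                   surv = exp(-0.2 * i / 3 * g5))
  })
  class(cv5) <- c("bime_curves", class(cv5))
  ibs <- integrated_brier(cv5, tt5, ev5, 5)
  # oracle: direct double loop over grid and subjects
  km_c <- km_curve(tt5, 1 - ev5)
  Gfun <- function(t) {
    i <- findInterval(t, km_c$time); max(c(1, km_c$surv)[i + 1], 1e-12)
  }
  bs <- sapply(g5, function(t) {
    mean(sapply(1:5, function(i) {
      S <- exp(-0.2 * i / 3 * t)
      if (tt5[i] <= t && ev5[i] == 1) S^2 / Gfun(tt5[i] - 1e-9)
      else if (tt5[i] > t) (1 - S)^2 / Gfun(t)
      else 0
    }))
  })
  oracle <- sum(diff(g5) * (bs[-1] + bs[-length(bs)]) / 2) / 5
  expect_equal(ibs, oracle, tolerance = 1e-12)
})

test_that("IPTW balances the confounded synthetic scenario", {
  # median over 5 seeds: max SMD > 0.1 before weighting, < 0.1 after
  res <- sapply(1:5, function(s) {
    sim <- generate_cohort(sim_config(n = 2000, seed = 200 + s))
    ps <- fit_propensity(sim$cohort, "treatment")
    w <- iptw_weights(ps)
    bt <- balance_table(sim$cohort, "treatment", weights = w)
    c(before = max(bt$smd), after = max(bt$smd_adj))
  })
  expect_gt(median(res["before", ]), 0.1)
  expect_lt(median(res["after", ]), 0.1)
})

test_that("recommendation evaluation recovers the oracle's benefit", {
  sim <- generate_cohort(sim_config(n = 1500, seed = 44))
  oracle <- make_oracle(sim)
  m <- evaluate_recommendation(oracle, sim$cohort, n_boot = 100, seed = 1)
  tab <- tidy(m)
  expect_gt(tab$estimate[tab$metric == "rd_adj"], 0)
  expect_lt(tab$estimate[tab$metric == "hr_adj"], 1)
  expect_true(all(c("ibs_nsm", "ibs_mrm") %in% tab$metric))
  expect_lt(tab$estimate[tab$metric == "ibs_nsm"], 0.25)
  # CIs contain their point estimates
  ok <- !is.na(tab$lower)
  expect_true(all(tab$lower[ok] <= tab$estimate[ok] + 1e-9))
  expect_true(all(tab$estimate[ok] <= tab$upper[ok] + 1e-9))
  # a model recommending everyone's received arm leaves Inconsis empty
  everyone <- sim$cohort
  recs_all <- recommend(oracle, everyone)
  recs_all$recommended <- everyone$treatment
  expect_error(evaluate_recommendation(NULL, everyone, recs = recs_all),
               "Inconsis")
})

test_that("bootstrap confidence intervals are reproducible under a seed", {
  sim <- generate_cohort(sim_config(n = 600, seed = 45))
  oracle <- make_oracle(sim)
  m1 <- evaluate_recommendation(oracle, sim$cohort, n_boot = 50, seed = 9)
  m2 <- evaluate_recommendation(oracle, sim$cohort, n_boot = 50, seed = 9)
  expect_identical(tidy(m1), tidy(m2))
})
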