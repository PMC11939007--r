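two_col_stats <- function() {
  list(center = c(age = 0, tumor_size = 0),
       scale = c(age = 1, tumor_size = 1),
       columns = c("age", "tumor_size"),
       covariates = c("age", "tumor_size"))
}

exp_baseline <- function(rate, times = seq(0.5, 400, by = 0.5)) {
  tibble::tibble(time = times, dhaz = c(rate * times[1], rate * diff(times)),
                 cumhaz = rate * times)
}

test_that("an identity encoder reproduces the standardized covariates", {
  heads <- list(bime:::new_heads(2, 1), bime:::new_heads(2, 1))
  m <- manual_bime(2, 2, heads, list(list(exp_baseline(0.01)),
                                     list(exp_baseline(0.01))),
                   c("age", "tumor_size"), two_col_stats(), k = 1)
  d <- tibble::tibble(age = c(1.5, -0.3, 1.5), tumor_size = c(0.2, 1, 0.9))
  phi <- encode(m, d)
  expect_equal(unname(as.matrix(phi)), unname(as.matrix(d)))
  # identical rows -> identical embeddings; permutation equivariance
  expect_equal(phi[1, ], phi[1, ])
  pm <- c(2, 3, 1)
  expect_equal(as.matrix(encode(m, d[pm, ])), as.matrix(phi)[pm, ],
               ignore_attr = TRUE)
})

test_that("mixture log-hazard follows the gated log-sum-exp arithmetic", {
  # hand-set gates (0.3, 0.7) and components f = (0, 1)
  heads <- list(
    list(Wg = matrix(0, 2, 2), bg = log(c(0.3, 0.7)),
         Wf = matrix(0, 2, 2), bf = c(0, 1)),
    list(Wg = matrix(0, 2, 2), bg = c(0, 0),
         Wf = matrix(0, 2, 2), bf = c(0.5, 0.5)))
  m <- manual_bime(2, 2, heads, list(list(exp_baseline(0.01),
                                          exp_baseline(0.02)),
                                     list(exp_baseline(0.01),
                                          exp_baseline(0.02))),
                   c("age", "tumor_size"), two_col_stats())
  d <- tibble::tibble(age = c(0.4, -1), tumor_size = c(2, 0))
  mh <- mixture_log_hazard(m, d, arm = 0)
  expect_equal(mh$eta, rep(log(0.3 + 0.7 * exp(1)), 2))
  expect_equal(mh$gate1, rep(0.3, 2))
  expect_equal(mh$gate2, rep(0.7, 2))
  # equal gates, equal components -> eta equals the common component
  mh1 <- mixture_log_hazard(m, d, arm = 1)
  expect_equal(mh1$eta, rep(0.5, 2))
  # K = 1 degenerates to a single head
  heads1 <- list(list(Wg = matrix(0, 2, 1), bg = 0,
                      Wf = matrix(c(1, 0), 2, 1), bf = 0.2),
                 list(Wg = matrix(0, 2, 1), bg = 0,
                      Wf = matrix(0, 2, 1), bf = 0))
  m1 <- manual_bime(2, 2, heads1, list(list(exp_baseline(0.01)),
                                       list(exp_baseline(0.01))),
                    c("age", "tumor_size"), two_col_stats(), k = 1)
  mh2 <- mixture_log_hazard(m1, d, arm = 0)
  expect_equal(mh2$eta, d$age + 0.2)
  expect_equal(mh2$gate1, rep(1, 2))
})

test_that("predicted survival matches closed forms for hand-set mixtures", {
  lam <- c(0.02, 0.08)
  heads <- list(
    list(Wg = matrix(0, 2, 2), bg = c(0, 0),      # equal gates 0.5/0.5
         Wf = matrix(0, 2, 2), bf = c(0, 0)),     # zero log-hazard
    list(Wg = matrix(0, 2, 2), bg = c(0, 0),
         Wf = matrix(0, 2, 2), bf = c(0, 0)))
  m <- manual_bime(2, 2, heads,
                   list(list(exp_baseline(lam[1]), exp_baseline(lam[2])),
                        list(exp_baseline(lam[1]), exp_baseline(lam[2]))),
                   c("age", "tumor_size"), two_col_stats())
  d <- tibble::tibble(age = c(0, 1), tumor_size = c(0, -1))
  times <- c(0, 10, 50, 100)
  cv <- predict_survival(m, d, arm = 0, times = times)
  expect_s3_class(cv, "bime_curves")
  one <- cv[cv$patient_id == "1", ]
  expect_equal(one$surv[one$time == 0], 1)
  expect_equal(one$surv,
               0.5 * exp(-lam[1] * times) + 0.5 * exp(-lam[2] * times),
               tolerance = 1e-10)
  expect_true(all(diff(one$surv) <= 0))
  expect_error(predict_survival(m, d, arm = 2), "arm")
  # K = 1 with zero log-hazard returns the baseline survival itself
  heads1 <- list(list(Wg = matrix(0, 2, 1), bg = 0,
                      Wf = matrix(0, 2, 1), bf = 0),
                 list(Wg = matrix(0, 2, 1), bg = 0,
                      Wf = matrix(0, 2, 1), bf = 0))
  m1 <- manual_bime(2, 2, heads1, list(list(exp_baseline(0.03)),
                                       list(exp_baseline(0.03))),
                    c("age", "tumor_size"), two_col_stats(), k = 1)
  cv1 <- predict_survival(m1, d[1, ], arm = 1, times = times)
  expect_equal(cv1$surv, exp(-0.03 * times), tolerance = 1e-12)
})

test_that("time-at-risk inverts, interpolates and caps", {
  # exponential with S(120) = 0.10
  lam <- log(10) / 120
  tgrid <- seq(0, 200, by = 0.25)
  curve <- tibble::tibble(time = tgrid, surv = exp(-lam * tgrid))
  expect_equal(time_at_risk(curve, 0.10, cap = 240), 120, tolerance = 1e-3)
  # never below threshold on [0, cap] -> cap
  flat <- tibble::tibble(time = c(0, 60, 120), surv = c(1, 0.9, 0.8))
  expect_equal(time_at_risk(flat, 0.10, cap = 120), 120)
  # step curve: S = 1 on [0, 10), 0.05 after -> 10 under step semantics
  step <- tibble::tibble(time = c(0, 10, 20), surv = c(1, 0.05, 0.05))
  expect_equal(time_at_risk(step, 0.10, cap = 120, interpolate = FALSE), 10)
})

test_that("the effect contrast and tie rule drive recommendations", {
  # arm 1 exponential reaching 0.1 at 100 months, arm 0 at 80 months
  heads1 <- list(list(Wg = matrix(0, 2, 1), bg = 0,
                      Wf = matrix(0, 2, 1), bf = 0),
                 list(Wg = matrix(0, 2, 1), bg = 0,
                      Wf = matrix(0, 2, 1), bf = 0))
  m <- manual_bime(2, 2, heads1,
                   list(list(exp_baseline(log(10) / 80)),
                        list(exp_baseline(log(10) / 100))),
                    c("age", "tumor_size"), two_col_stats(), k = 1)
  d <- tibble::tibble(age = c(0, 0), tumor_size = c(0, 0),
                      treatment = c(0, 1))
  r <- recommend(m, d, threshold = 0.10, cap = 120)
  expect_equal(r$ite, r$tar_mrm - r$tar_nsm)
  expect_equal(round(r$tar_mrm), c(100, 100))
  expect_equal(round(r$tar_nsm), c(80, 80))
  expect_equal(r$recommended, c(1L, 1L))   # positive effect -> MRM
  expect_equal(r$consis, c(0L, 1L))
  # identical arms -> zero effect -> NSM (ties go to the less invasive arm)
  m0 <- manual_bime(2, 2, heads1,
                    list(list(exp_baseline(log(10) / 90)),
                         list(exp_baseline(log(10) / 90))),
                    c("age", "tumor_size"), two_col_stats(), k = 1)
  r0 <- recommend(m0, d)
  expect_equal(r0$ite, c(0, 0))
  expect_equal(r0$recommended, c(0L, 0L))
})

test_that("fitting is deterministic given data and seed", {
  sim <- generate_cohort(sim_config(n = 250, seed = 31))
  f1 <- bime_fit(sim$cohort, control = quick_control(seed = 4,
                                                     max_iter = 40))
  f2 <- bime_fit(sim$cohort, control = quick_control(seed = 4,
                                                     max_iter = 40))
  expect_identical(f1$state, f2$state)
  expect_identical(f1$history, f2$history)
  r1 <- recommend(f1, sim$cohort)
  r2 <- recommend(f2, sim$cohort)
  expect_identical(r1, r2)
})

test_that("the loss decomposition identity holds and reduces correctly", {
  sim <- generate_cohort(sim_config(n = 250, seed = 32))
  fit <- bime_fit(sim$cohort, control = quick_control(seed = 5,
                                                      max_iter = 40))
  h <- fit$history
  expect_lt(max(abs(h$total - (h$q * h$lcox0 + (1 - h$q) * h$lcox1 +
                                 h$alpha * h$ipm + h$q0 + h$q1))), 1e-10)
  # the running minimum of the training loss never increases
  expect_true(all(diff(cummin(h$total)) <= 0))
  # independent recomputation of the Cox terms from the model's own
  # log-hazards reproduces the reported parts
  parts <- bime_loss(fit, sim$cohort)
  for (a in 0:1) {
    idx <- sim$cohort$treatment == a
    eta <- mixture_log_hazard(fit, sim$cohort[idx, ], arm = a)$eta
    lc <- cox_neg_partial_loglik(eta, sim$cohort$followup_months[idx],
                                 sim$cohort$event_overall[idx])
    expect_equal(parts[[paste0("lcox", a)]], lc, tolerance = 1e-12)
  }
  expect_equal(parts$total,
               parts$q * parts$lcox0 + (1 - parts$q) * parts$lcox1 +
                 parts$alpha * parts$ipm + parts$q0 + parts$q1,
               tolerance = 1e-12)
  # K = 1, alpha = 0: the loss is exactly the weighted pair of Cox terms
  fit0 <- bime_fit(sim$cohort,
                   control = quick_control(seed = 5, max_iter = 30, k = 1,
                                           alpha = 0))
  p0 <- bime_loss(fit0, sim$cohort)
  expect_equal(p0$total, p0$q * p0$lcox0 + (1 - p0$q) * p0$lcox1,
               tolerance = 1e-12)
  expect_equal(p0$q0 + p0$q1, 0)
  # an all-censored batch has zero Cox terms
  cens <- sim$cohort[sim$cohort$event_overall == 0, ]
  expect_warning(pc <- bime_loss(fit, cens), "no events")
  expect_equal(pc$lcox0 + pc$lcox1, 0)
})

test_that("relabelling the arms flips the recommendation", {
  sim <- generate_cohort(sim_config(n = 800, seed = 33))
  ctrl <- quick_control(seed = 6, max_iter = 150)
  f1 <- bime_fit(sim$cohort, control = ctrl)
  flipped <- sim$cohort
  flipped$treatment <- 1 - flipped$treatment
  f2 <- bime_fit(flipped, control = ctrl)
  r1 <- recommend(f1, sim$cohort)
  r2 <- recommend(f2, sim$cohort)
  expect_gt(mean(r2$recommended == 1 - r1$recommended), 0.85)
})

test_that("the balancing penalty actually shrinks the arm divergence", {
  # median over 5 seeds: latent IPM after training with alpha = 1 is
  # smaller than after training with alpha = 0
  deltas <- sapply(1:5, function(s) {
    sim <- generate_cohort(sim_config(n = 500, seed = 100 + s))
    ca <- quick_control(seed = s, max_iter = 60, alpha = 1)
    c0 <- quick_control(seed = s, max_iter = 60, alpha = 0)
    fa <- bime_fit(sim$cohort, control = ca)
    f0 <- bime_fit(sim$cohort, control = c0)
    ipm_a <- bime_loss(fa, sim$cohort, alpha = 1)$ipm
    ipm_0 <- bime_loss(f0, sim$cohort, alpha = 1)$ipm
    ipm_0 - ipm_a
  })
  expect_gt(median(deltas), 0)
})

test_that("cross-validation scores configurations on held-out Cox loss", {
  sim <- generate_cohort(sim_config(n = 400, seed = 34))
  cv <- bime_cv(sim$cohort, grid = data.frame(k = c(1, 2)), nfolds = 5,
                control = quick_control(seed = 2, max_iter = 30,
                                        val_every = 10))
  expect_equal(nrow(cv$results), 2)
  expect_true(all(is.finite(cv$results$mean_loss)))
  expect_true(cv$best$k %in% c(1, 2))
  expect_equal(sort(unique(cv$folds)), 1:5)
})

test_that("model checkpoints round-trip with a schema check", {
  sim <- generate_cohort(sim_config(n = 200, seed = 35))
  fit <- bime_fit(sim$cohort, control = quick_control(seed = 3,
                                                      max_iter = 20))
  path <- withr::local_tempfile(fileext = ".rds")
  save_bime(fit, path)
  back <- load_bime(path)
  expect_identical(recommend(back, sim$cohort), recommend(fit, sim$cohort))
  bad <- fit; bad$schema_version <- 99L
  saveRDS(bad, path)
  expect_error(load_bime(path), "schema")
})
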