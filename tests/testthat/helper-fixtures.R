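# Shared fixtures and independent oracles, built in code at test time.

# a small fully-valid cohort table
make_tiny_cohort <- function(n = 5) {
  tibble::tibble(
    patient_id = sprintf("T%03d", seq_len(n)),
    age = seq(40, 70, length.out = n),
    tumor_size = seq(12, 48, length.out = n),
    married = rep_len(c(1, 0), n),
    race = rep_len(c("White", "Black", "Other"), n),
    income_high = rep_len(c(0, 1), n),
    grade = rep_len(c("I", "II", "III"), n),
    location = rep_len(c("upper_outer", "central_overlapping"), n),
    t_stage = rep_len(c("T1", "T2"), n),
    n_stage = rep_len(c("N0", "N1"), n),
    m_stage = rep("M0", n),
    tnm_stage = rep_len(c("IA", "IIB"), n),
    iib_t3n0 = rep(0, n),
    aln_positive = rep_len(c(0, 1), n),
    er_positive = rep_len(c(1, 0), n),
    pr_positive = rep_len(c(1, 0), n),
    her2_positive = rep_len(c(0, 1), n),
    nst = rep_len(c(0, 1), n),
    treatment = rep_len(c(0, 1), n),
    followup_months = seq(12, 90, length.out = n),
    event_overall = rep_len(c(1, 0), n),
    event_bcss = rep(0, n)
  )
}

# independent brute-force negative Breslow partial log-likelihood (loops,
# no shared code with the package implementation)
brute_neg_pll <- function(beta, X, time, status, weights = NULL) {
  w <- if (is.null(weights)) rep(1, nrow(X)) else weights
  eta <- drop(as.matrix(X) %*% beta)
  ll <- 0
  for (i in seq_along(time)) {
    if (status[i] == 1) {
      risk <- which(time >= time[i])
      ll <- ll + w[i] * (eta[i] - log(sum(w[risk] * exp(eta[risk]))))
    }
  }
  -ll
}

# brute-force maximizer of the Breslow partial likelihood
brute_cox_fit <- function(X, time, status, weights = NULL) {
  optim(rep(0, ncol(X)), brute_neg_pll, X = X, time = time,
        status = status, weights = weights, method = "BFGS",
        control = list(reltol = 1e-14, maxit = 500))$par
}

# Harrell concordance of a risk score within one arm, via the survival
# package (higher eta = higher risk)
arm_concordance <- function(eta, time, status) {
  fit <- survival::concordance(survival::Surv(time, status) ~ eta,
                               reverse = TRUE)
  unname(fit$concordance)
}

# pooled (event-weighted) concordance across arms for a T-learner model:
# risk score is the predicted marginal log-hazard for the received arm
model_concordance <- function(model, data) {
  cs <- vapply(0:1, function(a) {
    idx <- which(data$treatment == a)
    eta <- mixture_log_hazard(model, data[idx, ], arm = a)$eta
    arm_concordance(eta, data$followup_months[idx],
                    data$event_overall[idx])
  }, numeric(1))
  ns <- vapply(0:1, function(a) sum(data$treatment == a), numeric(1))
  sum(cs * ns) / sum(ns)
}

# build a minimal fitted-model object around hand-set parameters: a single
# identity linear encoder and given heads/baselines, so closed-form
# predictions can be asserted
manual_bime <- function(p, latent, heads, baselines, covariates,
                        design_stats, k = ncol(heads[[1]]$Wf)) {
  net <- list(layers = list(list(W = diag(1, p, latent),
                                 b = rep(0, latent))),
              activation = "linear")
  class(net) <- "bime_mlp"
  structure(list(
    state = list(shared = TRUE, K = k, net = net, heads = heads),
    control = bime_control(k = k, latent_dim = latent, hidden = c(),
                           activation = "linear", dropout = 0),
    covariates = covariates, design_stats = design_stats,
    time = "followup_months", event = "event_overall",
    treatment = "treatment",
    baselines = baselines, history = tibble::tibble(),
    best_iter = NA_integer_, best_val = NA_real_, n = 0L, n_events = 0L
  ), class = "bime_fit")
}

# linear mediation system with known path coefficients: exposure -> mediator
# slope `a` (linear probability), mediator -> outcome slope `b`, direct
# effect `c_dir`, one confounder
make_linear_system <- function(n = 10000, a = 0.5, b = 0.4, c_dir = -0.3,
                               seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    ex <- rbinom(n, 1, plogis(0.3 * x))
    me <- rbinom(n, 1, pmin(pmax(0.3 + a * ex + 0.05 * x, 0.01), 0.99))
    y <- c_dir * ex + b * me + 0.2 * x + rnorm(n, 0, 0.5)
    tibble::tibble(x = x, ex = ex, me = me, y = y)
  })
}

# small quick-fit settings shared by tests that need a trained model but
# not a converged one
quick_control <- function(seed = 1, ...) {
  args <- list(k = 2, alpha = 1, hidden = c(8), latent_dim = 4,
               batch_size = 96, max_iter = 80, estep_every = 20,
               val_every = 20, m_samples = 5, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(bime_control, args)
}
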