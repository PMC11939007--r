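# BIME: a two-arm (T-learner) Cox mixture on a shared latent representation
# balanced across treatment arms by an entropic optimal-transport penalty.
#
# Architecture: an encoder Phi(x) feeds, per treatment arm, a softmax gating
# map over K latent components and K linear log-hazard heads; each arm-
# component pair carries its own Breslow baseline hazard. The batch loss is
#
#   q * lCox[T=0] + (1 - q) * lCox[T=1] + alpha * IPM(Phi1, Phi0) + Q0 + Q1
#
# where q is the batch fraction in the control arm (T = 0, NSM), lCox are
# the per-arm negative Cox partial log-likelihoods of the mixture-marginal
# log-hazard, IPM is the transport penalty between arm representations, and
# the Q terms are Monte-Carlo E-step complete-data negative log-likelihoods
# (gating log-probability plus component-conditional Cox/Breslow
# likelihood) with component assignments sampled from their posterior.
# Fitting alternates E-steps (posterior sampling + baseline refresh) with
# Adam steps on the batch loss (MCEM).

log_softmax <- function(U) {
  m <- apply(U, 1, max)
  U - m - log(rowSums(exp(U - m)))
}

logsumexp_rows <- function(U) {
  m <- apply(U, 1, max)
  m + log(rowSums(exp(U - m)))
}

#' Training controls for [bime_fit()]
#'
#' @param k Number of mixture components per arm.
#' @param alpha Weight of the representation-balancing (IPM) penalty.
#' @param latent_dim Dimension of the shared representation.
#' @param hidden Integer vector of encoder hidden-layer widths.
#' @param activation `"tanh"` or `"relu"`.
#' @param dropout Encoder dropout rate (training only; prediction is
#'   deterministic).
#' @param share_encoder Share one encoder across arms (`TRUE`, the BIME /
#'   BITES layout) or give each arm its own (`FALSE`, the DeepSurv
#'   T-learner layout).
#' @param use_marginal_lcox Include the per-arm marginal Cox terms in the
#'   loss alongside the mixture Q terms (default); `FALSE` drops them,
#'   recovering a pure deep-Cox-mixture objective.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size (arm-stratified).
#' @param max_iter Maximum number of minibatch iterations.
#' @param estep_every Refresh posteriors/baselines every this many
#'   iterations.
#' @param m_samples Monte-Carlo posterior samples per subject per E-step.
#' @param val_frac Fraction of the training data held out internally for
#'   early stopping (stratified by arm and event).
#' @param val_every Evaluate the validation loss every this many
#'   iterations.
#' @param patience Early-stopping patience, in iterations without
#'   validation improvement.
#' @param epsilon Entropic regularization of the IPM; `NULL` (default) uses
#'   0.1 x the median pairwise latent distance of the batch.
#' @param p Order of the IPM ground cost.
#' @param ipm_cap Maximum points per arm entering the transport problem in
#'   a batch (evenly spaced subsample beyond that).
#' @param seed Seed governing initialization, batching and E-step
#'   sampling.
#' @param verbose Print progress.
#' @return A list of class `bime_control`.
#' @export
bime_control <- function(k = 3, alpha = 1, latent_dim = 8,
                         hidden = c(16, 16), activation = "tanh",
                         dropout = 0.1, share_encoder = TRUE,
                         use_marginal_lcox = TRUE, lr = 1e-2,
                         batch_size = 256, max_iter = 1500,
                         estep_every = 50, m_samples = 10,
                         val_frac = 0.15, val_every = 25, patience = 1000,
                         epsilon = NULL, p = 2, ipm_cap = 64, seed = 1,
                         verbose = FALSE) {
  stopifnot(k >= 1, alpha >= 0, latent_dim >= 1, dropout >= 0, dropout < 1,
            batch_size >= 8, max_iter >= 1, val_frac >= 0, val_frac < 0.5)
  structure(as.list(environment()), class = "bime_control")
}

new_heads <- function(latent_dim, k) {
  lim <- sqrt(6 / (latent_dim + k))
  list(Wg = matrix(runif(latent_dim * k, -lim, lim), latent_dim, k),
       bg = rep(0, k),
       Wf = matrix(runif(latent_dim * k, -lim, lim) * 0.1, latent_dim, k),
       bf = rep(0, k))
}

get_trainable <- function(state) {
  if (state$shared) {
    list(enc = state$net$layers, h0 = state$heads[[1]],
         h1 = state$heads[[2]])
  } else {
    list(enc0 = state$net0$layers, enc1 = state$net1$layers,
         h0 = state$heads[[1]], h1 = state$heads[[2]])
  }
}

set_trainable <- function(state, tree) {
  if (state$shared) {
    state$net$layers <- tree$enc
  } else {
    state$net0$layers <- tree$enc0
    state$net1$layers <- tree$enc1
  }
  state$heads[[1]] <- tree$h0
  state$heads[[2]] <- tree$h1
  state
}

# forward through encoder(s); rows0/rows1 index the arms within X
encode_arms <- function(state, X, rows0, rows1, dropout = 0,
                        training = FALSE) {
  if (state$shared) {
    fw <- nn_forward(state$net, X, dropout, training)
    list(Phi0 = fw$out[rows0, , drop = FALSE],
         Phi1 = fw$out[rows1, , drop = FALSE], cache = fw$cache)
  } else {
    fw0 <- nn_forward(state$net0, X[rows0, , drop = FALSE], dropout, training)
    fw1 <- nn_forward(state$net1, X[rows1, , drop = FALSE], dropout, training)
    list(Phi0 = fw0$out, Phi1 = fw1$out, cache0 = fw0$cache,
         cache1 = fw1$cache)
  }
}

head_forward <- function(head, Phi) {
  U <- sweep(Phi %*% head$Wg, 2, head$bg, `+`)
  logg <- log_softmax(U)
  FF <- sweep(Phi %*% head$Wf, 2, head$bf, `+`)
  list(logg = logg, g = exp(logg), f = FF,
       eta = logsumexp_rows(logg + FF))
}

# cumulative hazard of each component at given times; baselines: list of K
# baseline tibbles
comp_cumhaz <- function(baselines, times) {
  vapply(baselines, function(b) eval_cumhaz(b, times), numeric(length(times)))
}

comp_dhaz <- function(baselines, times) {
  vapply(baselines, function(b) {
    if (nrow(b) == 0) return(rep(0, length(times)))
    idx <- match(times, b$time)
    out <- rep(0, length(times))
    out[!is.na(idx)] <- b$dhaz[idx[!is.na(idx)]]
    out
  }, numeric(length(times)))
}

# posterior over components for one arm's subjects
component_posterior <- function(hf, baselines, time, status) {
  K <- ncol(hf$f)
  if (is.null(baselines)) return(exp(hf$logg))
  L <- matrix(comp_cumhaz(baselines, time), ncol = K)
  D <- matrix(comp_dhaz(baselines, time), ncol = K)
  loglik <- hf$logg - L * exp(hf$f) +
    status * (log(pmax(D, 1e-12)) + hf$f)
  exp(log_softmax(loglik))
}

sample_assignments <- function(post, m_samples) {
  t(apply(post, 1, function(p) {
    drop(rmultinom(1, m_samples, p)) / m_samples
  }))
}

refresh_baselines <- function(hf, time, status, pihat) {
  lapply(seq_len(ncol(pihat)), function(k) {
    if (sum(pihat[, k] * status) <= 0) {
      return(tibble(time = numeric(0), dhaz = numeric(0),
                    cumhaz = numeric(0)))
    }
    breslow_baseline(hf$f[, k], time, status, weights = pihat[, k])
  })
}

# complete-data (Q) negative log-likelihood for one arm + gradients wrt the
# head outputs; pihat rows sum to 1
q_term <- function(hf, baselines, time, status, pihat) {
  K <- ncol(hf$f)
  n <- nrow(hf$f)
  if (n == 0 || K == 1 || is.null(baselines)) {
    return(list(value = 0, dlogit = matrix(0, n, K),
                df = matrix(0, n, K)))
  }
  L <- matrix(comp_cumhaz(baselines, time), ncol = K)
  D <- matrix(comp_dhaz(baselines, time), ncol = K)
  comp_ll <- status * (log(pmax(D, 1e-12)) + hf$f) - L * exp(hf$f)
  value <- -sum(pihat * (hf$logg + comp_ll)) / n
  dlogit <- (exp(hf$logg) - pihat) / n        # softmax cross-entropy
  df <- -pihat * (status - L * exp(hf$f)) / n
  list(value = value, dlogit = dlogit, df = df)
}

# full loss (value + gradients) on a set of rows; pihat0/1 are assignment
# weights for those rows (NULL -> posterior probabilities, deterministic)
bime_batch_loss <- function(state, X, time, status, arm, control,
                            baselines, pihat0 = NULL, pihat1 = NULL,
                            training = FALSE, want_grad = FALSE) {
  rows0 <- which(arm == 0); rows1 <- which(arm == 1)
  enc <- encode_arms(state, X, rows0, rows1,
                     dropout = control$dropout, training = training)
  hf0 <- head_forward(state$heads[[1]], enc$Phi0)
  hf1 <- head_forward(state$heads[[2]], enc$Phi1)
  q <- length(rows0) / (length(rows0) + length(rows1))

  lcox <- function(hf, rows) {
    if (length(rows) == 0 || sum(status[rows]) == 0) {
      if (length(rows) > 0) {
        warn("bime loss: no events in arm batch; Cox term 0")
      }
      return(0)
    }
    cox_neg_partial_loglik(hf$eta, time[rows], status[rows])
  }
  l0 <- if (control$use_marginal_lcox) lcox(hf0, rows0) else 0
  l1 <- if (control$use_marginal_lcox) lcox(hf1, rows1) else 0

  if (is.null(pihat0)) {
    pihat0 <- component_posterior(hf0, baselines[[1]], time[rows0],
                                  status[rows0])
  }
  if (is.null(pihat1)) {
    pihat1 <- component_posterior(hf1, baselines[[2]], time[rows1],
                                  status[rows1])
  }
  qt0 <- q_term(hf0, baselines[[1]], time[rows0], status[rows0], pihat0)
  qt1 <- q_term(hf1, baselines[[2]], time[rows1], status[rows1], pihat1)

  ipm <- 0
  ipm_g <- NULL
  if (control$alpha > 0) {
    # cap the transport problem at ipm_cap points per arm (deterministic,
    # evenly spaced within the batch) to keep the penalty O(cap^2)
    cap <- control$ipm_cap
    sub <- function(n) if (n > cap) unique(round(seq(1, n, length.out = cap)))
      else seq_len(n)
    s1 <- sub(nrow(enc$Phi1)); s0 <- sub(nrow(enc$Phi0))
    ipm <- ipm_distance(enc$Phi1[s1, , drop = FALSE],
                        enc$Phi0[s0, , drop = FALSE], p = control$p,
                        epsilon = control$epsilon, grad = want_grad,
                        max_iter = 40, tol = 1e-5)
    if (want_grad) {
      g1 <- matrix(0, nrow(enc$Phi1), ncol(enc$Phi1))
      g0 <- matrix(0, nrow(enc$Phi0), ncol(enc$Phi0))
      g1[s1, ] <- attr(ipm, "grad_x1")
      g0[s0, ] <- attr(ipm, "grad_x0")
      ipm_g <- list(g1 = g1, g0 = g0)
    }
    ipm <- as.numeric(ipm)
  }

  parts <- tibble(lcox0 = l0, lcox1 = l1, ipm = ipm, q = q,
                  alpha = control$alpha, q0 = qt0$value, q1 = qt1$value,
                  total = q * l0 + (1 - q) * l1 + control$alpha * ipm +
                    qt0$value + qt1$value)
  if (!want_grad) return(list(parts = parts))

  grad_head <- function(hf, rows, qw, lterm_on, qt) {
    n <- length(rows)
    K <- ncol(hf$f)
    df <- qt$df
    dlogit <- qt$dlogit
    if (lterm_on && n > 0 && sum(status[rows]) > 0) {
      geta <- cox_pll_gradient(hf$eta, time[rows], status[rows])
      s <- exp(hf$logg + hf$f - hf$eta)    # within-mixture responsibilities
      df <- df + qw * geta * s
      dlogit <- dlogit + qw * geta * (s - exp(hf$logg))
    }
    list(df = df, dlogit = dlogit)
  }
  gh0 <- grad_head(hf0, rows0, q, control$use_marginal_lcox, qt0)
  gh1 <- grad_head(hf1, rows1, 1 - q, control$use_marginal_lcox, qt1)

  head_grads_phi <- function(head, Phi, gh, ipm_grad) {
    dPhi <- gh$dlogit %*% t(head$Wg) + gh$df %*% t(head$Wf)
    if (!is.null(ipm_grad)) dPhi <- dPhi + ipm_grad
    list(grads = list(Wg = crossprod(Phi, gh$dlogit), bg = colSums(gh$dlogit),
                      Wf = crossprod(Phi, gh$df), bf = colSums(gh$df)),
         dPhi = dPhi)
  }
  ig0 <- if (!is.null(ipm_g)) control$alpha * ipm_g$g0 else NULL
  ig1 <- if (!is.null(ipm_g)) control$alpha * ipm_g$g1 else NULL
  hg0 <- head_grads_phi(state$heads[[1]], enc$Phi0, gh0, ig0)
  hg1 <- head_grads_phi(state$heads[[2]], enc$Phi1, gh1, ig1)

  if (state$shared) {
    dPhi <- matrix(0, nrow(X), ncol(hg0$dPhi))
    dPhi[rows0, ] <- hg0$dPhi
    dPhi[rows1, ] <- hg1$dPhi
    bp <- nn_backward(state$net, enc$cache, dPhi)
    tree_grads <- list(enc = bp$grads, h0 = hg0$grads, h1 = hg1$grads)
  } else {
    bp0 <- nn_backward(state$net0, enc$cache0, hg0$dPhi)
    bp1 <- nn_backward(state$net1, enc$cache1, hg1$dPhi)
    tree_grads <- list(enc0 = bp0$grads, enc1 = bp1$grads,
                       h0 = hg0$grads, h1 = hg1$grads)
  }
  list(parts = parts, grads = tree_grads)
}

#' Fit the BIME model
#'
#' Fits the balanced Cox-mixture T-learner by Monte-Carlo EM: E-steps
#' sample component assignments from their posterior (gating probability
#' times component-conditional survival likelihood under the current
#' Breslow baselines); M-steps take Adam gradient steps on the batch loss
#' with the sampled assignments held fixed. An internal validation split
#' drives early stopping; the parameters with the best validation loss are
#' kept, and final per-arm, per-component Breslow baselines are computed
#' with posterior-weighted risk sets on the full training data.
#'
#' @param data A cohort tibble (see [cohort_dictionary()]), or any data
#'   frame containing `covariates`, the time/event columns and a 0/1
#'   treatment column.
#' @param covariates Covariate columns to encode; default
#'   [default_covariates()].
#' @param time,event,treatment Column names of follow-up time, event
#'   indicator and treatment arm (0 = NSM, 1 = MRM).
#' @param control A [bime_control()].
#' @return An object of class `bime_fit` with, notably, `history` (one row
#'   of loss components per iteration) and `baselines`.
#' @export
bime_fit <- function(data, covariates = default_covariates(),
                     time = "followup_months", event = "event_overall",
                     treatment = "treatment", control = bime_control()) {
  stopifnot(inherits(control, "bime_control"))
  tt <- data[[time]]; ev <- data[[event]]; arm <- data[[treatment]]
  if (is.null(tt) || is.null(ev) || is.null(arm)) {
    abort("bime_fit: time/event/treatment columns not found")
  }
  if (length(unique(arm)) < 2) abort("bime_fit: need both treatment arms")
  for (a in 0:1) {
    if (sum(ev[arm == a]) < 1) {
      abort(sprintf("bime_fit: no events in arm %d", a))
    }
  }

  dm <- design_matrix(data, covariates)
  X <- dm$X
  n <- nrow(X)

  # internal validation split for early stopping
  is_val <- if (control$val_frac > 0) {
    strat_split(paste(arm, ev), control$val_frac,
                substream_seed(control$seed, "valsplit"))
  } else rep(FALSE, n)
  tr <- which(!is_val); va <- which(is_val)

  with_seed(substream_seed(control$seed, "init"), {
    state <- list(shared = control$share_encoder, K = control$k)
    sizes <- c(ncol(X), control$hidden, control$latent_dim)
    if (control$share_encoder) {
      state$net <- nn_init(sizes, control$activation)
    } else {
      state$net0 <- nn_init(sizes, control$activation)
      state$net1 <- nn_init(sizes, control$activation)
    }
    state$heads <- list(new_heads(control$latent_dim, control$k),
                        new_heads(control$latent_dim, control$k))
  })

  Xtr <- X[tr, , drop = FALSE]
  arm_tr <- arm[tr]; t_tr <- tt[tr]; e_tr <- ev[tr]
  rows0 <- which(arm_tr == 0); rows1 <- which(arm_tr == 1)

  estep <- function(state, baselines, sample = TRUE) {
    enc <- encode_arms(state, Xtr, rows0, rows1, training = FALSE)
    hf0 <- head_forward(state$heads[[1]], enc$Phi0)
    hf1 <- head_forward(state$heads[[2]], enc$Phi1)
    post0 <- component_posterior(hf0, baselines[[1]], t_tr[rows0],
                                 e_tr[rows0])
    post1 <- component_posterior(hf1, baselines[[2]], t_tr[rows1],
                                 e_tr[rows1])
    pi0 <- if (sample && control$k > 1) {
      sample_assignments(post0, control$m_samples)
    } else post0
    pi1 <- if (sample && control$k > 1) {
      sample_assignments(post1, control$m_samples)
    } else post1
    list(pihat0 = pi0, pihat1 = pi1,
         baselines = list(refresh_baselines(hf0, t_tr[rows0], e_tr[rows0], pi0),
                          refresh_baselines(hf1, t_tr[rows1], e_tr[rows1], pi1)))
  }

  opt <- adam_init(get_trainable(state))
  baselines <- list(NULL, NULL)
  pih0 <- pih1 <- NULL
  history <- vector("list", control$max_iter)
  best <- list(val = Inf, tree = get_trainable(state), iter = 0L,
               baselines = baselines)
  stale <- 0L

  with_seed(substream_seed(control$seed, "train"), {
    for (it in seq_len(control$max_iter)) {
      if ((it - 1) %% control$estep_every == 0) {
        es <- estep(state, baselines, sample = TRUE)
        baselines <- es$baselines
        pih0 <- es$pihat0; pih1 <- es$pihat1
      }
      # arm-stratified minibatch
      b0 <- sample(rows0, min(length(rows0),
                              max(2, round(control$batch_size *
                                             length(rows0) / nrow(Xtr)))))
      b1 <- sample(rows1, min(length(rows1),
                              max(2, control$batch_size - length(b0))))
      bidx <- c(b0, b1)
      bl <- bime_batch_loss(
        state, Xtr[bidx, , drop = FALSE], t_tr[bidx], e_tr[bidx],
        arm_tr[bidx], control, baselines,
        pihat0 = pih0[match(b0, rows0), , drop = FALSE],
        pihat1 = pih1[match(b1, rows1), , drop = FALSE],
        training = TRUE, want_grad = TRUE)
      upd <- adam_step(get_trainable(state), bl$grads, opt, lr = control$lr)
      state <- set_trainable(state, upd$params)
      opt <- upd$state

      val_loss <- NA_real_
      if (length(va) > 0 && it %% control$val_every == 0) {
        vl <- bime_batch_loss(state, X[va, , drop = FALSE], tt[va], ev[va],
                              arm[va], control, baselines,
                              training = FALSE, want_grad = FALSE)
        val_loss <- vl$parts$total
        if (val_loss < best$val - 1e-9) {
          best <- list(val = val_loss, tree = get_trainable(state),
                       iter = it, baselines = baselines)
          stale <- 0L
        } else {
          stale <- stale + control$val_every
        }
      }
      history[[it]] <- dplyr::bind_cols(tibble(iter = it), bl$parts,
                                        tibble(val = val_loss))
      if (control$verbose && it %% 100 == 0) {
        message(sprintf("iter %d total %.4f val %.4f", it,
                        bl$parts$total, val_loss))
      }
      if (stale >= control$patience) break
    }
  })

  if (is.finite(best$val)) state <- set_trainable(state, best$tree)
  final <- estep(state, if (is.finite(best$val)) best$baselines else
    baselines, sample = FALSE)

  structure(list(
    state = state, control = control, covariates = covariates,
    design_stats = dm$stats, time = time, event = event,
    treatment = treatment,
    baselines = final$baselines,
    history = dplyr::bind_rows(history),
    best_iter = if (is.finite(best$val)) best$iter else NA_integer_,
    best_val = if (is.finite(best$val)) best$val else NA_real_,
    n = n, n_events = sum(ev)
  ), class = "bime_fit")
}

#' @export
print.bime_fit <- function(x, ...) {
  cat(sprintf(
    "BIME fit: n = %d (%d events), K = %d, alpha = %g, %s encoder\n",
    x$n, x$n_events, x$control$k, x$control$alpha,
    if (x$state$shared) "shared" else "per-arm"))
  cat(sprintf("  iterations run: %d; best validation loss %.4f at iter %s\n",
              nrow(x$history), x$best_val, x$best_iter))
  invisible(x)
}

#' @rdname bime_fit
#' @param x A `bime_fit`.
#' @param ... Unused.
#' @export
tidy.bime_fit <- function(x, ...) x$history

#' @rdname bime_fit
#' @export
glance.bime_fit <- function(x, ...) {
  tibble(n = x$n, n.events = x$n_events, k = x$control$k,
         alpha = x$control$alpha, iterations = nrow(x$history),
         best.iter = x$best_iter, best.val.loss = x$best_val)
}

bime_schema_version <- 1L

#' Save / load a fitted model checkpoint
#'
#' Serializes a fitted model (parameters, baselines, design statistics,
#' training history) to a single file with an embedded schema version,
#' checked on load.
#'
#' @param object A `bime_fit`.
#' @param path Checkpoint path.
#' @return `path` (save) or the restored `bime_fit` (load).
#' @export
save_bime <- function(object, path) {
  stopifnot(inherits(object, "bime_fit"))
  object$schema_version <- bime_schema_version
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_bime
#' @export
load_bime <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "bime_fit") ||
      !identical(object$schema_version, bime_schema_version)) {
    abort(sprintf("load_bime: not a schema-%d checkpoint",
                  bime_schema_version))
  }
  object
}

#' Cross-validated hyperparameter selection
#'
#' K-fold cross-validation (default fivefold) over a grid of mixture sizes
#' and balancing weights: each fold is held out once, the model is trained
#' on the remainder (with the fold as the early-stopping validation set),
#' and the fold's deterministic loss is recorded. Returns per-configuration
#' mean losses and the winning configuration.
#'
#' @inheritParams bime_fit
#' @param grid A data frame of configurations; columns must be
#'   [bime_control()] argument names (e.g. `k`, `alpha`).
#' @param nfolds Number of folds (default 5).
#' @param control Base control; each grid row overrides its fields.
#' @return A list of class `bime_cv`: `results` (one row per config with
#'   `mean_loss`), `best` (the winning control), `folds`.
#' @export
bime_cv <- function(data,
                    grid = expand.grid(k = c(1, 2, 3, 5),
                                       alpha = c(0.1, 1, 10)),
                    covariates = default_covariates(),
                    time = "followup_months", event = "event_overall",
                    treatment = "treatment", nfolds = 5,
                    control = bime_control()) {
  grid <- as.data.frame(grid)
  keys <- paste(data[[treatment]], data[[event]])
  fold <- with_seed(substream_seed(control$seed, "cvfolds"), {
    f <- integer(nrow(data))
    for (k in unique(keys)) {
      idx <- which(keys == k)
      f[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
    f
  })
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    ctrl <- control
    for (nm in names(grid)) ctrl[[nm]] <- grid[[nm]][i]
    losses <- vapply(seq_len(nfolds), function(f) {
      ctrl_f <- ctrl
      ctrl_f$val_frac <- 0   # the fold itself is the validation set
      fit <- bime_fit(data[fold != f, , drop = FALSE], covariates, time,
                      event, treatment, control = ctrl_f)
      # score on the held-out fold with the arm-weighted Cox terms only:
      # unlike the total, these are comparable across alpha and K
      parts <- bime_loss(fit, data[fold == f, , drop = FALSE])
      parts$q * parts$lcox0 + (1 - parts$q) * parts$lcox1
    }, numeric(1))
    dplyr::bind_cols(as_tibble(grid[i, , drop = FALSE]),
                     tibble(mean_loss = mean(losses),
                            sd_loss = sd(losses)))
  })
  best_i <- which.min(res$mean_loss)
  best <- control
  for (nm in names(grid)) best[[nm]] <- grid[[nm]][best_i]
  structure(list(results = res, best = best, folds = fold),
            class = "bime_cv")
}

#' @export
print.bime_cv <- function(x, ...) {
  cat("Cross-validation over", nrow(x$results), "configurations\n")
  print(x$results)
  invisible(x)
}

#' Loss components of a BIME model on a data set
#'
#' Evaluates the model's loss decomposition (per-arm Cox terms, balancing
#' penalty, mixture complete-data terms, and their weighted total) on a
#' batch of data, deterministically (posterior-probability assignments, no
#' dropout).
#'
#' @param object A fitted [bime_fit()].
#' @param data A data frame with the model's covariate/time/event/treatment
#'   columns.
#' @param alpha Penalty weight used for the total (default: the model's).
#' @return A one-row tibble: `lcox0`, `lcox1`, `ipm`, `q`, `alpha`, `q0`,
#'   `q1`, `total`.
#' @export
bime_loss <- function(object, data, alpha = NULL) {
  stopifnot(inherits(object, "bime_fit"))
  if (nrow(data) == 0) abort("bime_loss: empty batch")
  ctrl <- object$control
  if (!is.null(alpha)) ctrl$alpha <- alpha
  X <- design_matrix(data, object$covariates, object$design_stats)$X
  bl <- bime_batch_loss(object$state, X, data[[object$time]],
                        data[[object$event]], data[[object$treatment]],
                        ctrl, object$baselines, training = FALSE,
                        want_grad = FALSE)
  bl$parts
}
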