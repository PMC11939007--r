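# Cox partial-likelihood machinery (Breslow tie handling, optional case
# weights): loss and gradient on a fixed linear predictor, Newton-Raphson
# fitting, Breslow cumulative baseline hazard, robust (sandwich) variance
# for weighted fits. Written against sorted copies; callers keep original
# order.

# indices of the first / last member of each tie group on a sorted vector
tie_first <- function(t) cummax(seq_along(t) * !duplicated(t))
tie_last <- function(t) {
  v <- ifelse(!duplicated(t, fromLast = TRUE), seq_along(t), Inf)
  as.integer(rev(cummin(rev(v))))
}

revcumsum <- function(x) {
  if (is.matrix(x)) {
    apply(x[rev(seq_len(nrow(x))), , drop = FALSE], 2, cumsum)[
      rev(seq_len(nrow(x))), , drop = FALSE]
  } else rev(cumsum(rev(x)))
}

#' Negative Cox partial log-likelihood (Breslow)
#'
#' Computes the negative Cox partial log-likelihood of a fixed per-subject
#' log-hazard (linear predictor), with Breslow handling of tied event times
#' and optional case weights. By default the value is averaged over events
#' so batches of different sizes are comparable.
#'
#' @param eta Per-subject log-hazard values.
#' @param time Positive follow-up times.
#' @param status Event indicator (0/1).
#' @param weights Optional nonnegative case weights (default 1).
#' @param average If `TRUE` (default), divide by the (weighted) number of
#'   events; if `FALSE`, return the sum.
#' @return A scalar; 0 (with a warning) when no events are present.
#' @export
#' @examples
#' cox_neg_partial_loglik(c(0, 0), c(1, 2), c(1, 1), average = FALSE) # log 2
cox_neg_partial_loglik <- function(eta, time, status, weights = NULL,
                                   average = TRUE) {
  stopifnot(length(eta) == length(time), length(time) == length(status),
            all(time > 0), all(status %in% c(0, 1)))
  w <- if (is.null(weights)) rep(1, length(eta)) else weights
  if (sum(status) == 0) {
    warn("cox_neg_partial_loglik: no events in batch; returning 0")
    return(0)
  }
  ord <- order(time)
  t <- time[ord]; s <- status[ord]; ww <- w[ord]
  r <- ww * exp(eta[ord])
  denom <- revcumsum(r)[tie_first(t)]
  ll <- sum(ww[s == 1] * (eta[ord][s == 1] - log(denom[s == 1])))
  norm <- if (average) sum(ww * s) else 1
  -ll / norm
}

# gradient of cox_neg_partial_loglik w.r.t. eta (original order)
cox_pll_gradient <- function(eta, time, status, weights = NULL,
                             average = TRUE) {
  w <- if (is.null(weights)) rep(1, length(eta)) else weights
  if (sum(status) == 0) return(rep(0, length(eta)))
  ord <- order(time)
  t <- time[ord]; s <- status[ord]; ww <- w[ord]
  r <- ww * exp(eta[ord])
  denom <- revcumsum(r)[tie_first(t)]
  h <- ifelse(s == 1, ww / denom, 0)
  A <- cumsum(h)[tie_last(t)]
  g_sorted <- -ww * s + r * A
  norm <- if (average) sum(ww * s) else 1
  g <- numeric(length(eta))
  g[ord] <- g_sorted / norm
  g
}

#' Breslow cumulative baseline hazard
#'
#' Nonparametric step estimate of the cumulative baseline hazard given a
#' fixed linear predictor, with optional case weights (used for
#' posterior-weighted risk sets in the mixture model).
#'
#' @inheritParams cox_neg_partial_loglik
#' @return A tibble with `time` (unique event times, ascending), `dhaz`
#'   (hazard increments) and `cumhaz`.
#' @export
breslow_baseline <- function(eta, time, status, weights = NULL) {
  w <- if (is.null(weights)) rep(1, length(eta)) else weights
  ord <- order(time)
  t <- time[ord]; s <- status[ord]; ww <- w[ord]
  r <- ww * exp(eta[ord])
  if (sum(s * ww) == 0) {
    return(tibble(time = numeric(0), dhaz = numeric(0), cumhaz = numeric(0)))
  }
  denom <- revcumsum(r)[tie_first(t)]
  ev <- s == 1 & ww > 0
  et <- t[ev]
  inc <- ww[ev] / denom[ev]
  agg <- unname(drop(rowsum(inc, group = et)))
  tibble(time = sort(unique(et)), dhaz = agg, cumhaz = cumsum(agg))
}

# evaluate a Breslow cumulative hazard (step function, flat beyond last
# event time) at arbitrary times
eval_cumhaz <- function(baseline, times) {
  if (nrow(baseline) == 0) return(rep(0, length(times)))
  idx <- findInterval(times, baseline$time)
  c(0, baseline$cumhaz)[idx + 1L]
}

#' Fit a Cox proportional hazards model by Newton-Raphson
#'
#' In-package maximization of the (optionally weighted) Breslow partial
#' likelihood with step-halving, model-based and robust (sandwich)
#' variances. Constant columns are dropped with a warning; diverging
#' coefficients raise an error naming the offending covariate.
#'
#' @param X Numeric covariate matrix (n x p, with column names).
#' @param time Positive follow-up times.
#' @param status Event indicator (0/1).
#' @param weights Optional nonnegative case weights.
#' @param robust Compute the sandwich variance (always sensible with
#'   weights).
#' @param max_iter,tol Newton iteration controls.
#' @param diverge What to do when a coefficient diverges (monotone
#'   likelihood / separation): `"error"` (default) or `"drop"` the
#'   offending column with a warning and refit.
#' @return A list of class `bime_coxfit`: `coef`, `vcov`, `robust_vcov`,
#'   `loglik`, `iter`, `baseline` (Breslow, at the fitted coefficients),
#'   `dropped` (names of excluded constant columns).
#' @export
coxph_breslow <- function(X, time, status, weights = NULL, robust = FALSE,
                          max_iter = 50, tol = 1e-9,
                          diverge = c("error", "drop")) {
  diverge <- match.arg(diverge)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(time), all(status %in% c(0, 1)))
  if (sum(status) < 1) abort("coxph_breslow: no events")
  w <- if (is.null(weights)) rep(1, nrow(X)) else weights

  keep <- apply(X, 2, function(col) sd(col) > 1e-12)
  dropped <- colnames(X)[!keep]
  if (length(dropped) > 0) {
    warn(paste("coxph_breslow: dropping constant column(s):",
               paste(dropped, collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  p <- ncol(X)
  if (p == 0) abort("coxph_breslow: no non-constant covariates")

  ord <- order(time)
  t_s <- time[ord]; s_s <- status[ord]; w_s <- w[ord]
  X_s <- X[ord, , drop = FALSE]
  first <- tie_first(t_s); last <- tie_last(t_s)
  ev <- which(s_s == 1)

  score_info <- function(beta) {
    eta <- drop(X_s %*% beta)
    r <- w_s * exp(eta)
    S0 <- revcumsum(r)[first]
    S1 <- revcumsum(r * X_s)[first, , drop = FALSE]
    xbar <- S1 / S0
    ll <- sum(w_s[ev] * (eta[ev] - log(S0[ev])))
    U <- drop(crossprod(X_s[ev, , drop = FALSE] - xbar[ev, , drop = FALSE],
                        w_s[ev]))
    # information via S2 accumulated per event
    XX <- X_s[, rep(seq_len(p), each = p), drop = FALSE] *
      X_s[, rep(seq_len(p), times = p), drop = FALSE]
    S2 <- revcumsum(r * XX)[first, , drop = FALSE]
    I <- matrix(0, p, p)
    wS0 <- w_s[ev] / S0[ev]
    I <- matrix(colSums(S2[ev, , drop = FALSE] * wS0), p, p) -
      crossprod(xbar[ev, , drop = FALSE] * sqrt(w_s[ev]))
    list(ll = ll, U = U, I = I, eta = eta, r = r, S0 = S0, xbar = xbar)
  }

  beta <- rep(0, p)
  si <- score_info(beta)
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(si$I, si$U), error = function(e)
      abort("coxph_breslow: singular information matrix"))
    newbeta <- beta + step
    newsi <- score_info(newbeta)
    halvings <- 0
    while ((!is.finite(newsi$ll) || newsi$ll < si$ll - 1e-10) &&
           halvings < 20) {
      step <- step / 2
      newbeta <- beta + step
      newsi <- score_info(newbeta)
      halvings <- halvings + 1
    }
    if (any(abs(newbeta) > 15)) {
      worst <- colnames(X)[which.max(abs(newbeta))]
      if (diverge == "drop" && ncol(X) > 1) {
        warn(paste0("coxph_breslow: dropping '", worst,
                    "' (diverging coefficient)"))
        fit <- coxph_breslow(X[, colnames(X) != worst, drop = FALSE],
                             time, status, weights = w, robust = robust,
                             max_iter = max_iter, tol = tol,
                             diverge = diverge)
        fit$dropped <- c(dropped, worst, fit$dropped)
        return(fit)
      }
      abort(paste0("coxph_breslow: coefficient for '", worst,
                   "' diverging (possible separation / monotone likelihood)"))
    }
    done <- sqrt(sum((newbeta - beta)^2)) < tol ||
      abs(newsi$ll - si$ll) < tol * (abs(si$ll) + 1)
    beta <- newbeta; si <- newsi
    if (done) break
    if (it == max_iter) {
      abort(sprintf(
        "coxph_breslow: no convergence in %d iterations (loglik %.4f)",
        max_iter, si$ll))
    }
  }
  vcov <- solve(si$I)

  robust_vcov <- NULL
  if (robust) {
    # score residuals -> dfbeta -> sandwich
    h <- ifelse(s_s == 1, w_s / si$S0, 0)
    A <- cumsum(h)[last]
    B <- apply(h * si$xbar, 2, cumsum)[last, , drop = FALSE]
    Ures <- s_s * (X_s - si$xbar) -
      (si$r / w_s) * (X_s * A - B)
    dfbeta <- (w_s * Ures) %*% vcov
    robust_vcov <- crossprod(dfbeta)
  }

  eta_full <- drop(X %*% beta)
  base <- breslow_baseline(eta_full, time, status, weights = w)
  names(beta) <- colnames(X)
  structure(list(coef = beta, vcov = vcov, robust_vcov = robust_vcov,
                 loglik = si$ll, iter = it, baseline = base,
                 dropped = dropped),
            class = "bime_coxfit")
}

#' @export
print.bime_coxfit <- function(x, ...) {
  cat("Cox PH fit (Breslow), loglik", format(x$loglik), "\n")
  print(tidy.bime_coxfit(x))
  invisible(x)
}

#' @rdname coxph_breslow
#' @param x A `bime_coxfit`.
#' @param ... Unused.
#' @export
tidy.bime_coxfit <- function(x, ...) {
  V <- if (!is.null(x$robust_vcov)) x$robust_vcov else x$vcov
  se <- sqrt(diag(V))
  tibble(term = names(x$coef), estimate = unname(x$coef),
         std.error = unname(se),
         statistic = unname(x$coef / se),
         p.value = 2 * pnorm(-abs(unname(x$coef / se))))
}

#' @rdname coxph_breslow
#' @export
glance.bime_coxfit <- function(x, ...) {
  tibble(logLik = x$loglik, n.iter = x$iter, n.term = length(x$coef),
         robust = !is.null(x$robust_vcov))
}
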