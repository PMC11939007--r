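# Entropic optimal transport between the latent representations of the two
# treatment arms. The penalty is the (optionally debiased) transport cost of
# the Sinkhorn plan with ground cost |x - y|^p; gradients are taken with the
# plan held fixed (envelope approximation), which is the standard practice
# when the penalty is minimized jointly with other losses.

pairwise_cost <- function(x, y, p = 2) {
  x <- as.matrix(x); y <- as.matrix(y)
  d2 <- outer(rowSums(x^2), rep(1, nrow(y))) +
    outer(rep(1, nrow(x)), rowSums(y^2)) - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  if (p == 2) d2 else sqrt(d2)^p
}

row_max <- function(M) M[cbind(seq_len(nrow(M)), max.col(M, "first"))]

# log-domain Sinkhorn with uniform marginals; returns the plan and the
# primal transport cost <P, C>
sinkhorn_plan <- function(C, epsilon, max_iter = 40, tol = 1e-5) {
  n <- nrow(C); m <- ncol(C)
  loga <- -log(n); logb <- -log(m)
  f <- rep(0, n); g <- rep(0, m)
  K <- -C / epsilon
  Kt <- t(K)
  for (it in seq_len(max_iter)) {
    f_old <- f
    # f_i = -eps * logsumexp_j((g_j - C_ij)/eps) + eps*loga
    M <- K + rep(g / epsilon, each = n)
    rmax <- row_max(M)
    f <- -epsilon * (rmax + log(rowSums(exp(M - rmax)))) + epsilon * loga
    Mt <- Kt + rep(f / epsilon, each = m)
    cmax <- row_max(Mt)
    g <- -epsilon * (cmax + log(rowSums(exp(Mt - cmax)))) + epsilon * logb
    if (max(abs(f - f_old)) < tol * epsilon) break
  }
  P <- exp(K + rep(f / epsilon, times = m) + rep(g / epsilon, each = n))
  list(plan = P, cost = sum(P * C))
}

#' Entropic optimal-transport distance between arm representations
#'
#' Smoothed (entropy-regularized) optimal-transport divergence between two
#' point clouds with ground cost `|x - y|^p` and uniform marginals. With
#' `debias = TRUE` the two self-transport costs are subtracted, so the
#' divergence is ~0 when the clouds coincide. Used as the representation
#' balancing (IPM) penalty.
#'
#' @param x1,x0 Numeric matrices (points in rows): treated and control
#'   latent representations.
#' @param p Order of the ground cost (default 2: squared Euclidean).
#' @param epsilon Entropic regularization; default `0.1 *` median pairwise
#'   cross-distance (recomputed per call).
#' @param debias Subtract self-transport costs (default `TRUE`).
#' @param grad Also return gradients with respect to the rows of `x1` and
#'   `x0` (plan held fixed).
#' @param max_iter,tol Sinkhorn iteration controls (the training loop uses
#'   looser settings than these defaults).
#' @return The scalar divergence; if `grad = TRUE`, attributes `grad_x1`
#'   and `grad_x0` hold the gradients. Returns 0 with a warning if either
#'   set is empty.
#' @export
ipm_distance <- function(x1, x0, p = 2, epsilon = NULL, debias = TRUE,
                         grad = FALSE, max_iter = 300, tol = 1e-9) {
  x1 <- as.matrix(x1); x0 <- as.matrix(x0)
  if (nrow(x1) == 0 || nrow(x0) == 0) {
    warn("ipm_distance: one arm empty; penalty contribution 0")
    out <- 0
    if (grad) {
      attr(out, "grad_x1") <- matrix(0, nrow(x1), ncol(x1))
      attr(out, "grad_x0") <- matrix(0, nrow(x0), ncol(x0))
    }
    return(out)
  }
  C10 <- pairwise_cost(x1, x0, p)
  if (is.null(epsilon)) {
    med <- median(C10[C10 > 0])
    if (!is.finite(med) || med <= 0) med <- 1
    epsilon <- 0.1 * med
  }
  s10 <- sinkhorn_plan(C10, epsilon, max_iter, tol)
  val <- s10$cost
  s11 <- s00 <- NULL
  if (debias) {
    s11 <- sinkhorn_plan(pairwise_cost(x1, x1, p), epsilon, max_iter, tol)
    s00 <- sinkhorn_plan(pairwise_cost(x0, x0, p), epsilon, max_iter, tol)
    val <- val - 0.5 * s11$cost - 0.5 * s00$cost
  }
  val <- max(val, 0)
  if (!grad) return(val)

  cost_grad <- function(P, a, b) {
    # d/d a_i of sum_ij P_ij |a_i - b_j|^p (P fixed)
    pr <- rowSums(P)
    if (p == 2) {
      2 * (pr * a - P %*% b)
    } else {
      g <- matrix(0, nrow(a), ncol(a))
      for (j in seq_len(nrow(b))) {
        d <- sweep(a, 2, b[j, ], `-`)
        nd <- sqrt(rowSums(d^2))
        coef <- P[, j] * p * pmax(nd, 1e-12)^(p - 2)
        g <- g + coef * d
      }
      g
    }
  }
  g1 <- cost_grad(s10$plan, x1, x0)
  g0 <- cost_grad(t(s10$plan), x0, x1)
  if (debias) {
    # both arguments of each self term move: symmetric plan doubles the
    # one-sided gradient
    g1 <- g1 - 0.5 * 2 * cost_grad(s11$plan, x1, x1)
    g0 <- g0 - 0.5 * 2 * cost_grad(s00$plan, x0, x0)
  }
  attr(val, "grad_x1") <- g1
  attr(val, "grad_x0") <- g0
  val
}
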