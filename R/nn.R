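# Minimal multilayer-perceptron machinery: Xavier init, forward pass with
# cached pre-activations, exact backprop, Adam updates. All internal; the
# networks involved are small (a shared encoder plus per-arm linear gate
# and component heads), so plain BLAS-backed matrix ops are fast enough.

act_fun <- function(name) {
  switch(name,
    tanh = list(f = tanh, df = function(a) 1 - a^2),          # df from output
    relu = list(f = function(x) pmax(x, 0),
                df = function(a) (a > 0) * 1),
    linear = list(f = identity, df = function(a) 1),
    abort(paste("unknown activation:", name)))
}

# sizes: c(in, hidden..., out); hidden layers use `activation`, the output
# layer is linear
nn_init <- function(sizes, activation = "tanh") {
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    layers[[l]] <- list(
      W = matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
      b = rep(0, fan_out))
  }
  structure(list(layers = layers, activation = activation), class = "bime_mlp")
}

nn_forward <- function(net, X, dropout = 0, training = FALSE) {
  L <- length(net$layers)
  a <- act_fun(net$activation)
  H <- X
  cache <- list(inputs = vector("list", L), acts = vector("list", L),
                masks = vector("list", L))
  for (l in seq_len(L)) {
    cache$inputs[[l]] <- H
    Z <- sweep(H %*% net$layers[[l]]$W, 2, net$layers[[l]]$b, `+`)
    H <- if (l < L) a$f(Z) else Z
    cache$acts[[l]] <- H  # pre-dropout activation (for the derivative)
    if (l < L && training && dropout > 0) {
      mask <- matrix(rbinom(length(H), 1, 1 - dropout) / (1 - dropout),
                     nrow(H), ncol(H))
      H <- H * mask
      cache$masks[[l]] <- mask
    }
  }
  list(out = H, cache = cache)
}

# dout: gradient w.r.t. network output; returns per-layer grads and dX
nn_backward <- function(net, cache, dout) {
  L <- length(net$layers)
  a <- act_fun(net$activation)
  grads <- vector("list", L)
  delta <- dout
  for (l in rev(seq_len(L))) {
    if (l < L) {
      if (!is.null(cache$masks[[l]])) delta <- delta * cache$masks[[l]]
      delta <- delta * a$df(cache$acts[[l]])
    }
    grads[[l]] <- list(W = crossprod(cache$inputs[[l]], delta),
                       b = colSums(delta))
    delta <- tcrossprod(delta, net$layers[[l]]$W)
  }
  list(grads = grads, dX = delta)
}

# --- generic Adam over nested numeric lists ---------------------------------

map_params <- function(f, ...) {
  xs <- list(...)
  if (is.list(xs[[1]])) {
    out <- purrr::pmap(xs, function(...) map_params(f, ...))
    names(out) <- names(xs[[1]])
    out
  } else do.call(f, xs)
}

adam_init <- function(params) {
  list(m = map_params(function(x) x * 0, params),
       v = map_params(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_params(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- map_params(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- map_params(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}
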