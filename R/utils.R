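#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom stats plogis qlogis rnorm rbinom runif rweibull rexp rmultinom
#'   quantile median sd var weighted.mean coef glm binomial lm predict
#'   pnorm qnorm
NULL

# round-half-up at `digits` decimals (base round() is half-to-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# draw a seed for a named sub-stream from a master seed, reproducibly and
# independently of the global RNG state
substream_seed <- function(master, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(master) * 69069 + h * 7919) %% 2147483647L)
}

# run expr with a local RNG seed, restoring the global state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

is_flag01 <- function(x) is.numeric(x) && all(x %in% c(0, 1))
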