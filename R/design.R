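# Covariate design matrix shared by every model in the package: numeric
# columns standardized with training-set statistics, categorical columns
# dummy-coded against their full dictionary level sets (so train and test
# matrices always align).

#' Default modelling covariates
#'
#' The covariate set used by the survival models and (minus `nst`) close to
#' the default propensity adjustment set: age, tumor size, grade, T/N/M
#' stage, receptor status, axillary-node status and neoadjuvant treatment.
#'
#' @return Character vector of cohort column names.
#' @export
default_covariates <- function() {
  c("age", "tumor_size", "grade", "t_stage", "n_stage", "m_stage",
    "er_positive", "pr_positive", "her2_positive", "aln_positive", "nst")
}

#' Default propensity adjustment covariates
#'
#' Variables known to influence prognosis or the treatment decision: age,
#' receptor subtype, grade, axillary lymph-node status and TNM stage.
#'
#' @return Character vector of cohort column names.
#' @export
default_adjustment_covariates <- function() {
  c("age", "er_positive", "pr_positive", "her2_positive", "grade",
    "aln_positive", "tnm_stage")
}

# returns list(X, stats); pass `stats` back in to reuse training
# standardization on new data
design_matrix <- function(data, covariates = default_covariates(),
                          stats = NULL) {
  miss <- setdiff(covariates, names(data))
  if (length(miss) > 0) {
    abort(paste("design_matrix: missing covariate(s):",
                paste(miss, collapse = ", ")))
  }
  cols <- list()
  for (v in covariates) {
    x <- data[[v]]
    if (v %in% names(cohort_levels)) {
      lev <- cohort_levels[[v]]
      f <- factor(as.character(x), levels = lev)
      if (anyNA(f)) abort(paste0("design_matrix: unknown level in '", v, "'"))
      m <- matrix(0, length(f), length(lev) - 1L,
                  dimnames = list(NULL, paste0(v, lev[-1])))
      for (j in seq_along(lev)[-1]) m[, j - 1L] <- as.numeric(f == lev[j])
      cols[[v]] <- m
    } else {
      cols[[v]] <- matrix(as.numeric(x), ncol = 1,
                          dimnames = list(NULL, v))
    }
  }
  X <- do.call(cbind, cols)
  if (is.null(stats)) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    # keep dummies and near-constant columns on their native scale
    binary <- apply(X, 2, function(col) all(col %in% c(0, 1)))
    ctr[binary] <- 0
    scl[binary | scl < 1e-12] <- 1
    stats <- list(center = ctr, scale = scl, columns = colnames(X),
                  covariates = covariates)
  } else {
    X <- X[, stats$columns, drop = FALSE]
  }
  X <- sweep(sweep(X, 2, stats$center, `-`), 2, stats$scale, `/`)
  list(X = X, stats = stats)
}

# arm x event stratified split; returns logical vector (TRUE = second part)
strat_split <- function(keys, frac2, seed) {
  with_seed(seed, {
    out <- logical(length(keys))
    for (k in unique(keys)) {
      idx <- which(keys == k)
      n2 <- round(length(idx) * frac2)
      out[sample(idx, n2)] <- TRUE
    }
    out
  })
}
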