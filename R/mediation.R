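# Downstream causal analyses: the effect of neoadjuvant systemic treatment
# (NST) on the model's surgical recommendation ("downgrading", overall and
# per stage group), and a linear-specification mediation decomposition of
# the recommendation's protective effect into natural direct and indirect
# components.

#' Effect of NST on the recommended surgical extent
#'
#' For each subgroup (all patients plus the EBC/LABC/MBC stage groups),
#' computes the risk difference `P(rec = NSM | NST = 1) - P(rec = NSM |
#' NST = 0)`, raw and IPTW-adjusted with NST as the exposure (propensity
#' fitted on `covariates` within the subgroup). CIs are nonparametric
#' bootstrap.
#'
#' @param recs A recommendation tibble ([recommend()] output) aligned with
#'   `data`.
#' @param data The cohort (must contain `nst` and the stage columns).
#' @param covariates Adjustment covariates for the NST propensity.
#' @param n_boot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @param level Confidence level.
#' @param iib_policy Residual stage-IIB routing for [derive_stage_group()].
#' @return A tibble of class `bime_downgrade`: one row per subgroup with
#'   `rd_pct`, `rd_adj_pct` and their CIs, and the NST stratum sizes.
#' @export
nst_downgrading <- function(recs, data,
                            covariates = default_adjustment_covariates(),
                            n_boot = 500, seed = 1, level = 0.95,
                            iib_policy = "EBC") {
  stopifnot(nrow(recs) == nrow(data), "nst" %in% names(data))
  data <- derive_stage_group(data, iib_policy)
  rec_nsm <- as.integer(recs$recommended == 0)
  groups <- list(all = rep(TRUE, nrow(data)),
                 EBC = data$stage_group == "EBC",
                 LABC = data$stage_group == "LABC",
                 MBC = data$stage_group == "MBC")
  z <- qnorm(1 - (1 - level) / 2)

  one_group <- function(sel, label) {
    d <- data[sel, ]
    r <- rec_nsm[sel]
    n1 <- sum(d$nst == 1); n0 <- sum(d$nst == 0)
    if (n1 == 0 || n0 == 0) {
      warn(sprintf("nst_downgrading: empty NST stratum in subgroup %s; skipped",
                   label))
      return(NULL)
    }
    rd_fun <- function(dd, rr) {
      raw <- 100 * (mean(rr[dd$nst == 1]) - mean(rr[dd$nst == 0]))
      adj <- tryCatch({
        w <- iptw_weights(fit_propensity(dd, "nst", covariates))
        100 * (weighted.mean(rr[dd$nst == 1], w[dd$nst == 1]) -
                 weighted.mean(rr[dd$nst == 0], w[dd$nst == 0]))
      }, error = function(e) NA_real_)
      c(raw, adj)
    }
    est <- rd_fun(d, r)
    boot <- with_seed(substream_seed(seed, paste0("downgrade_", label)), {
      replicate(n_boot, {
        idx <- sample.int(nrow(d), replace = TRUE)
        if (length(unique(d$nst[idx])) < 2) return(c(NA_real_, NA_real_))
        rd_fun(d[idx, ], r[idx])
      })
    })
    qs <- apply(boot, 1, quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                na.rm = TRUE)
    tibble(subgroup = label, n_nst = n1, n_no_nst = n0,
           rd_pct = est[1], rd_lower = qs[1, 1], rd_upper = qs[2, 1],
           rd_adj_pct = est[2], rd_adj_lower = qs[1, 2],
           rd_adj_upper = qs[2, 2])
  }
  out <- dplyr::bind_rows(purrr::compact(
    purrr::imap(groups, function(sel, label) one_group(sel, label))))
  class(out) <- unique(c("bime_downgrade", class(out)))
  attr(out, "level") <- level
  out
}

#' Linear mediation decomposition (natural direct / indirect effect)
#'
#' Product-of-coefficients mediation with a linear outcome model:
#' `outcome ~ exposure + mediator + covariates` yields the natural direct
#' effect (NDE, the exposure slope) and the mediator slope `b`;
#' `mediator ~ exposure + covariates` yields the exposure-to-mediator slope
#' `a`; the natural indirect effect is `NIE = a * b` and the total effect
#' `NDE + NIE` (which equals the exposure slope of the reduced outcome
#' model exactly, in sample). CIs are nonparametric bootstrap.
#'
#' @param data Data frame.
#' @param exposure,mediator Column names of binary exposure and mediator.
#' @param outcome Column name of the numeric outcome. The outcome scale is
#'   whatever this column carries (e.g. a 10-year event indicator, or
#'   survival months); it is recorded in the result.
#' @param covariates Confounder adjustment set.
#' @param n_boot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @param level Confidence level.
#' @return A one-row tibble of class `bime_mediation`: `nde`, `nie`,
#'   `total` with CIs, plus `a`, `b` and `outcome` (the column name).
#' @export
mediation_nde <- function(data, exposure, mediator, outcome,
                          covariates = default_adjustment_covariates(),
                          n_boot = 500, seed = 1, level = 0.95) {
  ex <- data[[exposure]]; me <- data[[mediator]]; y <- data[[outcome]]
  stopifnot(is_flag01(ex), is_flag01(me), is.numeric(y))
  if (sd(ex) == 0 || sd(me) == 0 ||
      isTRUE(abs(stats::cor(ex, me)) > 0.999)) {
    abort("mediation_nde: exposure and mediator are collinear or constant")
  }
  X <- if (length(covariates) > 0) design_matrix(data, covariates)$X else
    NULL
  fit_paths <- function(ex, me, y, X) {
    d_out <- data.frame(y = y, ex = ex, me = me)
    d_med <- data.frame(me = me, ex = ex)
    if (!is.null(X)) {
      d_out <- cbind(d_out, X)
      d_med <- cbind(d_med, X)
    }
    f_out <- lm(y ~ ., data = d_out)
    f_med <- lm(me ~ ., data = d_med)
    nde <- coef(f_out)[["ex"]]
    b <- coef(f_out)[["me"]]
    a <- coef(f_med)[["ex"]]
    c(nde = nde, nie = a * b, a = a, b = b)
  }
  est <- fit_paths(ex, me, y, X)
  boot <- with_seed(substream_seed(seed, "mediation"), {
    replicate(n_boot, {
      idx <- sample.int(length(ex), replace = TRUE)
      tryCatch(fit_paths(ex[idx], me[idx], y[idx],
                         if (is.null(X)) NULL else X[idx, , drop = FALSE]),
               error = function(e) rep(NA_real_, 4))
    })
  })
  qs <- apply(boot, 1, quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
  tot_boot <- boot[1, ] + boot[2, ]
  tot_ci <- quantile(tot_boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                     na.rm = TRUE)
  out <- tibble(
    nde = est[["nde"]], nde_lower = qs[1, 1], nde_upper = qs[2, 1],
    nie = est[["nie"]], nie_lower = qs[1, 2], nie_upper = qs[2, 2],
    total = est[["nde"]] + est[["nie"]],
    total_lower = tot_ci[[1]], total_upper = tot_ci[[2]],
    a = est[["a"]], b = est[["b"]], outcome = outcome)
  class(out) <- unique(c("bime_mediation", class(out)))
  out
}
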