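# Patient-level cohort table: schema, validation, IO, stage groups, summaries.
#
# The cohort is an ordinary tibble, one row per patient, with treatment coded
# 0 = nipple-sparing mastectomy (NSM) and 1 = modified radical mastectomy
# (MRM) throughout the package.

cohort_levels <- list(
  race     = c("White", "Black", "Other"),
  grade    = c("I", "II", "III", "IV"),
  location = c("upper_outer", "upper_inner", "lower_outer", "lower_inner",
               "central_overlapping", "nipple_axillary", "other_unknown"),
  t_stage  = c("T1", "T2", "T3", "T4"),
  n_stage  = c("N0", "N1", "N2", "N3"),
  m_stage  = c("M0", "M1"),
  tnm_stage = c("IA", "IB", "IIA", "IIB", "IIIA", "IIIB", "IIIC", "IV")
)

cohort_flag_cols <- c("married", "income_high", "iib_t3n0", "aln_positive",
                      "er_positive", "pr_positive", "her2_positive", "nst",
                      "treatment", "event_overall", "event_bcss")

cohort_numeric_cols <- c("age", "tumor_size", "followup_months")

#' Column dictionary of a cohort table
#'
#' Returns the data dictionary the cohort CSV format uses: one row per
#' column with its type and, for categorical columns, the allowed levels.
#'
#' @return A tibble with columns `column`, `type`, `levels`.
#' @export
#' @examples
#' cohort_dictionary()
cohort_dictionary <- function() {
  tibble(
    column = c("patient_id", cohort_numeric_cols, names(cohort_levels),
               cohort_flag_cols),
    type = c("character", rep("numeric", length(cohort_numeric_cols)),
             rep("category", length(cohort_levels)),
             rep("flag (0/1)", length(cohort_flag_cols))),
    levels = c(list(NULL), rep(list(NULL), length(cohort_numeric_cols)),
               unname(cohort_levels),
               rep(list(c("0", "1")), length(cohort_flag_cols)))
  )
}

cohort_columns <- function() cohort_dictionary()$column

#' Validate a cohort table
#'
#' Checks the schema (all dictionary columns present, categorical levels
#' known) and the row-level invariants: positive follow-up, breast-cancer
#' death implies overall death, and metastatic stage (M1) if and only if
#' TNM stage IV.
#'
#' @param data A data frame with the columns of [cohort_dictionary()].
#' @return `data` as a validated tibble (invisibly classed `bime_cohort`).
#' @export
validate_cohort <- function(data) {
  data <- as_tibble(data)
  missing_cols <- setdiff(cohort_columns(), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort schema error: missing column(s) ",
                 paste(missing_cols, collapse = ", ")),
          class = "bime_schema_error")
  }
  for (col in names(cohort_levels)) {
    bad <- !is.na(data[[col]]) & !(data[[col]] %in% cohort_levels[[col]])
    if (any(bad)) {
      abort(sprintf(
        "cohort validation error: unknown level '%s' in column '%s' (row %d)",
        data[[col]][which(bad)[1]], col, which(bad)[1]),
        class = "bime_validation_error")
    }
  }
  for (col in cohort_flag_cols) {
    v <- data[[col]]
    bad <- !is.na(v) & !(v %in% c(0, 1))
    if (any(bad)) {
      abort(sprintf(
        "cohort validation error: column '%s' must be 0/1 (row %d)",
        col, which(bad)[1]), class = "bime_validation_error")
    }
  }
  fail <- function(rows, what) {
    if (any(rows, na.rm = TRUE)) {
      abort(sprintf("cohort validation error: %s (row %d)",
                    what, which(rows)[1]),
            class = "bime_validation_error")
    }
  }
  fail(data$followup_months <= 0, "followup_months must be > 0")
  fail(data$event_bcss == 1 & data$event_overall == 0,
       "event_bcss = 1 requires event_overall = 1")
  fail(data$m_stage == "M1" & data$tnm_stage != "IV",
       "m_stage M1 requires tnm_stage IV")
  fail(data$tnm_stage == "IV" & data$m_stage != "M1",
       "tnm_stage IV requires m_stage M1")
  fail(data$age <= 0, "age must be positive")
  fail(data$tumor_size <= 0, "tumor_size must be positive")
  if (anyDuplicated(data$patient_id)) {
    abort("cohort validation error: duplicated patient_id",
          class = "bime_validation_error")
  }
  class(data) <- unique(c("bime_cohort", class(data)))
  data
}

#' Read a cohort CSV
#'
#' Reads a UTF-8 CSV whose header matches [cohort_dictionary()] and
#' validates it.
#'
#' @param path Path to the CSV file.
#' @return A validated cohort tibble.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path) {
  spec <- readr::cols(.default = readr::col_double(),
                      patient_id = readr::col_character())
  for (col in names(cohort_levels)) spec$cols[[col]] <- readr::col_character()
  data <- readr::read_csv(path, col_types = spec, progress = FALSE)
  validate_cohort(data)
}

#' Write a cohort CSV
#'
#' @param data A cohort tibble (validated on the way out).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  data <- validate_cohort(data)
  readr::write_csv(data[, cohort_columns()], path, progress = FALSE)
  invisible(path)
}

#' Derive clinical stage group (EBC / LABC / MBC)
#'
#' Classifies each patient into early (EBC), locally advanced (LABC) or
#' metastatic (MBC) breast cancer. LABC covers stage IIB limited to T3N0
#' plus stages IIIA-IIIC; MBC is metastatic disease (M1 / stage IV); EBC is
#' stages IA, IB and IIA. Stage IIB other than T3N0 (i.e. T2N1) is not
#' covered by either printed definition; `iib_policy` routes it (default
#' `"EBC"`).
#'
#' @param data A cohort tibble (or any data frame with `tnm_stage`,
#'   `m_stage` and `iib_t3n0`).
#' @param iib_policy Where residual stage IIB (T2N1) goes: `"EBC"` or
#'   `"LABC"`.
#' @return `data` with a `stage_group` factor column (`EBC`, `LABC`, `MBC`).
#' @export
derive_stage_group <- function(data, iib_policy = c("EBC", "LABC")) {
  iib_policy <- match.arg(iib_policy)
  stopifnot(all(c("tnm_stage", "m_stage", "iib_t3n0") %in% names(data)))
  grp <- ifelse(
    data$m_stage == "M1", "MBC",
    ifelse(data$tnm_stage %in% c("IIIA", "IIIB", "IIIC"), "LABC",
      ifelse(data$tnm_stage == "IIB",
        ifelse(data$iib_t3n0 == 1, "LABC", iib_policy),
        "EBC")))
  data$stage_group <- factor(grp, levels = c("EBC", "LABC", "MBC"))
  as_tibble(data)
}

#' Wald confidence interval for a proportion
#'
#' Normal-approximation (Wald) interval for a binomial proportion,
#' truncated to `[0, 1]`.
#'
#' @param k Number of successes (events).
#' @param n Number of trials; must be >= 1.
#' @param level Confidence level, strictly between 0 and 1.
#' @return A tibble with columns `estimate`, `lower`, `upper` (proportions,
#'   not percentages).
#' @export
#' @examples
#' proportion_ci(8301, 38159)  # overall mortality with its 95% CI
proportion_ci <- function(k, n, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (any(n < 1)) abort("proportion_ci: n must be >= 1")
  if (any(k < 0 | k > n)) abort("proportion_ci: need 0 <= k <= n")
  p <- k / n
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(p * (1 - p) / n)
  tibble(estimate = p, lower = clip(p - z * se, 0, 1),
         upper = clip(p + z * se, 0, 1))
}

summarize_flag <- function(x) {
  tibble(n = sum(x == 1, na.rm = TRUE),
         pct = round_half_up(100 * mean(x == 1, na.rm = TRUE), 1))
}

#' Descriptive cohort summary
#'
#' Counts and percentages (1 decimal, half-up) for every categorical and
#' flag column, means/SDs for continuous columns, and overall plus
#' breast-cancer-specific mortality rates with Wald 95% CIs — pooled and
#' per treatment arm.
#'
#' @param data A cohort tibble.
#' @param level Confidence level for mortality CIs.
#' @return A list of class `bime_cohort_summary` with elements
#'   `sizes`, `continuous`, `categorical`, `mortality`.
#' @export
summarize_cohort <- function(data, level = 0.95) {
  data <- validate_cohort(data)
  if (nrow(data) == 0) abort("summarize_cohort: empty cohort")
  arms <- list(pooled = data,
               NSM = data[data$treatment == 0, ],
               MRM = data[data$treatment == 1, ])

  sizes <- tibble(group = names(arms),
                  n = unname(vapply(arms, nrow, integer(1))))

  cont <- purrr::map_dfr(names(arms), function(g) {
    d <- arms[[g]]
    purrr::map_dfr(cohort_numeric_cols, function(col) {
      tibble(group = g, variable = col,
             mean = if (nrow(d)) mean(d[[col]]) else NA_real_,
             sd = if (nrow(d) > 1) sd(d[[col]]) else NA_real_,
             median = if (nrow(d)) median(d[[col]]) else NA_real_)
    })
  })

  cat_cols <- c(names(cohort_levels),
                setdiff(cohort_flag_cols,
                        c("treatment", "event_overall", "event_bcss")))
  cats <- purrr::map_dfr(names(arms), function(g) {
    d <- arms[[g]]
    purrr::map_dfr(cat_cols, function(col) {
      lev <- if (col %in% names(cohort_levels)) cohort_levels[[col]]
             else c("0", "1")
      x <- factor(as.character(d[[col]]), levels = lev)
      cnt <- table(x)
      tibble(group = g, variable = col, level = names(cnt),
             n = as.integer(cnt),
             pct = if (nrow(d)) round_half_up(100 * as.integer(cnt) / nrow(d), 1)
                   else NA_real_)
    })
  })

  mortality <- purrr::map_dfr(names(arms), function(g) {
    d <- arms[[g]]
    purrr::map_dfr(c(overall = "event_overall", bcss = "event_bcss"),
                   function(col) {
      if (nrow(d) == 0) {
        return(tibble(group = g, outcome = col, deaths = NA_integer_,
                      n = 0L, rate_pct = NA_real_, lower_pct = NA_real_,
                      upper_pct = NA_real_))
      }
      ci <- proportion_ci(sum(d[[col]]), nrow(d), level)
      tibble(group = g, outcome = col, deaths = as.integer(sum(d[[col]])),
             n = nrow(d),
             rate_pct = round_half_up(100 * ci$estimate, 1),
             lower_pct = round_half_up(100 * ci$lower, 1),
             upper_pct = round_half_up(100 * ci$upper, 1))
    })
  })
  mortality$outcome <- rep(c("overall", "bcss"), length(arms))

  structure(list(sizes = sizes, continuous = cont, categorical = cats,
                 mortality = mortality, level = level),
            class = "bime_cohort_summary")
}

#' @export
print.bime_cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  print(x$sizes)
  cat("\nMortality (%, with", paste0(100 * x$level, "%"), "Wald CI):\n")
  print(x$mortality)
  invisible(x)
}

#' @rdname summarize_cohort
#' @param x A `bime_cohort_summary`.
#' @param ... Unused.
#' @export
tidy.bime_cohort_summary <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$mortality, what = "mortality"),
    dplyr::mutate(x$categorical, what = "categorical")
  )
}

#' Export a cohort summary as JSON
#'
#' @param x A `bime_cohort_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  stopifnot(inherits(x, "bime_cohort_summary"))
  jsonlite::write_json(lapply(unclass(x), function(el) el),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
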