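# Orchestration: stratified train/test splitting and a config-driven
# pipeline (simulate / fit / recommend / evaluate / downgrade / mediate)
# whose artifacts embed the seed and a hash of the configuration. The
# command-line entry point in inst/cli/bime is a thin wrapper over
# run_pipeline().

#' Stratified train/test split
#'
#' Randomly partitions a cohort into training and test sets, stratified by
#' treatment arm and event indicator so arm shares and event counts stay
#' stable. Strata smaller than 2 fall back to a simple random split with a
#' warning.
#'
#' @param data Cohort tibble.
#' @param fractions Named numeric vector `c(train = , test = )` summing
#'   to 1.
#' @param seed Split seed.
#' @return A list with `train` and `test` tibbles (disjoint, exhaustive).
#' @export
split_cohort <- function(data, fractions = c(train = 0.7, test = 0.3),
                         seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions > 0))
  keys <- paste(data$treatment, data$event_overall)
  if (min(table(keys)) < 2) {
    warn("split_cohort: stratum too small; simple random split")
    keys <- rep("all", nrow(data))
  }
  test <- strat_split(keys, fractions[["test"]], seed)
  list(train = data[!test, ], test = data[test, ])
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  # small stable checksum over the serialized config
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 1e9
  sprintf("%09d", h)
}

pipeline_log <- function(dir, config, lines) {
  writeLines(c(
    sprintf("bime pipeline | seed=%s | config_hash=%s | time=%s",
            config$seed, config_hash(config),
            format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    "config:",
    strsplit(yaml::as.yaml(config), "\n")[[1]],
    lines), file.path(dir, "run.log"))
}

#' Run a pipeline step from a configuration
#'
#' Executes one subcommand with a configuration list (typically read from
#' YAML): `simulate` writes a synthetic cohort + ground truth;
#' `fit` trains a model and saves its recommendations for the held-out
#' split; `recommend` scores a cohort with a guideline rule; `evaluate`
#' computes the Consis/Inconsis metrics report; `downgrade` and `mediate`
#' run the NST and mediation analyses on saved recommendations. Every
#' artifact directory receives a `run.log` embedding the seed and config
#' hash.
#'
#' @param config A list with at least `command`, `out` (output directory)
#'   and `seed`; remaining fields depend on the subcommand (see the
#'   package vignette).
#' @return A list of produced artifact paths, invisibly.
#' @export
run_pipeline <- function(config) {
  req <- c("command", "out", "seed")
  miss <- setdiff(req, names(config))
  if (length(miss) > 0) {
    abort(paste("run_pipeline: missing config field(s):",
                paste(miss, collapse = ", ")))
  }
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  out <- config$out
  artifacts <- character(0)
  log_lines <- character(0)

  read_in <- function(field = "input") {
    if (is.null(config[[field]])) {
      abort(paste0("run_pipeline: config field '", field, "' required"))
    }
    read_cohort(config[[field]])
  }

  switch(config$command,
    simulate = {
      cfg_args <- config$sim %||% list()
      cfg_args$seed <- config$seed
      sim <- generate_cohort(do.call(sim_config, cfg_args))
      write_sim(sim, out)
      artifacts <- file.path(out, c("cohort.csv", "truth.csv",
                                    "sim_config.yaml"))
      log_lines <- sprintf("simulated %d patients", nrow(sim$cohort))
    },
    fit = {
      cohort <- read_in()
      sp <- split_cohort(cohort,
                         c(train = config$train_frac %||% 0.7,
                           test = 1 - (config$train_frac %||% 0.7)),
                         seed = config$seed)
      ctrl_args <- config$control %||% list()
      ctrl_args$seed <- config$seed
      spec <- make_baseline(config$model %||% "bime",
                            do.call(bime_control, ctrl_args))
      model <- fit_model(spec, sp$train)
      recs <- recommend(model, sp$test,
                        threshold = config$threshold %||% 0.10,
                        cap = config$cap %||% 120)
      write_recommendations(recs, file.path(out, "recommendations.csv"))
      write_cohort(sp$test, file.path(out, "test_cohort.csv"))
      if (inherits(model, "bime_fit")) {
        readr::write_csv(model$history, file.path(out, "history.csv"),
                         progress = FALSE)
      }
      artifacts <- file.path(out, c("recommendations.csv",
                                    "test_cohort.csv"))
      log_lines <- sprintf("fit %s on %d, scored %d",
                           config$model %||% "bime", nrow(sp$train),
                           nrow(sp$test))
    },
    recommend = {
      cohort <- read_in()
      spec <- make_baseline(config$model %||% "nccn")
      if (spec$name != "nccn") {
        abort("run_pipeline: 'recommend' without fitting supports rule models only")
      }
      model <- fit_model(spec, cohort)
      recs <- recommend(model, cohort)
      write_recommendations(recs, file.path(out, "recommendations.csv"))
      artifacts <- file.path(out, "recommendations.csv")
      log_lines <- sprintf("scored %d patients with %s", nrow(cohort),
                           spec$name)
    },
    evaluate = {
      cohort <- read_in()
      recs <- readr::read_csv(config$recommendations,
                              col_types = readr::cols(), progress = FALSE)
      m <- evaluate_recommendation(NULL, cohort, recs = recs,
                                   tau = config$tau %||% 120,
                                   n_boot = config$n_boot %||% 500,
                                   seed = config$seed)
      write_metrics(m, file.path(out, "metrics.json"),
                    csv = file.path(out, "metrics.csv"))
      artifacts <- file.path(out, c("metrics.json", "metrics.csv"))
      log_lines <- sprintf("evaluated %d patients", nrow(cohort))
    },
    downgrade = {
      cohort <- read_in()
      recs <- readr::read_csv(config$recommendations,
                              col_types = readr::cols(), progress = FALSE)
      dg <- nst_downgrading(recs, cohort,
                            n_boot = config$n_boot %||% 500,
                            seed = config$seed)
      readr::write_csv(dg, file.path(out, "downgrading.csv"),
                       progress = FALSE)
      jsonlite::write_json(dg, file.path(out, "downgrading.json"),
                           auto_unbox = TRUE, digits = NA)
      artifacts <- file.path(out, c("downgrading.csv", "downgrading.json"))
      log_lines <- "downgrading analysis written"
    },
    mediate = {
      cohort <- read_in()
      recs <- readr::read_csv(config$recommendations,
                              col_types = readr::cols(), progress = FALSE)
      consis <- as.integer(recs$recommended == cohort$treatment)
      tau <- config$tau %||% 120
      cohort$event_10y <- as.integer(cohort$event_overall == 1 &
                                       cohort$followup_months <= tau)
      cohort$consis <- consis
      md <- mediation_nde(cohort, "consis", "treatment",
                          config$outcome %||% "event_10y",
                          n_boot = config$n_boot %||% 500,
                          seed = config$seed)
      readr::write_csv(md, file.path(out, "mediation.csv"),
                       progress = FALSE)
      artifacts <- file.path(out, "mediation.csv")
      log_lines <- "mediation analysis written"
    },
    abort(paste("run_pipeline: unknown command:", config$command))
  )
  pipeline_log(out, config, log_lines)
  invisible(c(artifacts, file.path(out, "run.log")))
}
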