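# bime

Individual treatment effects for right-censored survival data, estimated
with a representation-balanced Cox mixture — plus everything needed to
*evaluate* a treatment-recommendation rule on observational data.

## The problem

Should a breast-cancer patient receive nipple-sparing mastectomy (NSM,
arm 0) or modified radical mastectomy (MRM, arm 1)? With no randomized
trials, the question has to be answered from registry cohorts in which
assignment is confounded, survival is right-censored, and the better arm
differs across latent clinical subgroups. `bime` implements:

- **BIME**, a two-arm (T-learner) Cox mixture: a shared encoder Φ(x) feeds
  per-arm gating networks over K latent components and per-component
  log-hazard heads, each with its own Breslow baseline:

  S(t | x, T) = Σₖ gᵏᵀ(Φ) · exp(−Λᵏᵀ(t) · exp(fᵏᵀ(Φ)))

  The encoder is balanced across arms by an entropic optimal-transport
  (p-Wasserstein IPM) penalty, and the batch loss decomposes as

  q·lCox⁰ + (1−q)·lCox¹ + α·IPM(Φ₁, Φ₀) + Q⁰ + Q¹

  fitted by Monte-Carlo EM (posterior-sampled component assignments,
  posterior-weighted Breslow baselines, Adam M-steps, early stopping).
- The clinical contrast: **time at risk** TaR = first time S(t|x, arm)
  falls to 0.10, capped at 120 months; ITE = TaR(MRM) − TaR(NSM);
  recommend MRM iff ITE > 0 (ties → the less invasive NSM).
- Comparators in the same interface: linear Cox T-learner, DeepSurv-style
  (K = 1, α = 0, per-arm encoders), BITES-style (K = 1, α > 0, shared
  encoder), an NCCN-note eligibility rule, and a ground-truth oracle for
  synthetic cohorts.
- The evaluation framework: propensity scores, stabilized IPTW, 1:1
  greedy propensity matching, SMD balance tables, (weighted) Kaplan-Meier
  and log-rank, restricted mean survival time, risk differences, weighted
  Cox hazard ratios with sandwich CIs, IPCW integrated Brier scores, the
  Consis/Inconsis report, NST surgical-downgrading risk differences, and
  linear NDE/NIE mediation.
- A synthetic SEER-like cohort generator with known ground truth
  (confounded assignment, two opposite-benefit latent subgroups, ~35%
  censoring), so the whole pipeline is testable without gated data.

## A worked example

```r
library(bime)

sim <- generate_cohort(sim_config(n = 4000, seed = 1))   # cohort + truth
sp  <- split_cohort(sim$cohort, c(train = 0.7, test = 0.3), seed = 1)

fit  <- bime_fit(sp$train, control = bime_control(seed = 1))
recs <- recommend(fit, sp$test)

truth <- true_tar_ite(sim, sp$test$patient_id)
mean(recs$recommended == as.integer(truth$ite > 0))
#> [1] 0.915

report <- evaluate_recommendation(fit, sp$test, seed = 1, recs = recs)
tidy(report)
#> # A tibble: 8 × 4
#>   metric    estimate  lower  upper
#>   <chr>        <dbl>  <dbl>  <dbl>
#> 1 hr           0.378  0.325  0.439
#> 2 hr_adj       0.376  0.322  0.439
#> 3 rd          16.8   11.4   21.7
#> 4 rd_adj      17.3   12.3   21.9
#> 5 drmst       28.9   24.1   33.4
#> 6 drmst_adj   29.8   25.3   34.4
#> 7 ibs_nsm      0.166 NA     NA
#> 8 ibs_mrm      0.147 NA     NA
```

Reading: the fitted model's recommended arm matches the sign of the true
individual effect for 91.5% of held-out patients. Patients who actually
received their recommended arm ("Consis") die at 0.38 times the hazard of
those who did not, are 17 percentage points likelier to be alive at 10
years, and gain ~29 restricted-mean months — essentially unchanged after
inverse-probability weighting, because the recommendation is driven by the
same covariates the weights balance. The integrated Brier scores grade the
per-arm survival curves themselves.

Cohort-level arithmetic works on plain tables too:

```r
proportion_ci(191 + 8110, 4749 + 33410)   # pooled overall mortality
#> # A tibble: 1 × 3
#>   estimate lower upper
#>      <dbl> <dbl> <dbl>
#> 1    0.218 0.213 0.222
```

## Command line

A thin CLI over the same functions lives at `inst/cli/bime`:

```sh
Rscript inst/cli/bime simulate --out runs/sim --seed 1 --n 4000
Rscript inst/cli/bime fit      --input runs/sim/cohort.csv --out runs/fit --seed 1 --model bime
Rscript inst/cli/bime evaluate --input runs/fit/test_cohort.csv \
    --recommendations runs/fit/recommendations.csv --out runs/eval --seed 1
```

Subcommands: `simulate`, `fit`, `recommend`, `evaluate`, `downgrade`,
`mediate`; every output directory gets a `run.log` embedding the seed and
a config hash.

## Documentation

The methods vignette (`vignettes/bime-methods.Rmd`) gives the model, the
loss, the MCEM scheme, what the synthetic generator does and does not
emulate, all numerical choices, and known limitations.
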