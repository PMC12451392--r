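# cullwelfare

Bayesian analysis of animal-welfare outcomes in helicopter-based culling
trials of wild ungulates, for wildlife-management scientists and
veterinary epidemiologists who need the standard welfare metrics — chase
time (CT), time to insensibility (TTI), total time (TT = CT + TTI),
encounter-outcome probabilities, the non-fatal wounding rate (NFWR), and
post-mortem ballistic summaries — with full posterior uncertainty.

## What it implements

* **Time-to-event models.** Exponential (Weibull shape = 1) survival
  models for CT and TTI, pooled or with ammunition type as a categorical
  covariate (`lambda_k = exp(beta0 + beta_k)`). Right-censored TTI values
  (animal out of view at insensibility) enter as latent times confined to
  [observed minimum, maximum observed time] and are re-imputed each sweep
  from the model's own truncated exponential — a proper Gibbs sampler
  whose pooled rate update is the conjugate
  `Gamma(a + n, b + sum(t))`. TT is derived within the model as CT plus
  the observed-or-imputed TTI per sweep, with a second exponential fitted
  to the totals. Percentiles use `-log(1 - q) / lambda`; models with and
  without the covariate are compared by DIC.
* **Encounter outcomes.** One-vs-rest Bayesian logistic regression for
  the four encounter categories (insensible within 1 s, insensible later,
  wounded-escaped, missed), per arm and pooled, plus posterior contrasts
  (`prob_greater`).
* **Wound and pellet models.** Poisson regression for wound tracts per
  carcase; exact conjugate zone-proportion posteriors for pellet
  locations; a binomial-logistic model for the proportion of fired
  pellets never detected on radiographs.
* **MCMC core.** Adaptive per-coordinate random-walk Metropolis (4
  chains, 10,000 draws after 5,000 burn-in by default), shortest-window
  90% HPDIs, the classical Gelman-Rubin statistic, and DIC.
* **Power analysis.** Monte-Carlo power for detecting an increase in TT
  over a log-normal baseline (geometric mean 148 s, 5th/95th percentiles
  50/700 s) with a one-sided two-sample t-test on log-times.
* **Synthetic trial generator.** Randomised blocks of four ammunition
  types over sorties, log-normal CT, exponential TTI, uniform-minimum
  censoring, two-shot-minimum repeat shooting, and pellet accounting with
  a mandatory thorax strike; a packaged 390-animal fixture regenerates
  bit-for-bit from its stored configuration.

## Worked example

```r
library(cullwelfare)

paths <- fixture_paths()                 # packaged synthetic trial
enc <- read_encounters(paths[["encounters"]])
pm  <- read_postmortem(paths[["postmortem"]])

nfwr(enc)
#> [1] 0

fit <- fit_exponential(enc$tti_s, enc$tti_censored,
                       settings = mcmc_settings(seed = 1))
fit$summaries
#>       parameter      mean    hpdi_lo    hpdi_hi      rhat
#> 1 lambda_pooled 0.0683091 0.06189439 0.07465387 0.9999756
mean(surv_percentile(as.vector(fit$rate_draws), 0.95))
#> [1] 43.99789

am <- enc$ammo[match(pm$animal_id, enc$animal_id)]
mp <- fit_missing_pellets(pm, am, settings = mcmc_settings(seed = 1))
mp$summaries[mp$summaries$ammo == "ALL", ]
#>   ammo      mean   hpdi_lo   hpdi_hi     rhat
#> 4  ALL 0.7788343 0.7628161 0.7946244 1.000164
```

The pooled TTI rate of about 0.068 per second says 95% of animals were
insensible within about 44 s of the first shot; the NFWR of 0 records
that no hit animal escaped; and about 78% of fired shotgun pellets were
never found on the radiographs (missed, passed through, or fragmented),
with a 90% HPDI of roughly 0.76-0.79.

A full pipeline run — simulate, fit every model, and produce a text
report of the welfare metrics — is:

```r
run_simulate(system.file("extdata", "trial_config.yaml",
                         package = "cullwelfare"), "out")
run_fit("out/encounters.csv", "out/postmortem.csv", "out/fits")
run_report("out/fits")
```

or from a shell via `inst/scripts/aerialcull.R`
(`simulate` / `fit` / `power` / `report` subcommands).

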