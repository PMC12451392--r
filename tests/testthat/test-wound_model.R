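# Wound-tract, pellet-zone and missing-pellet models.

make_pm <- function(tracts, ammo, detected = NULL, expected = NULL,
                    thorax_share = 0.6) {
  n <- length(tracts)
  zones <- matrix(0L, n, 5)
  if (!is.null(detected)) {
    zones[, 3] <- as.integer(round(detected * thorax_share))
    zones[, 2] <- as.integer(detected - zones[, 3])
  }
  data.frame(
    animal_id = sprintf("P%03d", seq_len(n)),
    wound_tracts = as.integer(tracts),
    pellets_head = zones[, 1], pellets_neck = zones[, 2],
    pellets_thorax = zones[, 3], pellets_abdomen = zones[, 4],
    pellets_limbs = zones[, 5],
    pellets_expected = if (is.null(expected)) 0L else as.integer(expected),
    body_mass_kg = 60, mass_censored = FALSE, exam = "EX_SITU",
    stringsAsFactors = FALSE)
}

test_that("wound-tract means recover the data under a near-flat prior", {
  pm <- make_pm(rep(4L, 40), rep("BUCK_00", 40))
  fit <- fit_wound_tracts(pm, pm_ammo <- rep("BUCK_00", 40),
                          settings = fast_settings(seed = 1,
                                                   n_draws = 4000L))
  v <- fit$mean_tracts_draws[, 1]
  # flat prior on the log mean corresponds to Gamma(sum y, n): mean y-bar
  expect_lt(abs(mean(v) - 4), max(3 * mc_se_batch(v), 0.04))

  # quadrature oracle with the model's own prior
  oracle <- local({
    g <- seq(log(2.5), log(6), length.out = 4001)
    w <- exp(160 * g - 40 * exp(g) - g^2 / (2 * 100) -
               max(160 * g - 40 * exp(g)))
    sum(exp(g) * w) / sum(w)
  })
  expect_lt(abs(mean(v) - oracle), max(3 * mc_se_batch(v), 0.04))
})

test_that("fitted tract means preserve the pellets-per-cartridge ordering", {
  cfg <- sim_config(seed = 41, n_sorties = 8, animals_per_sortie = 60,
                    insitu_fraction = 1, exsitu_fraction = 1)
  enc <- simulate_encounters(cfg)
  pm <- simulate_postmortem(enc, cfg)
  am <- enc$ammo[match(pm$animal_id, enc$animal_id)]
  fit <- fit_wound_tracts(pm, am, settings = fast_settings(seed = 2))
  m <- fit$summaries$mean[match(ammo_types(), fit$summaries$ammo)]
  expect_identical(order(m), 1:4)  # rifle < 00 Buck < 1 Buck < 4 Buck
  expect_error(fit_wound_tracts(pm[am == "BUCK_00", ],
                                am[am == "BUCK_00"][0]), "nrow")
})

test_that("zone proportions form a simplex with sensible limits", {
  # all pellets in the thorax
  pm <- make_pm(rep(5L, 20), rep("BUCK_1", 20), detected = rep(5L, 20),
                expected = rep(32L, 20), thorax_share = 1)
  fit <- fit_zone_proportions(pm, rep("BUCK_1", 20),
                              settings = fast_settings(seed = 3,
                                                       n_draws = 2000L))
  props <- apply(fit$zone_prop_draws[, , 1], 2, mean)
  expect_gt(props[["THORAX"]], 0.97)
  sums <- apply(fit$zone_prop_draws, c(1, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # equal counts across the five zones -> each near 0.2
  pm2 <- make_pm(rep(5L, 30), rep("BUCK_1", 30))
  for (z in c("pellets_head", "pellets_neck", "pellets_thorax",
              "pellets_abdomen", "pellets_limbs")) pm2[[z]] <- 2L
  pm2$pellets_expected <- 32L
  fit2 <- fit_zone_proportions(pm2, rep("BUCK_1", 30),
                               settings = fast_settings(seed = 4,
                                                        n_draws = 2000L))
  expect_true(all(abs(apply(fit2$zone_prop_draws[, , 1], 2, mean) - 0.2)
                  < 0.02))

  pm3 <- make_pm(rep(0L, 10), rep("BUCK_4", 10), detected = rep(0L, 10),
                 expected = rep(54L, 10))
  expect_error(fit_zone_proportions(pm3, rep("BUCK_4", 10)),
               "no pellets detected")
  expect_error(fit_zone_proportions(make_pm(2L, "RIFLE_308"),
                                    "RIFLE_308"), "no shotgun rows")
})

test_that("thorax concentration is highest for the fewest-pellet load", {
  cfg <- sim_config(seed = 43, n_sorties = 12, animals_per_sortie = 60,
                    insitu_fraction = 1, exsitu_fraction = 1)
  enc <- simulate_encounters(cfg)
  pm <- simulate_postmortem(enc, cfg)
  am <- enc$ammo[match(pm$animal_id, enc$animal_id)]
  fit <- fit_zone_proportions(pm, am, settings = fast_settings(seed = 5,
                                                               n_draws = 2000L))
  thorax <- fit$summaries[fit$summaries$zone == "THORAX", ]
  tm <- thorax$mean[match(c("BUCK_00", "BUCK_1", "BUCK_4"), thorax$ammo)]
  expect_identical(order(tm, decreasing = TRUE), 1:3)
})

test_that("missing-pellet model matches its conjugate-style oracle", {
  # detected equals expected everywhere: proportion shrinks to 0 boundary
  pm0 <- make_pm(rep(18L, 15), rep("BUCK_00", 15), detected = rep(18L, 15),
                 expected = rep(18L, 15))
  fit0 <- fit_missing_pellets(pm0, rep("BUCK_00", 15),
                              settings = fast_settings(seed = 6,
                                                       n_draws = 2000L))
  expect_lt(mean(fit0$pooled_draws), 0.02)

  # binomial data at miss probability 0.78
  set.seed(44)
  expd <- rep(32L, 40)
  det <- rbinom(40, expd, 0.22)
  pm1 <- make_pm(det, rep("BUCK_1", 40), detected = det, expected = expd)
  fit1 <- fit_missing_pellets(pm1, rep("BUCK_1", 40),
                              settings = fast_settings(seed = 7,
                                                       n_draws = 4000L))
  miss <- sum(expd - det)
  tot <- sum(expd)
  # quadrature oracle with the model's N(0, 10) logit prior
  g <- seq(qlogis(0.6), qlogis(0.9), length.out = 4001)
  lp <- miss * g - tot * log1p(exp(g)) - g^2 / 200
  w <- exp(lp - max(lp))
  oracle <- sum(plogis(g) * w) / sum(w)
  v <- fit1$pooled_draws
  expect_lt(abs(mean(v) - oracle), max(3 * mc_se_batch(v), 0.004))

  # inconsistent accounting is fatal
  pm_bad <- pm1
  pm_bad$pellets_expected[1] <- 1L
  expect_error(fit_missing_pellets(pm_bad, rep("BUCK_1", 40)),
               "exceeds pellets_expected|less than")
})

test_that("aggregating records within an arm leaves the fit unchanged", {
  set.seed(45)
  expd <- rep(27L, 30)
  det <- rbinom(30, expd, 0.25)
  am <- rep(c("BUCK_00", "BUCK_4"), each = 15)
  pm_split <- make_pm(det, am, detected = det, expected = expd)
  # aggregate each arm into one pseudo-carcase with the same totals
  agg_det <- tapply(det, am, sum)
  agg_exp <- tapply(expd, am, sum)
  pm_agg <- make_pm(as.integer(agg_det), names(agg_det),
                    detected = as.integer(agg_det),
                    expected = as.integer(agg_exp))
  s <- fast_settings(seed = 8, n_draws = 1500L)
  f_split <- fit_missing_pellets(pm_split, am, settings = s)
  f_agg <- fit_missing_pellets(pm_agg, names(agg_det), settings = s)
  expect_identical(f_split$missing_prop_draws, f_agg$missing_prop_draws)
})
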