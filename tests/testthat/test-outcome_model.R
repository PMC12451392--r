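# Encounter-outcome logistic model and posterior contrasts.

make_outcome_records <- function(y_k, n_k) {
  rows <- list()
  id <- 0L
  for (k in seq_along(n_k)) {
    for (i in seq_len(n_k[k])) {
      id <- id + 1L
      inst <- i <= y_k[k]
      rows[[id]] <- data.frame(
        animal_id = sprintf("X%04d", id), sortie_id = k, group_id = id,
        ammo = ammo_types()[k], ct_s = 30,
        tti_s = if (inst) 0.5 else 20, tti_censored = FALSE,
        shots_fired = 2L,
        outcome = if (inst) "INSENSIBLE_LE_1S" else "INSENSIBLE_GT_1S",
        sex_age = "ADULT_M", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("single-arm posterior matches a quadrature oracle", {
  rec <- make_outcome_records(y_k = 7L, n_k = 100L)
  rec$ammo <- "RIFLE_308"
  rec$sortie_id <- 1L
  fit <- fit_outcome(rec, settings = fast_settings(seed = 1,
                                                   n_draws = 4000L))
  # oracle: 1-D quadrature on the logit with the same N(0, 1.6) prior
  oracle_eta <- quad_mean(function(e) {
    7 * e - 100 * log1p(exp(e)) - e^2 / (2 * 1.6^2)
  }, -6, 1)
  oracle_grid <- seq(-6, 1, length.out = 4001)
  w <- exp(vapply(oracle_grid, function(e) {
    7 * e - 100 * log1p(exp(e)) - e^2 / (2 * 1.6^2)
  }, numeric(1)))
  oracle_p <- sum(plogis(oracle_grid) * w) / sum(w)
  v <- fit$p_draws[, 1]
  expect_lt(abs(mean(v) - oracle_p), max(3 * mc_se_batch(v), 0.003))
  # near-flat prior keeps the mean close to the conjugate-style estimate
  expect_lt(abs(mean(v) - (7 + 0.5) / 101), 0.01)
})

test_that("boundary and monotonicity behaviour is sane", {
  rec <- make_outcome_records(y_k = c(10L, 10L, 10L, 10L),
                              n_k = c(10L, 10L, 10L, 10L))
  fit <- fit_outcome(rec, settings = fast_settings(seed = 2))
  expect_true(all(fit$p_draws > 0 & fit$p_draws < 1))
  expect_true(all(fit$summaries$mean[fit$summaries$ammo != "ALL"] > 0.7))

  rec2 <- make_outcome_records(y_k = c(2L, 10L, 25L, 40L),
                               n_k = c(80L, 80L, 80L, 80L))
  fit2 <- fit_outcome(rec2, settings = fast_settings(seed = 3))
  m <- fit2$summaries$mean[match(ammo_types(), fit2$summaries$ammo)]
  expect_identical(order(m), 1:4)

  bad <- rec2[rec2$ammo != "BUCK_4", ]
  expect_no_error(fit_outcome(bad, settings = fast_settings(seed = 4,
                                                            n_draws = 500L,
                                                            n_burn = 300L)))
  expect_error(fit_outcome(bad[0, ]), "no encounters")
})

test_that("pooled instant-kill probability is recovered from simulation", {
  cfg <- sim_config(seed = 23, n_sorties = 16, animals_per_sortie = 130,
                    p_instant_per_ammo = 0.05)
  enc <- simulate_encounters(cfg)
  fit <- fit_outcome(enc, settings = fast_settings(seed = 5,
                                                   n_draws = 3000L))
  expect_lt(abs(mean(fit$overall_draws) - 0.05),
            3 * sqrt(0.05 * 0.95 / nrow(enc)) + 0.005)
  expect_true(all(fit$summaries$rhat < 1.05, na.rm = TRUE))
})

test_that("prob_greater is a tie-split exceedance probability", {
  x <- c(1, 2, 3, 4)
  expect_identical(prob_greater(x, x), 0.5)
  expect_identical(prob_greater(x + 1, x), 1)
  expect_error(prob_greater(numeric(0), x), "empty")

  set.seed(33)
  a <- rnorm(4000)
  b <- rnorm(4000, 0.3)
  expect_equal(prob_greater(a, b) + prob_greater(b, a), 1)

  # Beta(8, 94) vs Beta(4, 96): oracle by numerical integration
  oracle <- integrate(function(x) {
    dbeta(x, 8, 94) * pbeta(x, 4, 96)
  }, 0, 1)$value
  set.seed(34)
  pa <- rbeta(2e5, 8, 94)
  pb <- rbeta(2e5, 4, 96)
  expect_lt(abs(prob_greater(pa, pb) - oracle), 0.005)
})
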