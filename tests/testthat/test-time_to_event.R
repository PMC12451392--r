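# Exponential survival models: conjugate identities, censored-data
# quadrature oracle, total-time derivation, percentiles, curves and the
# DIC comparison.

test_that("uncensored pooled fit matches the conjugate Gamma posterior", {
  set.seed(14)
  tt <- rexp(80, 0.1)
  f <- fit_exponential(tt, settings = fast_settings(seed = 1,
                                                    n_draws = 5000L))
  v <- as.vector(f$rate_draws)
  a <- 0.001 + 80
  b <- 0.001 + sum(tt)
  expect_lt(abs(mean(v) - a / b), 3 * sd(v) / sqrt(length(v)))
  expect_lt(abs(sd(v) - sqrt(a) / b), 0.1 * sqrt(a) / b)
  expect_null(f$imputed_draws)  # latent path bypassed with no censoring
})

test_that("censored pooled fit matches a quadrature oracle", {
  set.seed(15)
  n <- 150
  lam <- 0.07
  t_true <- rexp(n, lam)
  cens <- seq_len(n) %in% sample(n, 30)
  tobs <- ifelse(cens, runif(n, 0, t_true), t_true)
  f <- fit_exponential(tobs, cens,
                       settings = fast_settings(seed = 2, n_draws = 4000L))
  U <- max(tobs)
  tu <- tobs[!cens]
  L <- tobs[cens]
  # marginal over the latent interval times: each censored row
  # contributes e^(-lL) - e^(-lU), absorbing its lambda factor
  oracle <- quad_mean(function(l) {
    (0.001 - 1 + length(tu)) * log(l) - l * (0.001 + sum(tu)) +
      sum(log(pmax(exp(-l * L) - exp(-l * U), 1e-300)))
  }, lam / 4, lam * 3)
  v <- as.vector(f$rate_draws)
  expect_lt(abs(mean(v) - oracle), max(3 * mc_se_batch(v), 0.005 * oracle))

  # every stored latent imputation lies in [row minimum, global max]
  ims <- f$imputed_draws
  lo <- rep(L, each = dim(ims)[1] * dim(ims)[2])
  expect_true(all(ims >= lo & ims <= U))
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_exponential(numeric(0)), "no observations")
  expect_error(fit_exponential(c(1, 2), censored = c(TRUE, TRUE)),
               "all values are censored")
  expect_error(fit_exponential(c(1, -2)), "> 0")
  expect_error(fit_exponential(c(1, 2), ammo = NULL,
                               covariate_mode = "by_ammo"), "ammo")
  # single observation, vague prior: posterior mean on the 1/t scale
  f1 <- fit_exponential(10, settings = fast_settings(n_draws = 3000L))
  expect_lt(abs(mean(f1$rate_draws) - 0.1), 0.05)
})

test_that("by-ammo fit recovers distinct per-arm rates", {
  set.seed(16)
  lam <- c(RIFLE_308 = 0.12, BUCK_00 = 0.04, BUCK_1 = 0.08,
           BUCK_4 = 0.06)
  am <- rep(ammo_types(), each = 120)
  tt <- rexp(length(am), lam[am])
  cens <- runif(length(am)) < 0.15
  L <- runif(sum(cens), 0, tt[cens])
  tobs <- tt
  tobs[cens] <- L
  f <- fit_exponential(tobs, cens, am, covariate_mode = "by_ammo",
                       settings = fast_settings(seed = 3,
                                                n_draws = 3000L,
                                                n_burn = 1500L))
  est <- f$summaries$mean[match(paste0("lambda_", names(lam)),
                                f$summaries$parameter)]
  expect_equal(order(est), order(unname(lam)))
  expect_true(all(f$summaries$rhat < 1.05))
  expect_true(all(abs(est - unname(lam)) / unname(lam) < 0.25))
})

test_that("total time is chase time plus observed-or-imputed tti", {
  set.seed(17)
  n <- 60
  tt <- rexp(n, 0.08)
  cens <- runif(n) < 0.2
  tobs <- ifelse(cens, runif(n, 0, tt), tt)
  f <- fit_exponential(tobs, cens, settings = fast_settings(seed = 4))

  # zero chase time: the TT fit reproduces the TTI fit
  tt0 <- derive_tt(f, rep(0, n))
  expect_lt(abs(mean(tt0$rate_draws) - mean(f$rate_draws)),
            0.05 * mean(f$rate_draws))

  # constant chase time shifts the empirical total-time median by c
  ttc <- derive_tt(f, rep(25, n))
  expect_equal(median(colMeans(ttc$tt_draws)) -
                 median(colMeans(tt0$tt_draws)), 25, tolerance = 1e-8)
  expect_equal(ttc$tt_mean, tt0$tt_mean + 25, tolerance = 1e-8)

  # misalignment is fatal
  expect_error(derive_tt(f, rep(10, n - 1)), "misaligned")
})

test_that("fixture total time sits between chase time and its ceiling", {
  enc <- read_encounters(fixture_paths()[["encounters"]])
  s <- fast_settings(seed = 5, n_draws = 2000L)
  f <- fit_exponential(enc$tti_s, enc$tti_censored, settings = s)
  ttf <- derive_tt(f, enc$ct_s)
  med_ct <- median(enc$ct_s)
  med_tt <- surv_percentile(mean(ttf$rate_draws), 0.5)
  expect_gt(med_tt, surv_percentile(mean(f$rate_draws), 0.5))
  expect_lt(med_tt, med_ct + max(enc$tti_s) + 1)
})

test_that("exponential percentiles follow the closed form", {
  expect_equal(surv_percentile(log(20) / 43, 0.95), 43)
  lam <- 0.31
  expect_equal(surv_percentile(lam, 0.5), log(2) / lam)
  expect_equal(surv_percentile(2 * lam, 0.9),
               surv_percentile(lam, 0.9) / 2)
})

test_that("survival curves are proper and widen with posterior spread", {
  set.seed(18)
  tt <- rexp(100, 0.05)
  f_wide <- fit_exponential(tt[1:12],
                            settings = fast_settings(seed = 6,
                                                     n_draws = 2000L))
  f_narrow <- fit_exponential(tt,
                              settings = fast_settings(seed = 6,
                                                       n_draws = 2000L))
  grid <- c(0, 5, 10, 20, 50)
  c_wide <- survival_curve(f_wide, grid)
  c_narrow <- survival_curve(f_narrow, grid)
  expect_equal(c_wide$mean[1], 1)
  expect_true(all(diff(c_narrow$mean) <= 0))
  widths_w <- (c_wide$hi - c_wide$lo)[-1]
  widths_n <- (c_narrow$hi - c_narrow$lo)[-1]
  expect_true(all(widths_w > widths_n))
})

test_that("model comparison prefers the generating structure", {
  set.seed(19)
  am <- rep(ammo_types(), each = 60)
  tt_eq <- rexp(length(am), 0.07)
  s <- fast_settings(seed = 7, n_draws = 1500L, n_burn = 800L)
  f_by <- fit_exponential(tt_eq, ammo = am, covariate_mode = "by_ammo",
                          settings = s)
  f_po <- fit_exponential(tt_eq, settings = s)
  cmp <- compare_models(f_by, f_po)
  expect_identical(cmp$preferred, "pooled")

  # strong rate differences favour the covariate model
  lam <- c(RIFLE_308 = 0.21, BUCK_00 = 0.07, BUCK_1 = 0.21,
           BUCK_4 = 0.07)
  tt_df <- rexp(length(am), lam[am])
  f_by2 <- fit_exponential(tt_df, ammo = am, covariate_mode = "by_ammo",
                           settings = s)
  f_po2 <- fit_exponential(tt_df, settings = s)
  cmp2 <- compare_models(f_by2, f_po2)
  expect_identical(cmp2$preferred, "by_ammo")

  expect_identical(compare_models(f_by, f_by)$preferred, "tie")
  expect_error(compare_models(f_by, f_po2), "identical data")
})
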