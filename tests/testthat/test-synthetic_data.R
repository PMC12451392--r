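# Generator: block randomisation, encounter and post-mortem structure.

test_that("ammunition is assigned in randomised blocks of four", {
  expect_setequal(assign_ammo_to_sorties(4, seed = 1), ammo_types())
  a8 <- assign_ammo_to_sorties(8, seed = 2)
  expect_true(all(table(a8) == 2L))
  a6 <- assign_ammo_to_sorties(6, seed = 3)
  expect_setequal(a6[1:4], ammo_types())
  expect_identical(anyDuplicated(a6[5:6]), 0L)
  # deterministic given seed
  expect_identical(assign_ammo_to_sorties(17, seed = 42),
                   assign_ammo_to_sorties(17, seed = 42))
})

test_that("block counts stay balanced over many assignments", {
  set.seed(101)
  counts <- table(unlist(lapply(1:50, function(i)
    assign_ammo_to_sorties(8))))
  expect_true(all(counts == 100L))
})

test_that("encounter simulation honours censoring and outcome rules", {
  cfg <- sim_config(seed = 7, n_sorties = 8, animals_per_sortie = 30,
                    censor_prob = 0)
  enc <- simulate_encounters(cfg)
  expect_false(any(enc$tti_censored))

  cfg2 <- sim_config(seed = 7, n_sorties = 8, animals_per_sortie = 30)
  enc2 <- simulate_encounters(cfg2)
  expect_identical(enc2, simulate_encounters(cfg2))  # bit-reproducible

  latent <- attr(enc2, "latent_tti")
  cens <- enc2$tti_censored
  expect_true(all(enc2$tti_s[cens] < latent[cens]))
  expect_true(all((latent <= 1) == (enc2$outcome == "INSENSIBLE_LE_1S")))
  expect_true(all(enc2$shots_fired >= 2L))
})

test_that("tti rates reproduce the intended tail and instant fractions", {
  lam <- log(20) / 43
  cfg <- sim_config(seed = 11, n_sorties = 40, animals_per_sortie = 250,
                    tti_rate_per_ammo = stats::setNames(rep(lam, 4),
                                                        ammo_types()),
                    censor_prob = 0)
  enc <- simulate_encounters(cfg)
  latent <- attr(enc, "latent_tti")
  frac43 <- mean(latent <= 43)
  expect_lt(abs(frac43 - 0.95), 3 * sqrt(0.95 * 0.05 / length(latent)))

  cfg2 <- sim_config(seed = 12, n_sorties = 40, animals_per_sortie = 250,
                     p_instant_per_ammo = 0.05, censor_prob = 0)
  enc2 <- simulate_encounters(cfg2)
  inst <- mean(enc2$outcome == "INSENSIBLE_LE_1S")
  expect_lt(abs(inst - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(enc2)))
})

test_that("inconsistent rate and instant-probability specs are fatal", {
  expect_error(
    sim_config(tti_rate_per_ammo = stats::setNames(rep(0.5, 4),
                                                   ammo_types()),
               p_instant_per_ammo = 0.05),
    "inconsistent")
  # consistent double specification is accepted
  p <- 0.05
  expect_s3_class(
    sim_config(tti_rate_per_ammo = stats::setNames(rep(-log(1 - p), 4),
                                                   ammo_types()),
               p_instant_per_ammo = p),
    "sim_config")
})

test_that("post-mortem pellet accounting matches its generative rules", {
  # deterministic limit: every fired pellet detected
  cfg <- sim_config(seed = 3, n_sorties = 4, animals_per_sortie = 40,
                    pellet_hit_prob = 1, shots_mean = 2,
                    insitu_fraction = 1, exsitu_fraction = 1)
  enc <- simulate_encounters(cfg)
  pm <- simulate_postmortem(enc, cfg)
  idx <- match(pm$animal_id, enc$animal_id)
  sg <- is_shotgun(enc$ammo[idx])
  det <- rowSums(pm[, c("pellets_head", "pellets_neck", "pellets_thorax",
                        "pellets_abdomen", "pellets_limbs")])
  expect_identical(as.integer(det[sg]), pm$pellets_expected[sg])
  buck00_2 <- sg & enc$ammo[idx] == "BUCK_00" & enc$shots_fired[idx] == 2L
  expect_true(all(det[buck00_2] == 18L))

  # stochastic detection: about 78% of fired pellets undetected
  cfg2 <- sim_config(seed = 5, n_sorties = 8, animals_per_sortie = 80,
                     insitu_fraction = 1, exsitu_fraction = 1)
  enc2 <- simulate_encounters(cfg2)
  pm2 <- simulate_postmortem(enc2, cfg2)
  idx2 <- match(pm2$animal_id, enc2$animal_id)
  sg2 <- is_shotgun(enc2$ammo[idx2])
  det2 <- rowSums(pm2[sg2, c("pellets_head", "pellets_neck",
                             "pellets_thorax", "pellets_abdomen",
                             "pellets_limbs")])
  ratio <- sum(det2) / sum(pm2$pellets_expected[sg2])
  expect_lt(abs(ratio - 0.22), 0.02)

  # mandatory thorax strike on every examined shotgun carcase
  expect_true(all(pm2$pellets_thorax[sg2] >= 1L))
  expect_true(all(det2 <= pm2$pellets_expected[sg2]))
})

test_that("the trial fixture regenerates the packaged data exactly", {
  cfg <- trial_config()
  enc <- simulate_encounters(cfg)
  expect_identical(nrow(enc), 390L)
  expect_identical(as.vector(table(enc$ammo)[ammo_types()]),
                   c(100L, 98L, 98L, 94L))
  expect_identical(nfwr(enc), 0)

  dir <- withr::local_tempdir()
  paths <- trial_fixture(dir, cfg)
  expect_identical(readLines(paths[["encounters"]]),
                   readLines(fixture_paths()[["encounters"]]))
  expect_identical(readLines(paths[["postmortem"]]),
                   readLines(fixture_paths()[["postmortem"]]))
})
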