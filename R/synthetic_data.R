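# Synthetic trial-data generator. Emulates the statistical structure of a
# randomised helicopter-culling trial: ammunition assigned to sorties in
# randomised blocks of four, log-normal chase times, exponential times to
# insensibility with right-censoring when the animal drops out of view,
# two-shot-minimum repeat shooting, and post-mortem pellet accounting with
# a mandatory thorax strike and a large fraction of undetected pellets.

#' Simulation configuration
#'
#' All knobs of the synthetic trial. Defaults reproduce trial-like
#' conditions: 17 sorties of about 23 animals, log-normal chase time with
#' median about 60 s, exponential time to insensibility with per-arm 95th
#' percentiles of 35-47 s, 23% right-censoring, 22% pellet detection
#' (so about 78% of fired pellets go undetected), and thorax-dominated
#' pellet placement that concentrates further as pellets per cartridge
#' decrease.
#'
#' Exactly one of `tti_rate_per_ammo` (rates, per second) or
#' `p_instant_per_ammo` (probability of insensibility within 1 s, solved
#' to a rate via `lambda = -log(1 - p)`) may be supplied.
#'
#' @param seed integer master seed.
#' @param n_sorties number of culling flights.
#' @param animals_per_sortie expected animals per sortie (Poisson), unless
#'   `sortie_sizes` is given.
#' @param sortie_sizes optional explicit integer vector of per-sortie
#'   animal counts (length `n_sorties`).
#' @param ct_lognormal `c(meanlog, sdlog)` of chase time in seconds.
#' @param tti_rate_per_ammo named rate per ammunition type, per second.
#' @param p_instant_per_ammo named probability of insensibility within
#'   1 s, per ammunition type (alternative parameterisation).
#' @param censor_prob probability that a non-instant kill is observed only
#'   as a minimum (animal out of view at insensibility).
#' @param pellet_hit_prob probability that a fired pellet is detectable in
#'   the carcase.
#' @param zone_weights named non-negative allocation weights over the five
#'   anatomical zones.
#' @param thorax_concentration named multiplier (> 0) applied to the
#'   THORAX weight per shotgun arm; defaults decrease with pellets per
#'   cartridge, reflecting tighter patterns of fewer, heavier pellets.
#' @param shots_mean mean shots fired per animal (>= 2; generated as
#'   `2 + Poisson(shots_mean - 2)` under the two-shot-minimum protocol).
#' @param insitu_fraction fraction of carcases receiving any post-mortem
#'   record (field inspection).
#' @param exsitu_fraction fraction of all animals transported for full
#'   ex-situ examination (subset of the in-situ fraction).
#' @param sex_age_probs named probabilities over the sex/age classes.
#' @param mass_lognormal `c(meanlog, sdlog)` of body mass in kg; masses
#'   above 100 kg are recorded as censored at the scale limit.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_sorties = 17L,
                       animals_per_sortie = 23,
                       sortie_sizes = NULL,
                       ct_lognormal = c(meanlog = log(60), sdlog = 0.8),
                       tti_rate_per_ammo = c(RIFLE_308 = log(20) / 35,
                                             BUCK_00 = log(20) / 47,
                                             BUCK_1 = log(20) / 43,
                                             BUCK_4 = log(20) / 40),
                       p_instant_per_ammo = NULL,
                       censor_prob = 0.23,
                       pellet_hit_prob = 0.22,
                       zone_weights = c(HEAD = 0.08, NECK = 0.12,
                                        THORAX = 0.55, ABDOMEN = 0.15,
                                        LIMBS = 0.10),
                       thorax_concentration = c(BUCK_00 = 3.0, BUCK_1 = 2.0,
                                                BUCK_4 = 1.4),
                       shots_mean = 2.3,
                       insitu_fraction = 0.20,
                       exsitu_fraction = 0.15,
                       sex_age_probs = c(ADULT_M = 0.68, ADULT_F = 0.17,
                                         YEARLING = 0.10, FAWN = 0.05),
                       mass_lognormal = c(meanlog = log(62), sdlog = 0.35)) {
  if (!is.null(p_instant_per_ammo)) {
    if (length(p_instant_per_ammo) == 1L &&
        is.null(names(p_instant_per_ammo))) {
      p_instant_per_ammo <- stats::setNames(rep(p_instant_per_ammo, 4L),
                                            ammo_types())
    }
    stopifnot(all(ammo_types() %in% names(p_instant_per_ammo)),
              all(p_instant_per_ammo > 0 & p_instant_per_ammo < 1))
    p_full <- p_instant_per_ammo[ammo_types()]
    implied <- -log(1 - p_full)
    if (!missing(tti_rate_per_ammo) &&
        !isTRUE(all.equal(unname(tti_rate_per_ammo[ammo_types()]),
                          unname(implied), tolerance = 1e-6))) {
      stop("tti_rate_per_ammo and p_instant_per_ammo were both supplied ",
           "and are inconsistent", call. = FALSE)
    }
    tti_rate_per_ammo <- implied
    names(tti_rate_per_ammo) <- ammo_types()
  }
  stopifnot(n_sorties >= 1L,
            all(ammo_types() %in% names(tti_rate_per_ammo)),
            all(tti_rate_per_ammo > 0),
            censor_prob >= 0, censor_prob <= 1,
            pellet_hit_prob > 0, pellet_hit_prob <= 1,
            all(zone_names() %in% names(zone_weights)),
            all(zone_weights >= 0), sum(zone_weights) > 0,
            all(thorax_concentration > 0),
            shots_mean >= 2,
            insitu_fraction >= 0, insitu_fraction <= 1,
            exsitu_fraction >= 0, exsitu_fraction <= insitu_fraction,
            abs(sum(sex_age_probs) - 1) < 1e-6)
  if (!is.null(sortie_sizes)) {
    stopifnot(length(sortie_sizes) == n_sorties, all(sortie_sizes >= 0))
    sortie_sizes <- as.integer(sortie_sizes)
  }
  structure(list(
    seed = as.integer(seed), n_sorties = as.integer(n_sorties),
    animals_per_sortie = animals_per_sortie, sortie_sizes = sortie_sizes,
    ct_lognormal = ct_lognormal,
    tti_rate_per_ammo = tti_rate_per_ammo[ammo_types()],
    censor_prob = censor_prob, pellet_hit_prob = pellet_hit_prob,
    zone_weights = zone_weights[zone_names()],
    thorax_concentration = thorax_concentration,
    shots_mean = shots_mean, insitu_fraction = insitu_fraction,
    exsitu_fraction = exsitu_fraction,
    sex_age_probs = sex_age_probs[sex_age_levels()],
    mass_lognormal = mass_lognormal), class = "sim_config")
}

#' Randomised-block ammunition assignment
#'
#' Assigns one ammunition type per sortie by drawing independent random
#' permutations of the four types (blocks of four, without replacement)
#' and concatenating them, truncating the final block if needed.
#'
#' @param n_sorties number of sorties (>= 1).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return Character vector of length `n_sorties`.
#' @export
assign_ammo_to_sorties <- function(n_sorties, seed = NULL) {
  stopifnot(n_sorties >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- ceiling(n_sorties / 4)
  seq_full <- unlist(lapply(seq_len(n_blocks),
                            function(i) sample(ammo_types())))
  seq_full[seq_len(n_sorties)]
}

#' Simulate encounter records
#'
#' Draws one encounter row per animal: log-normal chase time, exponential
#' time to insensibility at the arm's rate, outcome `INSENSIBLE_LE_1S`
#' exactly when the latent time is at most 1 s, and right-censoring of
#' non-instant kills with probability `censor_prob`, in which case the
#' recorded time is a uniform draw on (0, latent time) flagged as an
#' observed minimum. Times are recorded to 0.1 s (censored minima rounded
#' down so they never exceed the latent value). The latent times are
#' attached as attribute `"latent_tti"` for testing.
#'
#' @param config a [sim_config()].
#' @return Validated encounter data.frame with attribute `latent_tti`.
#' @export
simulate_encounters <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ammo_seq <- assign_ammo_to_sorties(config$n_sorties)
  sizes <- if (!is.null(config$sortie_sizes)) config$sortie_sizes else
    stats::rpois(config$n_sorties, config$animals_per_sortie)
  n <- sum(sizes)
  if (n == 0L) stop("configuration yields zero animals", call. = FALSE)
  sortie <- rep(seq_len(config$n_sorties), sizes)
  ammo <- ammo_seq[sortie]

  # groups of deer within a sortie; mean group size about 3.3
  group_id <- integer(n)
  gid <- 0L
  for (s in seq_len(config$n_sorties)) {
    idx <- which(sortie == s)
    left <- length(idx)
    pos <- 1L
    while (left > 0L) {
      gid <- gid + 1L
      size <- min(1L + stats::rpois(1L, 2.3), left)
      group_id[idx[pos:(pos + size - 1L)]] <- gid
      pos <- pos + size
      left <- left - size
    }
  }

  ct <- stats::rlnorm(n, config$ct_lognormal[[1]], config$ct_lognormal[[2]])
  rate <- config$tti_rate_per_ammo[ammo]
  tti_true <- stats::rexp(n, rate)
  instant <- tti_true <= 1
  censored <- !instant & stats::runif(n) < config$censor_prob
  tti_obs <- tti_true
  tti_obs[censored] <- stats::runif(sum(censored), 0,
                                    tti_true[censored])
  # voice-recorder style rounding; censored minima floored so the
  # recorded minimum never exceeds the latent time
  tti_rec <- ifelse(censored, floor(tti_obs * 10) / 10,
                    pmax(round(tti_obs, 1), 0.1))
  shots <- 2L + stats::rpois(n, config$shots_mean - 2)
  sex_age <- sample(sex_age_levels(), n, replace = TRUE,
                    prob = config$sex_age_probs)

  records <- data.frame(
    animal_id = sprintf("D%04d", seq_len(n)),
    sortie_id = sortie,
    group_id = group_id,
    ammo = ammo,
    ct_s = pmax(round(ct, 1), 0.1),
    tti_s = tti_rec,
    tti_censored = censored,
    shots_fired = shots,
    outcome = ifelse(instant, "INSENSIBLE_LE_1S", "INSENSIBLE_GT_1S"),
    sex_age = sex_age,
    stringsAsFactors = FALSE)
  validate_encounters(records)
  attr(records, "latent_tti") <- tti_true
  records
}

# Binomial(size, p) conditioned on >= 1, vectorised rejection sampling.
rbinom_pos <- function(size, p) {
  n <- length(size)
  out <- stats::rbinom(n, size, p)
  for (i in 1:100) {
    zero <- out == 0L
    if (!any(zero)) break
    out[zero] <- stats::rbinom(sum(zero), size[zero], p)
  }
  out[out == 0L] <- 1L
  out
}

#' Simulate post-mortem records
#'
#' Selects the inspected subset of carcases (in-situ field checks, a
#' sub-subset transported for ex-situ examination), then generates pellet
#' accounting for shotgun kills: detected pellets are binomial over the
#' fired pellets (shots times pellets per cartridge) at
#' `pellet_hit_prob`, conditioned on at least one for examined shotgun
#' carcases; zones are allocated multinomially with the THORAX weight
#' scaled by the arm's concentration factor, and if no pellet lands in
#' the thorax one detected pellet is reassigned there (the protocol's
#' mandatory thorax shot). Wound tracts equal detected pellets for
#' shotguns and shots fired for the rifle. Zone counts and body mass are
#' only recorded for ex-situ examinations.
#'
#' @param encounters encounter data.frame from [simulate_encounters()].
#' @param config the same [sim_config()].
#' @return Validated post-mortem data.frame.
#' @export
simulate_postmortem <- function(encounters, config) {
  stopifnot(inherits(config, "sim_config"))
  encounters <- validate_encounters(encounters)
  set.seed(config$seed + 1L)
  n <- nrow(encounters)
  killed <- !(encounters$outcome %in% c("WOUNDED_ESCAPED",
                                        "MISSED_ESCAPED"))
  inspected <- killed & stats::runif(n) < config$insitu_fraction
  p_ex <- if (config$insitu_fraction > 0) {
    config$exsitu_fraction / config$insitu_fraction
  } else {
    0
  }
  exsitu <- inspected & stats::runif(n) < p_ex
  idx <- which(inspected)
  if (length(idx) == 0L) {
    stop("no carcases selected for post-mortem examination", call. = FALSE)
  }
  enc <- encounters[idx, ]
  is_ex <- exsitu[idx]
  shotgun <- is_shotgun(enc$ammo)
  ppc <- pellets_per_cartridge()[enc$ammo]
  expected <- ifelse(shotgun, enc$shots_fired * ppc, 0L)

  m <- length(idx)
  detected <- integer(m)
  if (any(shotgun)) {
    detected[shotgun] <- rbinom_pos(expected[shotgun],
                                    config$pellet_hit_prob)
  }

  zones <- matrix(NA_integer_, m, 5L,
                  dimnames = list(NULL, pellet_zone_columns()))
  for (i in which(shotgun & is_ex)) {
    w <- config$zone_weights
    conc <- config$thorax_concentration[enc$ammo[i]]
    if (!is.na(conc)) w["THORAX"] <- w["THORAX"] * conc
    z <- as.vector(stats::rmultinom(1L, detected[i], w))
    if (z[3L] == 0L) {
      donor <- which.max(z)
      z[donor] <- z[donor] - 1L
      z[3L] <- z[3L] + 1L
    }
    zones[i, ] <- z
  }
  zones[!shotgun & is_ex, ] <- 0L

  tracts <- ifelse(shotgun, detected, enc$shots_fired)
  mass <- stats::rlnorm(m, config$mass_lognormal[[1]],
                        config$mass_lognormal[[2]])
  mass <- round(mass * 2) / 2  # weighed to the nearest 0.5 kg
  mass_cens <- mass > 100
  mass[mass_cens] <- 100

  records <- data.frame(
    animal_id = enc$animal_id,
    wound_tracts = as.integer(tracts),
    pellets_head = zones[, 1L], pellets_neck = zones[, 2L],
    pellets_thorax = zones[, 3L], pellets_abdomen = zones[, 4L],
    pellets_limbs = zones[, 5L],
    pellets_expected = as.integer(expected),
    body_mass_kg = ifelse(is_ex, mass, NA_real_),
    mass_censored = ifelse(is_ex, mass_cens, NA),
    exam = ifelse(is_ex, "EX_SITU", "IN_SITU_ONLY"),
    stringsAsFactors = FALSE)
  validate_postmortem(records, encounters)
  records
}

#' Trial-like fixture configuration
#'
#' A frozen configuration regenerating the packaged trial-scale data set:
#' 390 animals over 17 sorties with per-arm totals of 100 (.308 rifle),
#' 98 (00 Buck), 98 (1 Buck) and 94 (4 Buck), and no escapes. The
#' randomised-block assignment determines which arm flies five sorties;
#' each arm's total is split near-evenly across its sorties.
#'
#' @param seed fixture seed (frozen default).
#' @return A [sim_config()] with explicit `sortie_sizes`.
#' @export
trial_config <- function(seed = 20230220L) {
  ammo_seq <- assign_ammo_to_sorties(17L, seed = seed)
  arm_totals <- c(RIFLE_308 = 100L, BUCK_00 = 98L, BUCK_1 = 98L,
                  BUCK_4 = 94L)
  sizes <- integer(17L)
  for (a in ammo_types()) {
    s <- which(ammo_seq == a)
    base <- arm_totals[[a]] %/% length(s)
    extra <- arm_totals[[a]] %% length(s)
    sz <- rep(base, length(s))
    if (extra > 0L) sz[seq_len(extra)] <- sz[seq_len(extra)] + 1L
    sizes[s] <- sz
  }
  sim_config(seed = seed, n_sorties = 17L, sortie_sizes = sizes)
}

#' Regenerate the packaged trial-like fixture
#'
#' @param dir output directory; created if needed.
#' @param config fixture configuration (default [trial_config()]).
#' @return Named character vector of the two written CSV paths.
#' @export
trial_fixture <- function(dir, config = trial_config()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  enc <- simulate_encounters(config)
  pm <- simulate_postmortem(enc, config)
  paths <- c(encounters = file.path(dir, "encounters.csv"),
             postmortem = file.path(dir, "postmortem.csv"))
  write_encounters(enc, paths[["encounters"]])
  write_postmortem(pm, paths[["postmortem"]])
  paths
}

#' Paths to the packaged fixture CSVs
#'
#' @return Named character vector with elements `encounters` and
#'   `postmortem`.
#' @export
fixture_paths <- function() {
  c(encounters = system.file("extdata", "encounters.csv",
                             package = "cullwelfare", mustWork = TRUE),
    postmortem = system.file("extdata", "postmortem.csv",
                             package = "cullwelfare", mustWork = TRUE))
}
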