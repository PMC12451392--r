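# Post-mortem ballistic models: Poisson regression for wound tracts per
# carcase, conjugate per-zone pellet proportions, and the logistic model
# for the proportion of fired pellets not detected on radiographs.

#' Priors for the wound and pellet models
#'
#' `coef_sd` is the Normal(0, sd) prior on log-mean (Poisson) or logit
#' (binomial) coefficients; `zone_shape`/`zone_rate` parameterise the
#' Gamma prior on per-zone Poisson means used by the pellet-zone model.
#'
#' @param coef_sd prior sd of regression coefficients.
#' @param zone_shape,zone_rate Gamma hyperparameters of zone means.
#' @return list of class `wound_prior`.
#' @export
wound_prior <- function(coef_sd = 10, zone_shape = 0.5, zone_rate = 0.01) {
  stopifnot(coef_sd > 0, zone_shape > 0, zone_rate > 0)
  structure(list(coef_sd = coef_sd, zone_shape = zone_shape,
                 zone_rate = zone_rate), class = "wound_prior")
}

poisson_log_post <- function(beta, y_k, n_k, coef_sd) {
  eta <- if (length(beta) == 1L) beta else c(beta[1L], beta[1L] + beta[-1L])
  mu <- exp(eta)
  sum(y_k * eta - n_k * mu) - sum(beta^2) / (2 * coef_sd^2)
}

#' Mean wound tracts per deer, by ammunition type
#'
#' Poisson regression of wound-tract counts on ammunition type
#' (`log(mu_k) = beta0 + beta_k`, reference-coded, normal priors).
#'
#' @param postmortem post-mortem data.frame (rows with missing
#'   `wound_tracts` are dropped).
#' @param ammo ammunition code per post-mortem row.
#' @param prior a [wound_prior()].
#' @param settings an [mcmc_settings()].
#' @return Object of class `wound_fit` with per-arm mean-tract draws and
#'   summaries.
#' @export
fit_wound_tracts <- function(postmortem, ammo, prior = wound_prior(),
                             settings = mcmc_settings()) {
  stopifnot(nrow(postmortem) == length(ammo))
  keep <- !is.na(postmortem$wound_tracts)
  counts <- postmortem$wound_tracts[keep]
  ammo <- ammo[keep]
  if (length(counts) == 0L) stop("no wound-tract counts", call. = FALSE)
  stopifnot(all(counts >= 0))
  levels_k <- intersect(ammo_types(), unique(ammo))
  missing_arms <- setdiff(unique(ammo), levels_k)
  if (length(missing_arms) > 0L) stop("unknown ammo code(s)", call. = FALSE)
  arm <- factor(ammo, levels = levels_k)
  n_k <- as.vector(table(arm))
  if (any(n_k == 0L)) {
    stop("no post-mortem records for arm(s): ",
         paste(levels_k[n_k == 0L], collapse = ", "), call. = FALSE)
  }
  y_k <- as.vector(tapply(counts, arm, sum, default = 0))
  K <- length(levels_k)

  init <- c(log((sum(y_k) + 0.5) / sum(n_k)), rep(0, K - 1L))
  names(init) <- c("beta0", if (K > 1L) paste0("beta_", levels_k[-1L]))
  chains <- mcmc_sample(
    function(b) poisson_log_post(b, y_k, n_k, prior$coef_sd),
    init, settings)
  b0 <- chain_draws(chains, 1L)
  mean_tracts_draws <- matrix(NA_real_, length(b0), K,
                              dimnames = list(NULL, levels_k))
  mean_tracts_draws[, 1L] <- exp(b0)
  if (K > 1L) {
    for (k in 2L:K) {
      mean_tracts_draws[, k] <- exp(b0 + chain_draws(chains, k))
    }
  }

  n_chains <- settings$n_chains
  summaries <- do.call(rbind, lapply(seq_len(K), function(k) {
    eta <- if (k == 1L) chains$draws[, , 1L, drop = FALSE] else
      chains$draws[, , 1L, drop = FALSE] + chains$draws[, , k, drop = FALSE]
    mm <- exp(matrix(eta, n_chains))
    interval <- hpdi(as.vector(mm), 0.90)
    data.frame(ammo = levels_k[k], mean = mean(mm),
               hpdi_lo = interval[["lo"]], hpdi_hi = interval[["hi"]],
               rhat = if (n_chains >= 2L) gelman_rubin(t(mm)) else NA_real_)
  }))

  structure(list(levels = levels_k, y_k = y_k, n_k = n_k,
                 mean_tracts_draws = mean_tracts_draws,
                 summaries = summaries, chains = chains, prior = prior,
                 settings = settings),
            class = "wound_fit")
}

#' @export
print.wound_fit <- function(x, ...) {
  cat("Poisson wound-tract fit\n")
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Pellet proportions by anatomical zone
#'
#' For each shotgun arm, models the pellet count in each of the five
#' zones as Poisson with a conjugate Gamma prior on the zone mean, and
#' normalises the per-zone mean draws to proportions draw by draw
#' (equivalent to a Dirichlet-multinomial decomposition conditional on
#' totals). Draws are exact conjugate Monte Carlo, arranged as pseudo
#' chains for uniform reporting.
#'
#' @param postmortem post-mortem data.frame; only rows with radiographic
#'   pellet counts are used.
#' @param ammo ammunition code per row; rifle rows are excluded (a single
#'   bullet fragments rather than scattering countable pellets).
#' @param prior a [wound_prior()].
#' @param settings an [mcmc_settings()] (controls draw counts/seed).
#' @return Object of class `zone_fit`: `zone_prop_draws`, an array
#'   `draw x zone x arm` whose rows sum to one, plus summaries.
#' @export
fit_zone_proportions <- function(postmortem, ammo, prior = wound_prior(),
                                 settings = mcmc_settings()) {
  stopifnot(nrow(postmortem) == length(ammo))
  zones <- pellet_zone_columns()
  keep <- is_shotgun(ammo) & stats::complete.cases(postmortem[, zones])
  if (!any(keep)) stop("no shotgun rows with pellet-zone counts",
                       call. = FALSE)
  pm <- postmortem[keep, ]
  ammo <- ammo[keep]
  levels_k <- intersect(ammo_types(), unique(ammo))
  arm <- factor(ammo, levels = levels_k)
  K <- length(levels_k)
  n_draws <- settings$n_chains * settings$n_draws

  counts <- t(vapply(levels_k, function(a) {
    colSums(pm[arm == a, zones, drop = FALSE])
  }, numeric(length(zones))))
  exposure <- as.vector(table(arm))
  if (any(rowSums(counts) == 0L)) {
    stop("no pellets detected in arm(s): ",
         paste(levels_k[rowSums(counts) == 0L], collapse = ", "),
         call. = FALSE)
  }

  set.seed(settings$seed)
  Z <- length(zones)
  zone_prop_draws <- array(NA_real_, dim = c(n_draws, Z, K),
                           dimnames = list(NULL, zone_names(), levels_k))
  for (k in seq_len(K)) {
    lam <- matrix(stats::rgamma(n_draws * Z,
                                shape = prior$zone_shape + rep(counts[k, ],
                                                               each = n_draws),
                                rate = prior$zone_rate + exposure[k]),
                  n_draws, Z)
    zone_prop_draws[, , k] <- lam / rowSums(lam)
  }
  stopifnot(all(abs(apply(zone_prop_draws, c(1L, 3L), sum) - 1) < 1e-9))

  n_chains <- settings$n_chains
  summaries <- do.call(rbind, lapply(seq_len(K), function(k) {
    do.call(rbind, lapply(seq_len(Z), function(z) {
      v <- zone_prop_draws[, z, k]
      interval <- hpdi(v, 0.90)
      pseudo <- matrix(v, ncol = n_chains)
      data.frame(ammo = levels_k[k], zone = zone_names()[z],
                 mean = mean(v), hpdi_lo = interval[["lo"]],
                 hpdi_hi = interval[["hi"]],
                 rhat = if (n_chains >= 2L) gelman_rubin(pseudo) else
                   NA_real_)
    }))
  }))

  structure(list(levels = levels_k, counts = counts, exposure = exposure,
                 zone_prop_draws = zone_prop_draws, summaries = summaries,
                 prior = prior, settings = settings),
            class = "zone_fit")
}

#' @export
print.zone_fit <- function(x, ...) {
  cat("Pellet-zone proportion fit\n")
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Proportion of fired pellets not detected
#'
#' Logistic model for the per-arm probability that a fired shotgun pellet
#' is not found on the radiograph (missed the animal, passed through, or
#' fragmented beyond recognition). The response per carcase is
#' (expected - detected) out of expected pellets, where expected is shots
#' fired times pellets per cartridge; totals are sufficient under the
#' binomial likelihood. A pooled intercept-only fit gives the
#' across-arms proportion.
#'
#' @param postmortem post-mortem data.frame; shotgun rows with pellet
#'   counts are used.
#' @param ammo ammunition code per row.
#' @param prior a [wound_prior()] (uses `coef_sd` on the logit scale).
#' @param settings an [mcmc_settings()].
#' @return Object of class `missing_pellet_fit` with per-arm and pooled
#'   missing-proportion draws and summaries.
#' @export
fit_missing_pellets <- function(postmortem, ammo, prior = wound_prior(),
                                settings = mcmc_settings()) {
  stopifnot(nrow(postmortem) == length(ammo))
  zones <- pellet_zone_columns()
  keep <- is_shotgun(ammo) & stats::complete.cases(postmortem[, zones]) &
    !is.na(postmortem$pellets_expected)
  if (!any(keep)) stop("no shotgun rows with pellet counts", call. = FALSE)
  pm <- postmortem[keep, ]
  ammo <- ammo[keep]
  detected <- rowSums(pm[, zones])
  expected <- pm$pellets_expected
  if (any(expected < detected)) {
    fail_rows("pellets_expected is less than pellets detected",
              pm$animal_id[expected < detected])
  }
  levels_k <- intersect(ammo_types(), unique(ammo))
  arm <- factor(ammo, levels = levels_k)
  K <- length(levels_k)
  miss_k <- as.vector(tapply(expected - detected, arm, sum, default = 0))
  tot_k <- as.vector(tapply(expected, arm, sum, default = 0))

  p0 <- (sum(miss_k) + 0.5) / (sum(tot_k) + 1)
  init <- c(stats::qlogis(p0), rep(0, K - 1L))
  names(init) <- c("beta0", if (K > 1L) paste0("beta_", levels_k[-1L]))
  chains <- mcmc_sample(
    function(b) logit_log_post(b, miss_k, tot_k, prior$coef_sd),
    init, settings)
  b0 <- chain_draws(chains, 1L)
  missing_prop_draws <- matrix(NA_real_, length(b0), K,
                               dimnames = list(NULL, levels_k))
  missing_prop_draws[, 1L] <- stats::plogis(b0)
  if (K > 1L) {
    for (k in 2L:K) {
      missing_prop_draws[, k] <- stats::plogis(b0 + chain_draws(chains, k))
    }
  }

  pooled_settings <- settings
  pooled_settings$seed <- settings$seed + 101L
  pooled <- mcmc_sample(
    function(b) logit_log_post(b, sum(miss_k), sum(tot_k), prior$coef_sd),
    c(beta0 = stats::qlogis(p0)), pooled_settings)
  pooled_draws <- stats::plogis(chain_draws(pooled, 1L))

  n_chains <- settings$n_chains
  summaries <- do.call(rbind, lapply(seq_len(K), function(k) {
    eta <- if (k == 1L) chains$draws[, , 1L, drop = FALSE] else
      chains$draws[, , 1L, drop = FALSE] + chains$draws[, , k, drop = FALSE]
    pmat <- stats::plogis(matrix(eta, n_chains))
    interval <- hpdi(as.vector(pmat), 0.90)
    data.frame(ammo = levels_k[k], mean = mean(pmat),
               hpdi_lo = interval[["lo"]], hpdi_hi = interval[["hi"]],
               rhat = if (n_chains >= 2L) gelman_rubin(t(pmat)) else
                 NA_real_)
  }))
  ov <- hpdi(pooled_draws, 0.90)
  summaries <- rbind(summaries, data.frame(
    ammo = "ALL", mean = mean(pooled_draws), hpdi_lo = ov[["lo"]],
    hpdi_hi = ov[["hi"]],
    rhat = if (n_chains >= 2L) {
      gelman_rubin(t(stats::plogis(matrix(pooled$draws[, , 1L],
                                          n_chains))))
    } else {
      NA_real_
    }))

  structure(list(levels = levels_k, miss_k = miss_k, tot_k = tot_k,
                 missing_prop_draws = missing_prop_draws,
                 pooled_draws = pooled_draws, summaries = summaries,
                 chains = chains, prior = prior, settings = settings),
            class = "missing_pellet_fit")
}

#' @export
print.missing_pellet_fit <- function(x, ...) {
  cat("Missing-pellet logistic fit\n")
  print(x$summaries, row.names = FALSE)
  invisible(x)
}
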