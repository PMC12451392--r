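# Independent oracles and small fixture builders shared across tests.

# Exhaustive shortest-window HPDI: checks every contiguous window of
# ceiling(mass * n) sorted points.
brute_hpdi <- function(x, mass = 0.90) {
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(mass * n)
  best <- c(xs[1L], xs[m])
  for (i in seq_len(n - m + 1L)) {
    if (xs[i + m - 1L] - xs[i] < best[2L] - best[1L]) {
      best <- c(xs[i], xs[i + m - 1L])
    }
  }
  best
}

# Batch-means Monte-Carlo standard error for a (possibly autocorrelated)
# draw sequence.
mc_se_batch <- function(draws, n_batches = 50L) {
  n <- length(draws)
  bs <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches), function(b) {
    mean(draws[((b - 1L) * bs + 1L):(b * bs)])
  }, numeric(1L))
  stats::sd(means) / sqrt(n_batches)
}

# Grid-quadrature posterior mean of a scalar parameter given an
# unnormalised log-posterior function.
quad_mean <- function(log_post, lo, hi, n_grid = 4001L) {
  g <- seq(lo, hi, length.out = n_grid)
  lp <- vapply(g, log_post, numeric(1L))
  w <- exp(lp - max(lp))
  sum(g * w) / sum(w)
}

# Minimal well-formed encounter table: one row per ammo type, one sortie
# each.
tiny_encounters <- function() {
  data.frame(
    animal_id = c("A1", "A2", "A3", "A4"),
    sortie_id = 1:4,
    group_id = 1:4,
    ammo = ammo_types(),
    ct_s = c(30.5, 45, 60, 120.2),
    tti_s = c(0.8, 12.4, 30, 7.7),
    tti_censored = c(FALSE, FALSE, TRUE, FALSE),
    shots_fired = c(2L, 2L, 3L, 2L),
    outcome = c("INSENSIBLE_LE_1S", "INSENSIBLE_GT_1S",
                "INSENSIBLE_GT_1S", "INSENSIBLE_GT_1S"),
    sex_age = c("ADULT_M", "ADULT_F", "YEARLING", "FAWN"),
    stringsAsFactors = FALSE)
}

fast_settings <- function(seed = 1L, n_draws = 2000L, n_burn = 1000L,
                          n_chains = 2L) {
  mcmc_settings(n_chains = n_chains, n_draws = n_draws, n_burn = n_burn,
                seed = seed)
}
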