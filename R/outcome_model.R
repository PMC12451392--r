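# Bayesian logistic models for encounter outcomes. Each of the four
# encounter categories (insensible within 1 s, insensible later, wounded
# and escaped, missed) is modelled one-vs-rest with ammunition type as a
# categorical covariate, plus an intercept-only pooled fit for the
# across-all-arms summary.

#' Prior for logistic-model coefficients
#'
#' Independent Normal(0, `coef_sd`) priors on the logit-scale intercept
#' and reference-coded arm contrasts. The default sd of 1.6 is weakly
#' informative and close to uniform on the probability scale.
#'
#' @param coef_sd prior standard deviation.
#' @return list of class `outcome_prior`.
#' @export
outcome_prior <- function(coef_sd = 1.6) {
  stopifnot(coef_sd > 0)
  structure(list(coef_sd = coef_sd), class = "outcome_prior")
}

# Log posterior for a reference-coded binomial logit model on per-arm
# sufficient statistics.
logit_log_post <- function(beta, y_k, n_k, coef_sd) {
  eta <- if (length(beta) == 1L) beta else c(beta[1L], beta[1L] + beta[-1L])
  sum(y_k * eta - n_k * log1p(exp(eta))) - sum(beta^2) / (2 * coef_sd^2)
}

#' Fit the encounter-outcome logistic model
#'
#' Estimates, for one encounter category, the per-ammunition probability
#' of that outcome (`logit(p_k) = beta0 + beta_k`, reference-coded) and a
#' pooled intercept-only probability across all arms.
#'
#' @param records encounter data.frame.
#' @param outcome the category of interest (default immediate
#'   insensibility, `"INSENSIBLE_LE_1S"`).
#' @param prior an [outcome_prior()].
#' @param settings an [mcmc_settings()].
#' @return Object of class `outcome_fit`: per-arm probability draws
#'   (`p_draws`), pooled draws (`overall_draws`), and summaries.
#' @export
fit_outcome <- function(records, outcome = "INSENSIBLE_LE_1S",
                        prior = outcome_prior(),
                        settings = mcmc_settings()) {
  stopifnot(outcome %in% outcome_levels())
  records <- validate_encounters(records)
  if (nrow(records) == 0L) stop("no encounters", call. = FALSE)
  levels_k <- intersect(ammo_types(), unique(records$ammo))
  arm <- factor(records$ammo, levels = levels_k)
  n_k <- as.vector(table(arm))
  if (any(n_k == 0L)) {
    stop("no records for arm(s): ",
         paste(levels_k[n_k == 0L], collapse = ", "), call. = FALSE)
  }
  y <- records$outcome == outcome
  y_k <- as.vector(tapply(y, arm, sum, default = 0))
  K <- length(levels_k)

  p0 <- (sum(y_k) + 0.5) / (sum(n_k) + 1)
  init <- c(stats::qlogis(p0), rep(0, K - 1L))
  names(init) <- c("beta0", if (K > 1L) paste0("beta_", levels_k[-1L]))
  chains <- mcmc_sample(
    function(b) logit_log_post(b, y_k, n_k, prior$coef_sd),
    init, settings)
  b0 <- chain_draws(chains, 1L)
  p_draws <- matrix(NA_real_, length(b0), K,
                    dimnames = list(NULL, levels_k))
  p_draws[, 1L] <- stats::plogis(b0)
  if (K > 1L) {
    for (k in 2L:K) {
      p_draws[, k] <- stats::plogis(b0 + chain_draws(chains, k))
    }
  }

  pooled_settings <- settings
  pooled_settings$seed <- settings$seed + 101L
  pooled <- mcmc_sample(
    function(b) logit_log_post(b, sum(y_k), sum(n_k), prior$coef_sd),
    c(beta0 = stats::qlogis(p0)), pooled_settings)
  overall_draws <- stats::plogis(chain_draws(pooled, 1L))

  n_chains <- settings$n_chains
  summaries <- do.call(rbind, lapply(seq_len(K), function(k) {
    eta <- if (k == 1L) chains$draws[, , 1L, drop = FALSE] else
      chains$draws[, , 1L, drop = FALSE] + chains$draws[, , k, drop = FALSE]
    pm <- stats::plogis(matrix(eta, n_chains))
    interval <- hpdi(as.vector(pm), 0.90)
    data.frame(ammo = levels_k[k], mean = mean(pm),
               hpdi_lo = interval[["lo"]], hpdi_hi = interval[["hi"]],
               rhat = if (n_chains >= 2L) gelman_rubin(t(pm)) else NA_real_)
  }))
  ov <- hpdi(overall_draws, 0.90)
  summaries <- rbind(summaries, data.frame(
    ammo = "ALL", mean = mean(overall_draws), hpdi_lo = ov[["lo"]],
    hpdi_hi = ov[["hi"]],
    rhat = if (n_chains >= 2L) {
      gelman_rubin(t(stats::plogis(matrix(pooled$draws[, , 1L], n_chains))))
    } else {
      NA_real_
    }))

  structure(list(outcome = outcome, levels = levels_k, y_k = y_k,
                 n_k = n_k, p_draws = p_draws,
                 overall_draws = overall_draws, summaries = summaries,
                 chains = chains, prior = prior, settings = settings),
            class = "outcome_fit")
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat("Encounter-outcome logistic fit for", x$outcome, "\n")
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Posterior probability that one quantity exceeds another
#'
#' The fraction of paired posterior draws in which `draws_a` exceeds
#' `draws_b`, with exact ties counted with weight one half (so that
#' `prob_greater(a, b) + prob_greater(b, a) = 1`). Unequal-length inputs
#' are truncated to the shorter length.
#'
#' @param draws_a,draws_b numeric vectors of posterior draws.
#' @return Probability in `[0, 1]`.
#' @export
prob_greater <- function(draws_a, draws_b) {
  if (length(draws_a) == 0L || length(draws_b) == 0L) {
    stop("empty draws", call. = FALSE)
  }
  m <- min(length(draws_a), length(draws_b))
  a <- draws_a[seq_len(m)]
  b <- draws_b[seq_len(m)]
  mean(a > b) + 0.5 * mean(a == b)
}
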