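# Exponential (Weibull shape = 1) time-to-event models for chase time and
# time to insensibility, with right-censored observations treated as
# interval-censored on [observed minimum, global maximum observed time] and
# imputed inside the sampler. Total time is derived within the model as
# chase time plus the observed or imputed time to insensibility.

#' Priors for the exponential survival models
#'
#' Pooled mode places a conjugate Gamma(`shape`, `rate`) prior directly on
#' the event rate. Covariate mode parameterises the per-ammunition rate as
#' `lambda_k = exp(beta0 + beta_k)` (reference-coded) with independent
#' Normal(0, `coef_sd`) priors on the coefficients. Both are weakly
#' informative package assumptions.
#'
#' @param shape,rate Gamma hyperparameters for the pooled rate.
#' @param coef_sd prior standard deviation of the log-rate coefficients.
#' @return A list of class `survival_prior`.
#' @export
survival_prior <- function(shape = 0.001, rate = 0.001, coef_sd = 10) {
  stopifnot(shape > 0, rate > 0, coef_sd > 0)
  structure(list(shape = shape, rate = rate, coef_sd = coef_sd),
            class = "survival_prior")
}

# Inverse-CDF draw from Exp(rate) truncated to [lo, hi], vectorised.
rtrunc_exp <- function(n, rate, lo, hi) {
  s_lo <- exp(-rate * lo)
  s_hi <- exp(-rate * hi)
  u <- stats::runif(n)
  s <- s_lo - u * (s_lo - s_hi)
  s <- pmin(pmax(s, .Machine$double.xmin), 1)
  t <- -log(s) / rate
  pmin(pmax(t, lo), hi)
}

exp_deviance <- function(n_k, sum_k, lambda_k) {
  -2 * sum(n_k * log(lambda_k) - lambda_k * sum_k)
}

#' Fit an exponential survival model
#'
#' Fits `f(t) = lambda exp(-lambda t)` to event times, either pooled
#' (one rate) or with ammunition type as a categorical covariate (one rate
#' per arm via reference-coded log-linear coefficients). Censored rows
#' carry only an observed minimum; their latent event times are imputed
#' every sweep from an interval distribution spanning the row's minimum
#' and the maximum time observed across all data. The default imputation
#' density is the model's own exponential truncated to that interval (the
#' proper Gibbs conditional); `imputation = "uniform"` is available as a
#' sensitivity mode.
#'
#' @param time event times in seconds: exact for uncensored rows, the
#'   observed minimum for censored rows.
#' @param censored logical vector; `NULL` means none censored.
#' @param ammo character vector of ammunition codes (required for
#'   `covariate_mode = "by_ammo"`).
#' @param covariate_mode `"pooled"` or `"by_ammo"`.
#' @param prior a [survival_prior()].
#' @param settings an [mcmc_settings()].
#' @param imputation `"truncated_exp"` (default) or `"uniform"`.
#' @param thin_impute keep every `thin_impute`-th sweep's latent times
#'   (and deviance contribution) for downstream derivation of total time.
#' @return An object of class `survival_fit` with per-arm rate draws,
#'   stored latent imputations, DIC, and convergence summaries.
#' @export
fit_exponential <- function(time, censored = NULL, ammo = NULL,
                            covariate_mode = c("pooled", "by_ammo"),
                            prior = survival_prior(),
                            settings = mcmc_settings(),
                            imputation = c("truncated_exp", "uniform"),
                            thin_impute = 10L) {
  covariate_mode <- match.arg(covariate_mode)
  imputation <- match.arg(imputation)
  n <- length(time)
  if (is.null(censored)) censored <- rep(FALSE, n)
  stopifnot(length(censored) == n)
  if (n == 0L) stop("no observations", call. = FALSE)
  if (all(censored)) stop("all values are censored", call. = FALSE)
  if (any(time[!censored] <= 0)) {
    stop("uncensored times must be > 0", call. = FALSE)
  }
  if (any(time[censored] < 0)) {
    stop("censored minima must be >= 0", call. = FALSE)
  }
  if (covariate_mode == "by_ammo") {
    if (is.null(ammo)) stop("ammo is required for by_ammo mode",
                            call. = FALSE)
    stopifnot(length(ammo) == n)
    levels_k <- intersect(ammo_types(), unique(ammo))
    if (length(setdiff(ammo, levels_k)) > 0L) {
      stop("unknown ammo code(s)", call. = FALSE)
    }
    arm <- match(ammo, levels_k)
  } else {
    levels_k <- "pooled"
    arm <- rep(1L, n)
  }
  K <- length(levels_k)
  upper <- max(time)       # global maximum observed time (censoring bound)
  cens_idx <- which(censored)
  n_cens <- length(cens_idx)
  lower <- time[cens_idx]
  n_k <- tabulate(arm, K)
  arm_f <- factor(arm, levels = seq_len(K))
  sum_obs_k <- as.vector(tapply(ifelse(censored, 0, time), arm_f, sum,
                                default = 0))
  sum_obs_k[is.na(sum_obs_k)] <- 0

  n_chains <- settings$n_chains
  n_keep <- settings$n_draws
  n_burn <- settings$n_burn
  keep_lat <- seq(from = thin_impute, to = n_keep, by = thin_impute)
  lat_slot <- integer(n_keep)
  lat_slot[keep_lat] <- seq_along(keep_lat)

  rate_draws <- array(NA_real_, dim = c(n_chains, n_keep, K),
                      dimnames = list(NULL, NULL, levels_k))
  deviance_draws <- matrix(NA_real_, n_chains, n_keep)
  imputed_store <- if (n_cens > 0L) {
    array(NA_real_, dim = c(n_chains, length(keep_lat), n_cens))
  } else {
    NULL
  }
  latent_mean <- rep(0, n_cens)
  latent_count <- 0L

  # Fast path: pooled, nothing censored -> conjugate Gamma posterior,
  # sampled iid (the latent-imputation machinery is bypassed entirely).
  if (covariate_mode == "pooled" && n_cens == 0L) {
    for (ch in seq_len(n_chains)) {
      set.seed(settings$seed + ch - 1L)
      lam <- stats::rgamma(n_keep, prior$shape + n,
                           prior$rate + sum(time))
      rate_draws[ch, , 1L] <- lam
      deviance_draws[ch, ] <- vapply(
        lam, function(l) exp_deviance(n, sum(time), l), numeric(1))
    }
  } else if (covariate_mode == "pooled") {
    cens_arm <- arm[cens_idx]
    for (ch in seq_len(n_chains)) {
      set.seed(settings$seed + ch - 1L)
      lam <- (n - n_cens) / sum(time[!censored])
      lat <- pmin(pmax(lower + 1 / lam, lower), upper)
      for (it in seq_len(n_burn + n_keep)) {
        lat <- if (imputation == "truncated_exp") {
          rtrunc_exp(n_cens, lam, lower, upper)
        } else {
          stats::runif(n_cens, lower, upper)
        }
        total <- sum_obs_k[1L] + sum(lat)
        lam <- stats::rgamma(1L, prior$shape + n, prior$rate + total)
        if (it > n_burn) {
          k <- it - n_burn
          rate_draws[ch, k, 1L] <- lam
          deviance_draws[ch, k] <- exp_deviance(n, total, lam)
          if (lat_slot[k] > 0L) imputed_store[ch, lat_slot[k], ] <- lat
          latent_mean <- latent_mean + lat
          latent_count <- latent_count + 1L
        }
      }
    }
  } else {
    # by-ammo: Metropolis-within-Gibbs on reference-coded coefficients,
    # alternating with the latent-time imputation. The likelihood reduces
    # to per-arm sufficient statistics (n_k, sum of times).
    cens_arm <- arm[cens_idx]
    d <- K  # intercept + K-1 contrasts
    for (ch in seq_len(n_chains)) {
      set.seed(settings$seed + ch - 1L)
      lam0 <- (n - n_cens) / sum(time[!censored])
      beta <- c(log(lam0), rep(0, K - 1L))
      if (ch > 1L) beta <- beta + stats::rnorm(d, 0, settings$init_jitter)
      log_scale <- rep(log(0.2), d)
      batch_acc <- numeric(d)
      batch_n <- 0L
      batch_idx <- 0L
      lam_k <- exp(c(beta[1L], beta[1L] + beta[-1L]))
      lat <- pmin(pmax(lower + 1 / lam_k[cens_arm], lower), upper)

      sum_k <- sum_obs_k
      if (n_cens > 0L) {
        sum_k <- sum_obs_k + as.vector(tapply(lat, factor(cens_arm,
                                                          levels = seq_len(K)),
                                              sum, default = 0))
        sum_k[is.na(sum_k)] <- sum_obs_k[is.na(sum_k)]
      }
      log_post <- function(b, sk) {
        lk <- exp(c(b[1L], b[1L] + b[-1L]))
        sum(n_k * log(lk) - lk * sk) - sum(b^2) / (2 * prior$coef_sd^2)
      }
      lp_cur <- log_post(beta, sum_k)

      for (it in seq_len(n_burn + n_keep)) {
        if (n_cens > 0L) {
          rate_i <- lam_k[cens_arm]
          lat <- if (imputation == "truncated_exp") {
            rtrunc_exp(n_cens, rate_i, lower, upper)
          } else {
            stats::runif(n_cens, lower, upper)
          }
          add <- as.vector(tapply(lat, factor(cens_arm, levels = seq_len(K)),
                                  sum, default = 0))
          add[is.na(add)] <- 0
          sum_k <- sum_obs_k + add
          lp_cur <- log_post(beta, sum_k)
        }
        for (j in seq_len(d)) {
          prop <- beta
          prop[j] <- beta[j] + exp(log_scale[j]) * stats::rnorm(1L)
          lp_prop <- log_post(prop, sum_k)
          if (is.finite(lp_prop) &&
              log(stats::runif(1L)) < lp_prop - lp_cur) {
            beta <- prop
            lp_cur <- lp_prop
            if (it <= n_burn) batch_acc[j] <- batch_acc[j] + 1
          }
        }
        lam_k <- exp(c(beta[1L], beta[1L] + beta[-1L]))
        if (it <= n_burn) {
          batch_n <- batch_n + 1L
          if (batch_n == 50L || it == n_burn) {
            batch_idx <- batch_idx + 1L
            delta <- min(0.1, 1 / sqrt(batch_idx))
            log_scale <- log_scale +
              ifelse(batch_acc / batch_n > settings$target_accept,
                     delta, -delta)
            batch_acc[] <- 0
            batch_n <- 0L
          }
        } else {
          k <- it - n_burn
          rate_draws[ch, k, ] <- lam_k
          deviance_draws[ch, k] <- exp_deviance(n_k, sum_k, lam_k)
          if (n_cens > 0L) {
            if (lat_slot[k] > 0L) imputed_store[ch, lat_slot[k], ] <- lat
            latent_mean <- latent_mean + lat
            latent_count <- latent_count + 1L
          }
        }
      }
    }
  }

  if (n_cens > 0L) {
    latent_mean <- latent_mean / latent_count
    # hard invariant: every stored latent lies in [row minimum, global max]
    lo_arr <- rep(lower, each = n_chains * length(keep_lat))
    stopifnot(all(imputed_store >= lo_arr - 1e-9),
              all(imputed_store <= upper + 1e-9))
  }

  rate_mean <- apply(rate_draws, 3L, mean)
  sum_k_mean <- sum_obs_k
  if (n_cens > 0L) {
    add <- as.vector(tapply(latent_mean,
                            factor(arm[cens_idx], levels = seq_len(K)),
                            sum, default = 0))
    add[is.na(add)] <- 0
    sum_k_mean <- sum_obs_k + add
  }
  dev_at_mean <- exp_deviance(n_k, sum_k_mean, rate_mean)
  fit_dic <- dic(as.vector(deviance_draws), dev_at_mean)

  summaries <- do.call(rbind, lapply(seq_len(K), function(k) {
    m <- t(rate_draws[, , k, drop = TRUE])
    if (n_chains == 1L) m <- matrix(rate_draws[1L, , k], ncol = 1L)
    v <- as.vector(rate_draws[, , k])
    interval <- hpdi(v, 0.90)
    data.frame(parameter = paste0("lambda_", levels_k[k]),
               mean = mean(v), hpdi_lo = interval[["lo"]],
               hpdi_hi = interval[["hi"]],
               rhat = if (n_chains >= 2L) gelman_rubin(m) else NA_real_)
  }))

  structure(list(
    rate_draws = rate_draws, levels = levels_k,
    covariate_mode = covariate_mode,
    time = time, censored = censored, ammo = ammo, arm = arm,
    upper = upper, lower = lower, cens_idx = cens_idx,
    imputed_draws = imputed_store, imputed_mean = latent_mean,
    keep_lat = keep_lat, deviance_draws = deviance_draws,
    dic = as.numeric(fit_dic), pD = attr(fit_dic, "pD"),
    summaries = summaries, prior = prior, settings = settings,
    imputation = imputation, thin_impute = as.integer(thin_impute)),
    class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("Exponential survival fit (", x$covariate_mode, " mode), n = ",
      length(x$time), ", censored = ", sum(x$censored), "\n", sep = "")
  print(x$summaries, row.names = FALSE)
  cat("DIC:", format(x$dic, digits = 6), " (pD =",
      format(x$pD, digits = 3), ")\n")
  invisible(x)
}

# All rate draws for one arm (or the pooled rate) as a vector.
rate_draws_vector <- function(fit, level = 1L) {
  as.vector(fit$rate_draws[, , level])
}

#' Total time derived within the model
#'
#' For each stored imputation sweep, total time per animal is chase time
#' plus the observed or imputed time to insensibility; a second
#' exponential model is then fitted to those complete total times by its
#' conjugate Gamma update, and the rate draws are pooled across sweeps so
#' that imputation uncertainty propagates into the total-time fit.
#' `mode = "mean"` conditions on the posterior-mean imputation instead.
#'
#' @param fit a [fit_exponential()] fit to time-to-insensibility.
#' @param ct chase time in seconds, aligned with the rows of `fit`.
#' @param prior a [survival_prior()] for the total-time rate.
#' @param mode `"integrate"` (default) or `"mean"`.
#' @param draws_per_sweep conjugate rate draws taken per stored sweep.
#' @return A `survival_fit`-like object of class `tt_fit` with rate draws,
#'   per-animal total-time draws and DIC.
#' @export
derive_tt <- function(fit, ct, prior = survival_prior(),
                      mode = c("integrate", "mean"),
                      draws_per_sweep = 10L) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "survival_fit"))
  n <- length(fit$time)
  if (length(ct) != n) {
    stop("chase times are misaligned with the survival fit (", length(ct),
         " vs ", n, " rows)", call. = FALSE)
  }
  if (any(is.na(ct) | ct < 0)) stop("chase times must be >= 0",
                                    call. = FALSE)
  K <- length(fit$levels)
  n_k <- tabulate(fit$arm, K)
  n_cens <- length(fit$cens_idx)

  sweep_list <- if (mode == "mean" || n_cens == 0L) {
    list(fit$imputed_mean)
  } else {
    ims <- fit$imputed_draws
    lapply(seq_len(dim(ims)[1L] * dim(ims)[2L]), function(i) {
      ch <- ((i - 1L) %/% dim(ims)[2L]) + 1L
      it <- ((i - 1L) %% dim(ims)[2L]) + 1L
      ims[ch, it, ]
    })
  }
  n_sweeps <- length(sweep_list)
  per_sweep <- if (n_sweeps == 1L) {
    max(draws_per_sweep, 1000L)  # conditioning on one imputation: draw many
  } else {
    draws_per_sweep
  }

  set.seed(fit$settings$seed + 7919L)
  rate_out <- matrix(NA_real_, n_sweeps * per_sweep, K,
                     dimnames = list(NULL, fit$levels))
  tt_store <- matrix(NA_real_, n_sweeps, n)
  dev_draws <- numeric(n_sweeps * per_sweep)
  row <- 0L
  for (s in seq_len(n_sweeps)) {
    tti <- fit$time
    if (n_cens > 0L) tti[fit$cens_idx] <- sweep_list[[s]]
    tt <- ct + tti
    tt_store[s, ] <- tt
    sum_k <- as.vector(tapply(tt, factor(fit$arm, levels = seq_len(K)),
                              sum, default = 0))
    sum_k[is.na(sum_k)] <- 0
    for (r in seq_len(per_sweep)) {
      row <- row + 1L
      lam <- stats::rgamma(K, prior$shape + n_k, prior$rate + sum_k)
      rate_out[row, ] <- lam
      dev_draws[row] <- exp_deviance(n_k, sum_k, lam)
    }
  }

  tt_mean <- colMeans(tt_store)
  sum_k_mean <- as.vector(tapply(tt_mean, factor(fit$arm,
                                                 levels = seq_len(K)),
                                 sum, default = 0))
  sum_k_mean[is.na(sum_k_mean)] <- 0
  lam_mean <- colMeans(rate_out)
  fit_dic <- dic(dev_draws, exp_deviance(n_k, sum_k_mean, lam_mean))

  summaries <- do.call(rbind, lapply(seq_len(K), function(k) {
    interval <- hpdi(rate_out[, k], 0.90)
    data.frame(parameter = paste0("lambda_tt_", fit$levels[k]),
               mean = mean(rate_out[, k]), hpdi_lo = interval[["lo"]],
               hpdi_hi = interval[["hi"]], rhat = NA_real_)
  }))

  structure(list(
    rate_draws = rate_out, levels = fit$levels,
    covariate_mode = fit$covariate_mode, tt_draws = tt_store,
    tt_mean = tt_mean, arm = fit$arm, ammo = fit$ammo, mode = mode,
    dic = as.numeric(fit_dic), pD = attr(fit_dic, "pD"),
    summaries = summaries, prior = prior),
    class = "tt_fit")
}

#' @export
print.tt_fit <- function(x, ...) {
  cat("Total-time exponential fit (", x$covariate_mode, " mode, ",
      x$mode, " over imputations)\n", sep = "")
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Percentile of an exponential time-to-event distribution
#'
#' The time by which a proportion `q` of animals has reached the event:
#' `-log(1 - q) / lambda`. Applied to posterior rate draws it yields
#' posterior draws of, e.g., the time by which 95% of animals are
#' insensible.
#'
#' @param lambda event rate(s), per second.
#' @param q probability in (0, 1).
#' @return Time(s) in seconds.
#' @export
#' @examples
#' surv_percentile(log(20) / 43, 0.95)  # 43 seconds
surv_percentile <- function(lambda, q) {
  stopifnot(all(lambda > 0), q > 0, q < 1)
  -log(1 - q) / lambda
}

#' Posterior survival curve
#'
#' Pointwise posterior mean and 90% HPDI of `S(t) = exp(-lambda t)` over
#' the rate draws, per ammunition arm.
#'
#' @param fit a `survival_fit` or `tt_fit`.
#' @param t_grid times (seconds) at which to evaluate the curve.
#' @param mass HPDI mass.
#' @return data.frame with columns `ammo`, `t`, `mean`, `lo`, `hi`.
#' @export
survival_curve <- function(fit, t_grid, mass = 0.90) {
  stopifnot(all(t_grid >= 0))
  K <- length(fit$levels)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    lam <- if (inherits(fit, "tt_fit")) fit$rate_draws[, k] else
      rate_draws_vector(fit, k)
    surv <- exp(-outer(lam, t_grid))
    bands <- apply(surv, 2L, hpdi, mass = mass)
    out[[k]] <- data.frame(ammo = fit$levels[k], t = t_grid,
                           mean = colMeans(surv),
                           lo = bands["lo", ], hi = bands["hi", ])
  }
  do.call(rbind, out)
}

#' Compare the covariate and pooled survival models by DIC
#'
#' @param fit_by_ammo exponential fit with the ammunition covariate.
#' @param fit_pooled exponential fit without it, on the same data.
#' @return list with `dic_by_ammo`, `dic_pooled` and `preferred`
#'   (`"by_ammo"`, `"pooled"`, or `"tie"`).
#' @export
compare_models <- function(fit_by_ammo, fit_pooled) {
  stopifnot(inherits(fit_by_ammo, "survival_fit"),
            inherits(fit_pooled, "survival_fit"))
  if (!isTRUE(all.equal(fit_by_ammo$time, fit_pooled$time)) ||
      !identical(fit_by_ammo$censored, fit_pooled$censored)) {
    stop("the two fits are not on identical data", call. = FALSE)
  }
  d1 <- fit_by_ammo$dic
  d2 <- fit_pooled$dic
  preferred <- if (isTRUE(all.equal(d1, d2))) "tie" else
    if (d1 < d2) "by_ammo" else "pooled"
  list(dic_by_ammo = d1, dic_pooled = d2, preferred = preferred)
}
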