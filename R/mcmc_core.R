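# Sampling engine and diagnostics shared by every model in the package:
# adaptive per-coordinate random-walk Metropolis, highest-posterior-density
# intervals, the Gelman-Rubin statistic and DIC.

#' MCMC sampler settings
#'
#' Defaults follow the trial's reporting convention: four chains, 10,000
#' retained draws per chain after 5,000 burn-in draws. Proposal scales are
#' adapted per coordinate during burn-in towards a 0.44 acceptance rate
#' (the optimum for one-dimensional random-walk updates) and frozen
#' afterwards so the post-burn-in kernel satisfies detailed balance.
#'
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_draws retained draws per chain.
#' @param n_burn burn-in draws per chain (adaptation window).
#' @param seed master seed; chain `c` uses `seed + c - 1`.
#' @param target_accept per-coordinate acceptance target during adaptation.
#' @param init_scale initial proposal standard deviation.
#' @param init_jitter sd of the over-dispersion jitter applied to shared
#'   initial values in chains after the first.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 4L, n_draws = 10000L, n_burn = 5000L,
                          seed = 1L, target_accept = 0.44, init_scale = 1,
                          init_jitter = 0.5) {
  stopifnot(n_chains >= 1L, n_draws >= 1L, n_burn >= 0L,
            target_accept > 0, target_accept < 1, init_scale > 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_draws = as.integer(n_draws),
                 n_burn = as.integer(n_burn),
                 seed = as.integer(seed),
                 target_accept = target_accept,
                 init_scale = init_scale,
                 init_jitter = init_jitter),
            class = "mcmc_settings")
}

#' Draw from a log-posterior by adaptive random-walk Metropolis
#'
#' Runs `settings$n_chains` independent chains of per-coordinate
#' random-walk Metropolis. Proposal scales adapt in batches of 50
#' iterations during burn-in only (Robbins-Monro step shrinking with the
#' batch index) and are frozen for the retained draws.
#'
#' @param log_posterior function taking a parameter vector and returning
#'   the unnormalised log posterior density.
#' @param init named numeric vector of initial values, or a matrix with
#'   one row per chain.
#' @param settings an [mcmc_settings()] object.
#' @return An object of class `chain_set`: list with `draws` (array
#'   `chain x iteration x parameter`), `accept_rate` (chain x parameter),
#'   and the settings used.
#' @export
mcmc_sample <- function(log_posterior, init, settings = mcmc_settings()) {
  if (is.matrix(init)) {
    stopifnot(nrow(init) == settings$n_chains)
    init_mat <- init
  } else {
    init_mat <- matrix(init, nrow = settings$n_chains, ncol = length(init),
                       byrow = TRUE)
    colnames(init_mat) <- names(init)
  }
  d <- ncol(init_mat)
  pnames <- colnames(init_mat)
  if (is.null(pnames)) pnames <- paste0("param", seq_len(d))
  n_keep <- settings$n_draws
  n_burn <- settings$n_burn
  draws <- array(NA_real_,
                 dim = c(settings$n_chains, n_keep, d),
                 dimnames = list(NULL, NULL, pnames))
  accept_rate <- matrix(NA_real_, settings$n_chains, d,
                        dimnames = list(NULL, pnames))

  for (ch in seq_len(settings$n_chains)) {
    set.seed(settings$seed + ch - 1L)
    cur <- init_mat[ch, ]
    if (ch > 1L) cur <- cur + stats::rnorm(d, 0, settings$init_jitter)
    lp_cur <- log_posterior(cur)
    if (!is.finite(lp_cur)) {
      # fall back to the undisturbed init before failing
      cur <- init_mat[ch, ]
      lp_cur <- log_posterior(cur)
    }
    if (!is.finite(lp_cur)) {
      stop("log posterior is not finite at the initial value of chain ",
           ch, call. = FALSE)
    }
    log_scale <- rep(log(settings$init_scale), d)
    batch_acc <- numeric(d)
    batch_n <- 0L
    batch_idx <- 0L
    acc_post <- numeric(d)
    chain_draws <- matrix(NA_real_, n_keep, d)

    for (it in seq_len(n_burn + n_keep)) {
      adapting <- it <= n_burn
      for (j in seq_len(d)) {
        prop <- cur
        prop[j] <- cur[j] + exp(log_scale[j]) * stats::rnorm(1L)
        lp_prop <- log_posterior(prop)
        if (is.finite(lp_prop) &&
            log(stats::runif(1L)) < lp_prop - lp_cur) {
          cur <- prop
          lp_cur <- lp_prop
          if (adapting) batch_acc[j] <- batch_acc[j] + 1
          else acc_post[j] <- acc_post[j] + 1
        }
      }
      if (adapting) {
        batch_n <- batch_n + 1L
        if (batch_n == 50L || it == n_burn) {
          batch_idx <- batch_idx + 1L
          delta <- min(0.1, 1 / sqrt(batch_idx))
          rate <- batch_acc / batch_n
          log_scale <- log_scale +
            ifelse(rate > settings$target_accept, delta, -delta)
          batch_acc[] <- 0
          batch_n <- 0L
        }
      } else {
        chain_draws[it - n_burn, ] <- cur
      }
    }
    draws[ch, , ] <- chain_draws
    accept_rate[ch, ] <- acc_post / n_keep
  }

  out_of_band <- accept_rate < 0.05 | accept_rate > 0.8
  if (any(out_of_band)) {
    warning("post-adaptation acceptance rate outside (0.05, 0.8) for ",
            sum(out_of_band), " chain/parameter combination(s)",
            call. = FALSE)
  }
  structure(list(draws = draws, accept_rate = accept_rate,
                 settings = settings, parameters = pnames),
            class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  cat("chain_set:", dim(x$draws)[1L], "chains x", dim(x$draws)[2L],
      "draws x", dim(x$draws)[3L], "parameter(s)\n")
  print(summary(x))
  invisible(x)
}

#' @export
summary.chain_set <- function(object, mass = 0.90, ...) {
  d <- dim(object$draws)[3L]
  out <- do.call(rbind, lapply(seq_len(d), function(j) {
    posterior_summary(object, parameter = j, mass = mass)
  }))
  out$parameter <- object$parameters
  out[, c("parameter", "mean", "hpdi_lo", "hpdi_hi", "rhat")]
}

# Flatten a chain_set parameter to a plain vector of draws.
chain_draws <- function(chains, parameter = 1L) {
  as.vector(chains$draws[, , parameter])
}

# Parameter draws as an iterations x chains matrix.
chain_matrix <- function(chains, parameter = 1L) {
  t(chains$draws[, , parameter, drop = TRUE])
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval of the sorted draws containing
#' `ceiling(mass * n)` points. Ties between equally short windows are
#' broken towards the lowest starting index, making the result
#' deterministic.
#'
#' @param draws numeric vector of posterior draws (at least 10).
#' @param mass interval probability mass, in (0, 1); 0.90 by default.
#' @return Numeric vector `c(lo, hi)`.
#' @export
#' @examples
#' hpdi(rexp(1000), 0.9)
hpdi <- function(draws, mass = 0.90) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1) {
    stop("mass must be a single value in (0, 1)", call. = FALSE)
  }
  draws <- draws[!is.na(draws)]
  n <- length(draws)
  if (n < 10L) stop("need at least 10 draws for an HPDI", call. = FALSE)
  m <- ceiling(mass * n)
  xs <- sort(draws)
  widths <- xs[m:n] - xs[seq_len(n - m + 1L)]
  i <- which.min(widths)  # which.min returns the first minimum: lowest start
  c(lo = xs[i], hi = xs[i + m - 1L])
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classical (non-split) form: with `W` the mean within-chain variance and
#' `B/n` the variance of chain means,
#' `rhat = sqrt(((n - 1)/n * W + B/n) / W)`. Values near 1 indicate the
#' chains are sampling the same distribution. Set `split = TRUE` to halve
#' each chain first (diagnoses within-chain trends).
#'
#' @param chains a `chain_set`, or an iterations x chains numeric matrix.
#' @param parameter parameter index or name (for a `chain_set`).
#' @param split halve each chain before computing the statistic.
#' @return The scalar potential scale reduction factor.
#' @export
gelman_rubin <- function(chains, parameter = 1L, split = FALSE) {
  m <- if (inherits(chains, "chain_set")) {
    chain_matrix(chains, parameter)
  } else {
    as.matrix(chains)
  }
  if (ncol(m) < 2L) stop("need at least 2 chains", call. = FALSE)
  if (nrow(m) < 10L) stop("need at least 10 draws per chain", call. = FALSE)
  if (split) {
    half <- floor(nrow(m) / 2L)
    m <- cbind(m[seq_len(half), , drop = FALSE],
               m[(nrow(m) - half + 1L):nrow(m), , drop = FALSE])
  }
  n <- nrow(m)
  within <- apply(m, 2L, stats::var)
  W <- mean(within)
  if (W <= 0 || !is.finite(W)) {
    stop("zero within-chain variance: chains are degenerate", call. = FALSE)
  }
  B_over_n <- stats::var(colMeans(m))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Deviance information criterion
#'
#' `DIC = mean(D) + pD` where `D` are posterior draws of the deviance
#' (-2 log likelihood) and `pD = mean(D) - D(at posterior mean)` is the
#' effective number of parameters.
#'
#' @param deviance_draws numeric vector of deviance draws.
#' @param deviance_at_mean deviance evaluated at the posterior mean of the
#'   parameters (and of any latent quantities).
#' @return The DIC value, with attributes `pD` and `mean_deviance`.
#' @export
dic <- function(deviance_draws, deviance_at_mean) {
  stopifnot(is.numeric(deviance_draws), length(deviance_draws) >= 1L,
            is.numeric(deviance_at_mean), length(deviance_at_mean) == 1L)
  if (any(!is.finite(deviance_draws)) || !is.finite(deviance_at_mean)) {
    stop("deviance values must be finite", call. = FALSE)
  }
  dbar <- mean(deviance_draws)
  pd <- dbar - deviance_at_mean
  if (pd < 0) {
    warning("negative effective parameter count pD = ",
            format(pd, digits = 4), call. = FALSE)
  }
  structure(dbar + pd, pD = pd, mean_deviance = dbar)
}

#' Posterior summary of one scalar quantity
#'
#' Posterior mean, 90% highest-density interval, and (when chain structure
#' is available) the Gelman-Rubin statistic.
#'
#' @param draws numeric vector of draws, or a `chain_set`.
#' @param parameter parameter index or name when `draws` is a `chain_set`.
#' @param mass HPDI mass (default 0.90).
#' @return One-row data.frame with columns `mean`, `hpdi_lo`, `hpdi_hi`,
#'   `mass`, `rhat`.
#' @export
posterior_summary <- function(draws, parameter = 1L, mass = 0.90) {
  if (inherits(draws, "chain_set")) {
    v <- chain_draws(draws, parameter)
    rhat <- if (dim(draws$draws)[1L] >= 2L) {
      gelman_rubin(draws, parameter)
    } else {
      NA_real_
    }
  } else {
    v <- as.numeric(draws)
    rhat <- NA_real_
  }
  interval <- hpdi(v, mass)
  data.frame(mean = mean(v), hpdi_lo = interval[["lo"]],
             hpdi_hi = interval[["hi"]], mass = mass, rhat = rhat)
}
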