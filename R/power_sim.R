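# Simulation-based sample-size analysis for detecting an increase in
# total time against a log-normal baseline described by its geometric
# mean and 5th/95th percentiles.

#' Log-normal parameters from a geometric mean and outer percentiles
#'
#' `meanlog = log(geometric mean)`;
#' `sdlog = log(p95 / p5) / (2 z_0.95)` with `z_0.95` the standard-normal
#' 95th percentile, so that the stated percentiles sit symmetrically on
#' the log scale.
#'
#' @param geometric_mean geometric-mean time, seconds.
#' @param p5,p95 5th and 95th percentiles, seconds.
#' @return Named vector `c(meanlog, sdlog)`.
#' @export
#' @examples
#' lognormal_from_summary(148, 50, 700)
lognormal_from_summary <- function(geometric_mean = 148, p5 = 50,
                                   p95 = 700) {
  if (!(p5 > 0 && p5 < geometric_mean && geometric_mean < p95)) {
    stop("need 0 < p5 < geometric_mean < p95", call. = FALSE)
  }
  c(meanlog = log(geometric_mean),
    sdlog = log(p95 / p5) / (2 * stats::qnorm(0.95)))
}

power_rejections <- function(n, delta, sdlog, reps, alpha, test,
                             meanlog) {
  if (test == "t") {
    # pooled-variance one-sided two-sample t on log-times, vectorised
    x <- matrix(stats::rnorm(reps * n, meanlog, sdlog), reps)
    y <- matrix(stats::rnorm(reps * n, meanlog + delta, sdlog), reps)
    mx <- rowMeans(x)
    my <- rowMeans(y)
    vx <- (rowSums(x^2) - n * mx^2) / (n - 1)
    vy <- (rowSums(y^2) - n * my^2) / (n - 1)
    tt <- (my - mx) / sqrt((vx + vy) / n)
    return(tt > stats::qt(1 - alpha, 2 * n - 2))
  }
  reject <- logical(reps)
  for (r in seq_len(reps)) {
    x <- stats::rlnorm(n, meanlog, sdlog)
    y <- stats::rlnorm(n, meanlog + delta, sdlog)
    reject[r] <- switch(
      test,
      wilcoxon = stats::wilcox.test(y, x, alternative = "greater",
                                    exact = FALSE)$p.value < alpha,
      lrt = {
        # exponential-rate likelihood ratio, one-sided via signed root
        n2 <- 2L * n
        lam0 <- n2 / (sum(x) + sum(y))
        ll1 <- n * log(n / sum(x)) - n + n * log(n / sum(y)) - n
        ll0 <- n2 * log(lam0) - lam0 * (sum(x) + sum(y))
        z <- sign(mean(y) - mean(x)) * sqrt(pmax(2 * (ll1 - ll0), 0))
        z > stats::qnorm(1 - alpha)
      })
  }
  reject
}

#' Monte-Carlo power for detecting a total-time increase
#'
#' Per replicate, draws a control group of `n` log-normal times at the
#' baseline parameters and a treatment group with the log-mean shifted by
#' `log((gm + effect_s) / gm)` (the effect added to the geometric mean),
#' then applies a one-sided two-sample test at level `alpha`. Power is
#' the rejection fraction; its Monte-Carlo standard error is
#' `sqrt(power (1 - power) / reps)`.
#'
#' @param effect_s increase in the geometric-mean time, seconds (>= 0).
#' @param n animals per group.
#' @param reps Monte-Carlo replicates.
#' @param alpha one-sided test level.
#' @param geometric_mean,p5,p95 baseline log-normal summary.
#' @param test `"t"` (pooled-variance t on log-times, default),
#'   `"wilcoxon"`, or `"lrt"` (exponential-rate likelihood ratio).
#' @param seed optional seed.
#' @return list of class `power_result`: `power`, `mc_se`, and the
#'   configuration used.
#' @export
simulate_power <- function(effect_s, n = 100L, reps = 10000L,
                           alpha = 0.05, geometric_mean = 148, p5 = 50,
                           p95 = 700, test = c("t", "wilcoxon", "lrt"),
                           seed = NULL) {
  test <- match.arg(test)
  stopifnot(effect_s >= 0, n >= 2L, alpha > 0, alpha < 1)
  if (reps < 100L) {
    warning("fewer than 100 replicates: Monte-Carlo error will be large",
            call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pars <- lognormal_from_summary(geometric_mean, p5, p95)
  delta <- log((geometric_mean + effect_s) / geometric_mean)
  reject <- power_rejections(n, delta, pars[["sdlog"]], reps, alpha,
                             test, pars[["meanlog"]])
  power <- mean(reject)
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / reps),
                 effect_s = effect_s, n = n, reps = reps, alpha = alpha,
                 geometric_mean = geometric_mean, p5 = p5, p95 = p95,
                 test = test),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "power %.3f (MC se %.4f) | n=%d/group, effect +%g s, %s test, alpha %g\n",
    x$power, x$mc_se, x$n, x$effect_s, x$test, x$alpha))
  invisible(x)
}

#' Power across a set of effect sizes
#'
#' @param effects vector of effect sizes, seconds.
#' @param ... passed to [simulate_power()]; when `seed` is supplied, each
#'   effect uses `seed + index - 1` so rows are independently seeded.
#' @param seed optional base seed.
#' @return data.frame with columns `effect_s`, `n`, `power`, `mc_se`.
#' @export
power_table <- function(effects, ..., seed = NULL) {
  stopifnot(length(effects) >= 1L)
  rows <- lapply(seq_along(effects), function(i) {
    r <- simulate_power(effects[i], ...,
                        seed = if (is.null(seed)) NULL else seed + i - 1L)
    data.frame(effect_s = r$effect_s, n = r$n, power = r$power,
               mc_se = r$mc_se)
  })
  do.call(rbind, rows)
}

#' Normal-theory power approximation
#'
#' Closed-form power of the one-sided pooled two-sample t-test on
#' log-times via the noncentral t distribution, for comparison with the
#' Monte-Carlo estimate.
#'
#' @inheritParams simulate_power
#' @return Power in `[0, 1]`.
#' @export
power_analytic <- function(effect_s, n = 100L, alpha = 0.05,
                           geometric_mean = 148, p5 = 50, p95 = 700) {
  pars <- lognormal_from_summary(geometric_mean, p5, p95)
  delta <- log((geometric_mean + effect_s) / geometric_mean)
  df <- 2 * n - 2
  ncp <- delta / (pars[["sdlog"]] * sqrt(2 / n))
  1 - stats::pt(stats::qt(1 - alpha, df), df, ncp = ncp)
}
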