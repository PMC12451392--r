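# Pipeline orchestration: simulate -> fit -> report, with a YAML
# configuration, seeded runs and a JSON manifest recording provenance.

#' Read and write simulation configurations as YAML
#'
#' @param path YAML file path.
#' @return `read_sim_config()`: a [sim_config()]. `write_sim_config()`:
#'   `path`, invisibly.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (f in c("ct_lognormal", "tti_rate_per_ammo", "p_instant_per_ammo",
              "zone_weights", "thorax_concentration", "sex_age_probs",
              "mass_lognormal")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$sortie_sizes)) raw$sortie_sizes <-
    as.integer(unlist(raw$sortie_sizes))
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- unclass(config)
  out <- out[!vapply(out, is.null, logical(1L))]
  out <- lapply(out, function(v) if (!is.null(names(v))) as.list(v) else v)
  yaml::write_yaml(out, path)
  invisible(path)
}

write_manifest <- function(out_dir, stage, seed, inputs, outputs,
                           rhat_worst = NULL, config_hash = NULL) {
  if (!is.null(rhat_worst)) {
    # drop slots with no chain structure (conjugate refits) rather than
    # serialising NA
    rhat_worst <- Filter(function(x) is.finite(x), rhat_worst)
  }
  manifest <- list(
    package = "cullwelfare",
    version = as.character(utils::packageVersion("cullwelfare")),
    stage = stage,
    seed = seed,
    config_hash = config_hash,
    inputs = as.list(inputs),
    outputs = as.list(outputs),
    rhat_worst = rhat_worst,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  missing_out <- outputs[!file.exists(unlist(outputs))]
  if (length(missing_out) > 0L) {
    stop("manifest lists output file(s) that were not written: ",
         paste(missing_out, collapse = ", "), call. = FALSE)
  }
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Simulate a trial data set to disk
#'
#' Generates `encounters.csv` and `postmortem.csv` under `out_dir` from a
#' YAML configuration (or a [sim_config()] object) and writes a run
#' manifest. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()] or the path of a YAML config file.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of the config seed.
#' @return Named character vector of the written CSV paths, invisibly.
#' @export
run_simulate <- function(config, out_dir, seed = NULL) {
  config_hash <- NULL
  if (is.character(config)) {
    config_hash <- unname(tools::md5sum(config))
    config <- read_sim_config(config)
  }
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  enc <- simulate_encounters(config)
  pm <- simulate_postmortem(enc, config)
  paths <- c(encounters = file.path(out_dir, "encounters.csv"),
             postmortem = file.path(out_dir, "postmortem.csv"))
  write_encounters(enc, paths[["encounters"]])
  write_postmortem(pm, paths[["postmortem"]])
  write_manifest(out_dir, "simulate", config$seed, character(0), paths,
                 config_hash = config_hash)
  invisible(paths)
}

fit_summary_path <- function(out_dir, model) {
  file.path(out_dir, paste0("fit_", model, ".csv"))
}

#' Fit the requested models and write summary CSVs
#'
#' Runs any subset of the trial's models on an encounter table (and
#' post-mortem table where needed) and writes one summary CSV per model
#' (`parameter`-level posterior mean, 90% HPDI and R-hat), survival-curve
#' CSVs for the time-to-event fits, a welfare-metrics CSV, and a
#' manifest. A model whose worst R-hat exceeds 1.1 is recorded as not
#' converged and its summary is still written, flagged in the manifest;
#' the run continues.
#'
#' @param encounters path to `encounters.csv`.
#' @param postmortem path to `postmortem.csv` (required for `wounds` /
#'   `pellets`).
#' @param out_dir output directory.
#' @param which subset of `c("outcome", "ct", "tti", "tt", "wounds",
#'   "pellets")`.
#' @param settings an [mcmc_settings()] shared by all fits.
#' @return Invisibly, a list of the fitted objects.
#' @export
run_fit <- function(encounters, postmortem = NULL, out_dir,
                    which = c("outcome", "ct", "tti", "tt", "wounds",
                              "pellets"),
                    settings = mcmc_settings()) {
  if (length(which) > 0L) {
    which <- match.arg(which, several.ok = TRUE)
  } else {
    which <- character(0)
  }
  enc <- read_encounters(encounters)
  pm <- NULL
  if (any(c("wounds", "pellets") %in% which)) {
    if (is.null(postmortem)) {
      stop("post-mortem file required for wound/pellet models",
           call. = FALSE)
    }
    pm <- read_postmortem(postmortem)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  fits <- list()
  outputs <- character(0)
  rhat_worst <- list()
  add_summary <- function(model, summaries) {
    p <- fit_summary_path(out_dir, model)
    utils::write.csv(summaries, p, row.names = FALSE)
    outputs <<- c(outputs, p)
    worst <- suppressWarnings(max(summaries$rhat, na.rm = TRUE))
    rhat_worst[[model]] <<- if (is.finite(worst)) worst else NA_real_
    if (is.finite(worst) && worst > 1.1) {
      warning("model '", model, "' did not converge (worst R-hat ",
              format(worst, digits = 4), ")", call. = FALSE)
    }
  }

  killed <- !(enc$outcome %in% c("WOUNDED_ESCAPED", "MISSED_ESCAPED"))
  if ("outcome" %in% which) {
    fits$outcome <- fit_outcome(enc, settings = settings)
    add_summary("outcome", fits$outcome$summaries)
  }
  if (any(c("ct", "tti", "tt") %in% which)) {
    kk <- enc[killed, ]
    if ("ct" %in% which) {
      fits$ct <- fit_exponential(kk$ct_s, ammo = kk$ammo,
                                 covariate_mode = "by_ammo",
                                 settings = settings)
      add_summary("ct", fits$ct$summaries)
      grid <- seq(0, stats::quantile(kk$ct_s, 0.99), length.out = 60L)
      utils::write.csv(survival_curve(fits$ct, grid),
                       file.path(out_dir, "curve_ct.csv"),
                       row.names = FALSE)
      outputs <- c(outputs, file.path(out_dir, "curve_ct.csv"))
    }
    if (any(c("tti", "tt") %in% which)) {
      fits$tti <- fit_exponential(kk$tti_s, censored = kk$tti_censored,
                                  ammo = kk$ammo,
                                  covariate_mode = "by_ammo",
                                  settings = settings)
      if ("tti" %in% which) {
        add_summary("tti", fits$tti$summaries)
        grid <- seq(0, max(kk$tti_s) * 1.2, length.out = 60L)
        utils::write.csv(survival_curve(fits$tti, grid),
                         file.path(out_dir, "curve_tti.csv"),
                         row.names = FALSE)
        outputs <- c(outputs, file.path(out_dir, "curve_tti.csv"))
      }
      if ("tt" %in% which) {
        fits$tt <- derive_tt(fits$tti, kk$ct_s)
        add_summary("tt", fits$tt$summaries)
      }
    }
  }
  if ("wounds" %in% which) {
    ammo_pm <- enc$ammo[match(pm$animal_id, enc$animal_id)]
    fits$wounds <- fit_wound_tracts(pm, ammo_pm, settings = settings)
    add_summary("wounds", fits$wounds$summaries)
  }
  if ("pellets" %in% which) {
    ammo_pm <- enc$ammo[match(pm$animal_id, enc$animal_id)]
    fits$zones <- fit_zone_proportions(pm, ammo_pm, settings = settings)
    add_summary("zones", fits$zones$summaries)
    fits$pellets <- fit_missing_pellets(pm, ammo_pm, settings = settings)
    add_summary("pellets", fits$pellets$summaries)
  }

  # headline welfare metrics available without any fit
  metrics <- data.frame(metric = "nfwr", value = nfwr(enc))
  if (!is.null(fits[["tti"]])) {
    lam <- colMeans(fits[["tti"]]$rate_draws[, , , drop = FALSE],
                    dims = 2L)
    metrics <- rbind(metrics, data.frame(
      metric = paste0("median_tti_", fits[["tti"]]$levels),
      value = surv_percentile(lam, 0.5)))
    metrics <- rbind(metrics, data.frame(
      metric = paste0("t95_tti_", fits[["tti"]]$levels),
      value = surv_percentile(lam, 0.95)))
  }
  if (!is.null(fits[["ct"]])) {
    lam <- colMeans(fits[["ct"]]$rate_draws[, , , drop = FALSE], dims = 2L)
    metrics <- rbind(metrics, data.frame(
      metric = paste0("median_ct_", fits[["ct"]]$levels),
      value = surv_percentile(lam, 0.5)))
  }
  if (!is.null(fits[["tt"]])) {
    lam <- colMeans(fits[["tt"]]$rate_draws)
    metrics <- rbind(metrics, data.frame(
      metric = paste0("median_tt_", fits[["tt"]]$levels),
      value = surv_percentile(lam, 0.5)))
  }
  metrics_path <- file.path(out_dir, "metrics.csv")
  utils::write.csv(metrics, metrics_path, row.names = FALSE)
  outputs <- c(outputs, metrics_path)

  write_manifest(out_dir, "fit", settings$seed,
                 c(encounters, postmortem), outputs,
                 rhat_worst = rhat_worst)
  invisible(fits)
}

#' Assemble a human-readable welfare report
#'
#' Collects the summary CSVs written by [run_fit()] into one text report:
#' the non-fatal wounding rate, per-arm median chase time, time to
#' insensibility and total time, instant-insensibility probabilities, and
#' (when both survival fits are present) the DIC comparison. Sections
#' whose fits were not run are marked absent. Rerunning on the same
#' directory reproduces the identical report.
#'
#' @param out_dir directory holding `run_fit()` outputs.
#' @return The report path, invisibly; the report text is also returned
#'   as attribute `"text"`.
#' @export
run_report <- function(out_dir) {
  metrics_path <- file.path(out_dir, "metrics.csv")
  if (!file.exists(metrics_path)) {
    stop("no fit outputs in ", out_dir, " (metrics.csv missing)",
         call. = FALSE)
  }
  metrics <- utils::read.csv(metrics_path)
  get_metric <- function(name) {
    v <- metrics$value[metrics$metric == name]
    if (length(v) == 0L) NA_real_ else v
  }
  lines <- c("Aerial culling welfare report",
             "=============================", "")
  lines <- c(lines, sprintf("NFWR = %.2f (proportion of hit animals escaping)",
                            get_metric("nfwr")), "")

  med_rows <- grep("^median_", metrics$metric)
  if (length(med_rows) > 0L) {
    lines <- c(lines, "Median times (posterior-mean rates, seconds):")
    for (i in med_rows) {
      lines <- c(lines, sprintf("  %-24s %8.1f", metrics$metric[i],
                                metrics$value[i]))
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "Median times: [not fitted]", "")
  }

  outcome_path <- fit_summary_path(out_dir, "outcome")
  if (file.exists(outcome_path)) {
    oc <- utils::read.csv(outcome_path)
    lines <- c(lines, "P(insensible within 1 s):")
    lines <- c(lines, sprintf("  %-10s %.3f [%.3f, %.3f]", oc$ammo,
                              oc$mean, oc$hpdi_lo, oc$hpdi_hi), "")
  } else {
    lines <- c(lines, "P(insensible within 1 s): [not fitted]", "")
  }

  pellets_path <- fit_summary_path(out_dir, "pellets")
  if (file.exists(pellets_path)) {
    mp <- utils::read.csv(pellets_path)
    lines <- c(lines, "Proportion of fired pellets not detected:")
    lines <- c(lines, sprintf("  %-10s %.3f [%.3f, %.3f]", mp$ammo,
                              mp$mean, mp$hpdi_lo, mp$hpdi_hi), "")
  } else {
    lines <- c(lines, "Missing-pellet model: [not fitted]", "")
  }

  report_path <- file.path(out_dir, "report.txt")
  writeLines(lines, report_path)
  structure(invisible(report_path), text = paste(lines, collapse = "\n"))
}
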