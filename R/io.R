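# ---- trial CSV round trip -------------------------------------------------

#' Write / read an accelerometer trial as CSV with a JSON sidecar
#'
#' The CSV carries columns `time_s,x_g,y_g,z_g`; axis samples are printed
#' with 17 significant digits so a read round-trips bitwise. Metadata
#' (sensor label, task, subject, sampling rate) lives in a JSON sidecar next
#' to the CSV.
#'
#' @param trial an [accel_trial()].
#' @param path CSV path; the sidecar defaults to `<path>.json`.
#' @param meta_path sidecar path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(trial, path, meta_path = paste0(path, ".json")) {
  stopifnot(inherits(trial, "accel_trial"))
  n <- n_samples(trial)
  tt <- (seq_len(n) - 1L) / trial$sampling_rate
  fmt <- function(v) formatC(v, digits = 17, format = "g")
  lines <- c("time_s,x_g,y_g,z_g",
             paste(fmt(tt), fmt(trial$axes[, "x"]), fmt(trial$axes[, "y"]),
                   fmt(trial$axes[, "z"]), sep = ","))
  writeLines(lines, path)
  jsonlite::write_json(
    list(subject_id = trial$subject_id, sensor_label = trial$sensor_label,
         task_label = trial$task_label, sampling_rate = trial$sampling_rate,
         units = "g", n_samples = n),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_accel_csv
#' @details `read_accel_csv()` validates the header, rejects non-finite
#'   samples and non-uniform time stamps (naming the offending row), and
#'   converts m/s^2 to g (divide by 9.80665) when the sidecar declares
#'   `units: "m/s^2"`.
#' @export
read_accel_csv <- function(path, meta_path = paste0(path, ".json")) {
  if (!file.exists(meta_path)) stopf("metadata sidecar not found: %s", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  d <- read.csv(path, colClasses = "numeric")
  if (!identical(names(d), c("time_s", "x_g", "y_g", "z_g"))) {
    stopf("malformed header: expected time_s,x_g,y_g,z_g; got %s",
          paste(names(d), collapse = ","))
  }
  for (col in c("x_g", "y_g", "z_g")) {
    bad <- which(!is.finite(d[[col]]))
    if (length(bad)) {
      stopf("non-finite sample in column %s at row %d", col, bad[1L])
    }
  }
  fs <- meta$sampling_rate
  if (is.null(fs) || fs <= 0) stopf("sidecar lacks a positive sampling_rate")
  dt <- diff(d$time_s)
  bad <- which(abs(dt - 1 / fs) > 0.01 / fs)
  if (length(bad)) {
    stopf("non-uniform sampling near row %d (dt = %.6g s, expected %.6g s)",
          bad[1L] + 1L, dt[bad[1L]], 1 / fs)
  }
  ax <- d[, c("x_g", "y_g", "z_g")]
  if (identical(meta$units, "m/s^2")) ax <- ax / 9.80665
  accel_trial(ax[[1L]], ax[[2L]], ax[[3L]], fs,
              sensor_label = meta$sensor_label %||% "DH",
              task_label = meta$task_label %||% "dominant",
              subject_id = meta$subject_id %||% "S01")
}

#' Write a feature table to CSV
#'
#' @param features a data.frame (e.g. from [features_table()] or
#'   [simulate_accel_features()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  stopifnot(is.data.frame(features))
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

# ---- cost worked example --------------------------------------------------

#' Imaging versus pegboard cost of a hypothetical multisite trial
#'
#' Imaging cost scales with every scan (`per_scan_cost x n_subjects x
#' n_timepoints`); a pegboard device is bought once per site and reused at
#' every time point (`device_cost x n_sites`). With the default scenario -
#' 300 subjects, 3 time points, 50 sites, $2,500 per scan, $150 per device -
#' imaging costs $2,250,000 against $7,500 for pegboards.
#'
#' @param per_scan_cost USD per imaging scan.
#' @param n_subjects,n_timepoints,n_sites trial dimensions.
#' @param device_cost USD per pegboard device.
#' @return a list: `imaging_total`, `pegboard_total` (USD).
#' @export
trial_cost <- function(per_scan_cost = 2500, n_subjects = 300,
                       n_timepoints = 3, device_cost = 150, n_sites = 50) {
  args <- c(per_scan_cost, n_subjects, n_timepoints, device_cost, n_sites)
  if (anyNA(args) || any(args < 0)) stopf("all cost inputs must be >= 0")
  list(imaging_total = per_scan_cost * n_subjects * n_timepoints,
       pegboard_total = device_cost * n_sites)
}

# ---- run configuration and pipeline --------------------------------------

#' Pipeline run configuration
#'
#' Assembles (and validates) the configuration consumed by
#' [run_pipeline()]: a seed, an output directory, simulation designs,
#' signal-processing specs, and statistical options. `yaml` may point to a
#' YAML file whose top-level keys override the defaults (nested keys for
#' `filter`, `apen`, `accel`, and `stats` are merged field-wise).
#'
#' @param yaml optional YAML config path; see
#'   `system.file("extdata", "example-config.yaml", package = "pegkin")`
#'   for the schema.
#' @param seed integer seed driving every stochastic stage.
#' @param outdir output directory for report tables and the run log.
#' @param cohort a [cohort_design()].
#' @param predictors a [predictor_design()].
#' @param accel named list of [simulate_accel_features()] arguments.
#' @param filter a [filter_spec()].
#' @param apen an [apen_spec()].
#' @param stats named list: `covariates` (logical, adjust change ANOVAs),
#'   `var_equal` (pooled t instead of Welch), `fdr_method` ("BH"/"BY"),
#'   `alpha` (elimination threshold).
#' @param cost named list of [trial_cost()] arguments.
#' @return an object of class `pegkin_config`.
#' @export
pipeline_config <- function(yaml = NULL, seed = 20230605,
                            outdir = tempfile("pegkin_run_"),
                            cohort = cohort_design(),
                            predictors = predictor_design(),
                            accel = list(task = "dominant", n_pd = 8,
                                         n_hc = 8, duration = 3,
                                         sampling_rate = 200),
                            filter = filter_spec(), apen = apen_spec(),
                            stats = list(covariates = TRUE,
                                         var_equal = FALSE,
                                         fdr_method = "BH", alpha = 0.05),
                            cost = list()) {
  cfg <- list(seed = seed, outdir = outdir, cohort = cohort,
              predictors = predictors, accel = accel, filter = filter,
              apen = apen, stats = stats, cost = cost)
  if (!is.null(yaml)) {
    ov <- yaml::read_yaml(yaml)
    for (key in names(ov)) {
      if (key %in% c("filter", "apen", "accel", "stats", "cost")) {
        for (sub in names(ov[[key]])) cfg[[key]][[sub]] <- ov[[key]][[sub]]
      } else if (key %in% c("seed", "outdir")) {
        cfg[[key]] <- ov[[key]]
      } else {
        stopf("unknown config key `%s`", key)
      }
    }
    cfg$filter <- do.call(filter_spec, cfg$filter[c("low_cut", "high_cut",
                                                    "order", "zero_phase")])
    cfg$apen <- do.call(apen_spec, cfg$apen[c("m", "r", "r_absolute")])
  }
  stopifnot(inherits(cfg$cohort, "cohort_design"),
            inherits(cfg$predictors, "predictor_design"),
            inherits(cfg$filter, "filter_spec"),
            inherits(cfg$apen, "apen_spec"))
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    stopf("`seed` must be a single number")
  }
  class(cfg) <- "pegkin_config"
  cfg
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates the whole study end to end: simulate a longitudinal cohort,
#' an accelerometry sub-study, and a baseline predictor matrix; extract
#' kinematic features; compute mixed ANCOVAs per task, one-year change
#' ANOVAs with FDR-corrected post hocs, change-change Spearman
#' correlations, per-sensor group tests, and the backward-elimination
#' regression; and report the trial-cost worked example. Every table is
#' written to `outdir` as CSV, alongside a JSON provenance record (config
#' and seed) and a timestamped run log. Any stage failure aborts with the
#' stage name.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built cohort data.frame (for real data);
#'   bypasses cohort simulation. An empty table is an error.
#' @return invisibly, a list with the report tables: `cohort`, `changes`,
#'   `change_table`, `ancova` (per task), `posthoc` (per task),
#'   `correlations`, `features`, `sensor_tests`, `regression`, `cost`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pegkin_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$outdir, "run.log")
  logline <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...), "\n",
        sep = "", file = logfile, append = TRUE)
  }
  stage <- function(name, expr) {
    logline("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      logline("stage %s: FAILED (%s)", name, conditionMessage(e))
      stopf("pipeline stage `%s` failed: %s", name, conditionMessage(e))
    })
  }
  logline("run_pipeline seed=%s pegkin %s", config$seed,
          as.character(packageVersion("pegkin")))
  out <- list()

  out$cohort <- stage("simulate-cohort", {
    if (is.null(cohort)) {
      generate_cohort(config$cohort, seed = config$seed)
    } else {
      if (nrow(cohort) == 0L) stopf("cohort table is empty")
      cohort
    }
  })

  out$features <- stage("features", {
    do.call(simulate_accel_features,
            c(config$accel, list(filter = config$filter, apen = config$apen,
                                 seed = config$seed + 1L)))
  })

  st <- config$stats
  out$changes <- stage("longitudinal", one_year_change(out$cohort))
  out$change_table <- change_summary(out$changes)
  out$ancova <- stage("longitudinal-ancova", {
    lapply(setNames(TASK_LABELS, TASK_LABELS), function(task) {
      long <- rbind(
        data.frame(subject = out$cohort$subject_id, visit = "v1",
                   diagnosis = out$cohort$diagnosis,
                   age = out$cohort$age, sex = out$cohort$sex,
                   site = out$cohort$site, moca = out$cohort$moca_v1,
                   score = out$cohort[[paste0("ppt_", task, "_v1")]]),
        data.frame(subject = out$cohort$subject_id, visit = "v2",
                   diagnosis = out$cohort$diagnosis,
                   age = out$cohort$age, sex = out$cohort$sex,
                   site = out$cohort$site, moca = out$cohort$moca_v1,
                   score = out$cohort[[paste0("ppt_", task, "_v2")]]))
      mixed_ancova(long, dv = "score", subject = "subject",
                   within = "visit", between = "diagnosis",
                   covariates = if (isTRUE(st$covariates))
                     c("age", "site", "moca", "sex") else character())
    })
  })
  out$posthoc <- stage("posthoc", {
    lapply(setNames(TASK_LABELS, TASK_LABELS), function(task) {
      posthoc_group_changes(out$changes, task, var_equal = st$var_equal,
                            fdr_method = st$fdr_method)
    })
  })
  out$correlations <- stage("correlations", {
    do.call(rbind, lapply(TASK_LABELS, function(task) {
      d <- out$changes[out$changes$task == task &
                         out$changes$diagnosis != "HC", ]
      ct <- correlate_changes(d$updrs_change, d$change, "spearman")
      data.frame(task = task, rho = ct$estimate, p = ct$p, n = ct$n)
    }))
  })
  out$sensor_tests <- stage("sensors", {
    task <- config$accel$task %||% "dominant"
    list(sd_accel = sensor_group_tests(out$features, "sd_accel", task,
                                       var_equal = st$var_equal,
                                       fdr_method = st$fdr_method),
         apen = sensor_group_tests(out$features, "apen", task,
                                   var_equal = st$var_equal,
                                   fdr_method = st$fdr_method))
  })
  out$regression <- stage("regress", {
    sim <- generate_predictors(config$predictors, seed = config$seed + 2L)
    backward_eliminate(sim$x, sim$y, alpha = st$alpha %||% 0.05)
  })
  out$cost <- stage("cost", do.call(trial_cost, config$cost))

  stage("report", {
    wr <- function(d, f) write.csv(d, file.path(config$outdir, f),
                                   row.names = FALSE)
    wr(out$change_table, "change_table.csv")
    wr(out$features, "features.csv")
    wr(do.call(rbind, lapply(names(out$ancova), function(t) {
      cbind(task = t, out$ancova[[t]]$table)
    })), "ancova.csv")
    wr(do.call(rbind, lapply(names(out$posthoc), function(t) {
      cbind(task = t, as.data.frame(out$posthoc[[t]]))
    })), "posthoc.csv")
    wr(out$correlations, "correlations.csv")
    wr(cbind(feature = "sd_accel", as.data.frame(out$sensor_tests$sd_accel)),
       "sensor_tests_sd.csv")
    wr(cbind(feature = "apen", as.data.frame(out$sensor_tests$apen)),
       "sensor_tests_apen.csv")
    reg <- out$regression
    if (!is.null(reg$model)) {
      wr(data.frame(term = names(reg$model$beta), beta = reg$model$beta,
                    t = reg$model$t, p = reg$model$p), "regression.csv")
    }
    wr(data.frame(imaging_total = out$cost$imaging_total,
                  pegboard_total = out$cost$pegboard_total), "cost.csv")
    jsonlite::write_json(
      list(seed = config$seed,
           package_version = as.character(packageVersion("pegkin")),
           stats = config$stats, accel = config$accel,
           filter = unclass(config$filter), apen = unclass(config$apen)),
      file.path(config$outdir, "provenance.json"), auto_unbox = TRUE)
    NULL
  })
  logline("run complete")
  invisible(out)
}
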