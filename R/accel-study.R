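#' Reference SD-of-acceleration targets for the accelerometry study
#'
#' Package defaults for the group-level magnitude of the SD-of-acceleration
#' feature (mean and between-subject SD, in g) for each task x sensor x
#' diagnosis cell, set to published magnitudes for pegboard accelerometry in
#' PD and controls: the PD/HC ratio is about 0.6 on sensors engaged by the
#' task. The simulator draws each subject's movement amplitude from these
#' cells.
#'
#' @return a data.frame: `task`, `sensor`, `group` (PD/HC), `mean`, `sd`.
#' @export
accel_sd_reference <- function() {
  grid <- expand.grid(sensor = SENSOR_LABELS, task = TASK_LABELS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pd_mean <- c(0.013, 0.013, 0.092, 0.060, 0.014,   # dominant
               0.100, 0.067, 0.016, 0.015, 0.015,   # nondominant
               0.076, 0.052, 0.071, 0.048, 0.014,   # both
               0.058, 0.043, 0.056, 0.040, 0.012)   # assembly
  pd_sd <- c(0.010, 0.005, 0.028, 0.016, 0.006,
             0.033, 0.023, 0.019, 0.012, 0.006,
             0.026, 0.018, 0.023, 0.019, 0.007,
             0.019, 0.013, 0.016, 0.011, 0.003)
  hc_mean <- c(0.023, 0.020, 0.146, 0.098, 0.023,
               0.149, 0.096, 0.021, 0.019, 0.020,
               0.121, 0.080, 0.121, 0.080, 0.021,
               0.096, 0.064, 0.089, 0.061, 0.017)
  hc_sd <- c(0.019, 0.014, 0.029, 0.028, 0.006,
             0.032, 0.025, 0.017, 0.010, 0.006,
             0.027, 0.021, 0.016, 0.016, 0.005,
             0.031, 0.023, 0.023, 0.018, 0.004)
  rbind(
    data.frame(grid, group = "PD", mean = pd_mean, sd = pd_sd),
    data.frame(grid, group = "HC", mean = hc_mean, sd = hc_sd))
}

#' Sensors engaged by a pegboard task
#'
#' The sensors on which the simulator plants the PD irregularity contrast:
#' the moving hand(s), their brachioradialis sensors, and the head sensor.
#'
#' @param task one of the four task labels.
#' @return a character vector of sensor labels.
#' @export
task_relevant_sensors <- function(task) {
  task <- match.arg(task, TASK_LABELS)
  switch(task,
         dominant = c("DH", "DB", "HD"),
         nondominant = c("NDH", "NDB", "HD"),
         both = SENSOR_LABELS,
         assembly = SENSOR_LABELS)
}

#' Simulate an accelerometry study and extract its features
#'
#' Generates a two-group (PD vs HC) pegboard accelerometry study for one
#' task: per subject and sensor, a triaxial trial is drawn from an
#' [accel_profile()] whose amplitude reproduces the [accel_sd_reference()]
#' cell for that group (amplitude = target SD x sqrt(2)) and whose
#' irregularity is raised in the PD group on the [task_relevant_sensors()];
#' the full conditioning + feature pipeline is then run on every trial.
#' This is the planted-effect surface on which group comparisons
#' ([sensor_group_tests()]) are validated: PD profiles have lower SD of
#' acceleration and higher approximate entropy on task-relevant sensors.
#'
#' @param task pegboard task to simulate.
#' @param n_pd,n_hc subjects per group.
#' @param duration,sampling_rate trial length (s) and rate (Hz) used for the
#'   simulated recordings.
#' @param movement_rate fundamental of the peg-transport motion, cycles/s.
#' @param irregularity_pd,irregularity_hc group-level irregularity on
#'   task-relevant sensors (HC value is also used for PD on non-relevant
#'   sensors).
#' @param irregularity_sd between-subject SD of irregularity.
#' @param spike_rate,spike_magnitude artifact settings for the generated
#'   trials.
#' @param filter,apen,decimate_to pipeline settings passed to
#'   [extract_sensor_features()].
#' @param seed integer seed or `NULL`.
#' @return a data.frame of per subject x sensor features: `subject`,
#'   `diagnosis`, `sensor`, `task`, `sd_accel`, `apen`.
#' @export
simulate_accel_features <- function(task = "dominant", n_pd = 20, n_hc = 19,
                                    duration = 4, sampling_rate = 200,
                                    movement_rate = 1.5,
                                    irregularity_pd = 0.40,
                                    irregularity_hc = 0.10,
                                    irregularity_sd = 0.06,
                                    spike_rate = 0.25, spike_magnitude = 8,
                                    filter = filter_spec(),
                                    apen = apen_spec(), decimate_to = 200,
                                    seed = NULL) {
  task <- match.arg(task, TASK_LABELS)
  ref <- accel_sd_reference()
  ref <- ref[ref$task == task, ]
  relevant <- task_relevant_sensors(task)
  with_seed(seed, {
    rows <- list()
    subj <- data.frame(
      id = sprintf("A%03d", seq_len(n_pd + n_hc)),
      group = rep(c("PD", "HC"), c(n_pd, n_hc)), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(subj))) {
      for (s in SENSOR_LABELS) {
        cell <- ref[ref$sensor == s & ref$group == subj$group[i], ]
        target_sd <- max(rnorm(1, cell$mean, cell$sd), 0.1 * cell$mean)
        irr_base <- if (subj$group[i] == "PD" && s %in% relevant) {
          irregularity_pd
        } else {
          irregularity_hc
        }
        irr <- clamp(rnorm(1, irr_base, irregularity_sd), 0.02, 0.9)
        prof <- accel_profile(
          movement_rate = movement_rate, amplitude = target_sd * sqrt(2),
          irregularity = irr, spike_rate = spike_rate,
          spike_magnitude = spike_magnitude, duration = duration,
          sampling_rate = sampling_rate)
        tr <- generate_accel_trial(prof, seed = NULL,
                                   subject_id = subj$id[i],
                                   sensor_label = s, task_label = task)
        f <- extract_sensor_features(tr, filter = filter, apen = apen,
                                     decimate_to = decimate_to)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj$id[i], diagnosis = subj$group[i], sensor = s,
          task = task, sd_accel = f$sd_accel, apen = f$apen,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
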