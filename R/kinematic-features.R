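#' Approximate entropy specification
#'
#' Parameters of the classical approximate entropy statistic, ApEn(m, r, N).
#' Defaults follow the de facto standard for physiological series: embedding
#' length m = 2 and tolerance r = 0.2 x series SD.
#'
#' @param m embedding (template) length in samples, >= 1.
#' @param r match tolerance; a fraction of the series SD when
#'   `r_absolute = FALSE` (default), otherwise an absolute tolerance in
#'   signal units. Must satisfy `0 < r <= 1` in relative mode.
#' @param r_absolute interpret `r` as an absolute tolerance.
#' @return an object of class `apen_spec`.
#' @export
apen_spec <- function(m = 2, r = 0.2, r_absolute = FALSE) {
  if (m < 1) stopf("`m` must be >= 1")
  if (r <= 0) stopf("`r` must be > 0")
  if (!r_absolute && r > 1) stopf("relative `r` must be <= 1")
  structure(list(m = as.integer(m), r = r, r_absolute = isTRUE(r_absolute)),
            class = "apen_spec")
}

#' Standard deviation of acceleration
#'
#' Sample standard deviation (denominator N - 1) of a filtered acceleration
#' axis: a proxy for movement vigor / range during the pegboard task.
#'
#' @param series numeric series of length >= 2, no missing values.
#' @return the sample SD, in g.
#' @export
acceleration_sd <- function(series) {
  if (length(series) < 2L) stopf("need at least 2 samples")
  if (anyNA(series) || !all(is.finite(series))) stopf("series must be finite")
  stats::sd(series)
}

#' Approximate entropy of a series
#'
#' Classical (Pincus) approximate entropy: ApEn(m, r, N) = Phi_m(r) -
#' Phi_(m+1)(r), where Phi_m(r) is the mean over templates i of the natural
#' log of the fraction of length-m templates within Chebyshev distance r of
#' template i, self-matches included. Low for regular/periodic signals, high
#' for unpredictable ones. A zero-variance series returns 0 (all templates
#' match) with a note.
#'
#' @param series numeric series with more than `m + 1` samples.
#' @param spec an [apen_spec()]; relative `r` is resolved to
#'   `r * sd(series)`.
#' @return a non-negative scalar.
#' @export
approximate_entropy <- function(series, spec = apen_spec()) {
  stopifnot(inherits(spec, "apen_spec"))
  if (anyNA(series) || !all(is.finite(series))) stopf("series must be finite")
  if (length(series) <= spec$m + 1L) {
    stopf("series length (%d) must exceed m + 1 (%d)", length(series),
          spec$m + 1L)
  }
  r_abs <- if (spec$r_absolute) spec$r else spec$r * stats::sd(series)
  if (r_abs == 0) {
    message("zero-variance series: all templates match, ApEn = 0")
    return(0)
  }
  apen_kernel(as.numeric(series), spec$m, r_abs)
}

#' Average per-axis feature values into one sensor-level value
#'
#' Arithmetic mean of the three per-axis feature values (x, y, z), producing
#' a single measure per sensor per task.
#'
#' @param per_axis numeric vector of three finite values.
#' @return their arithmetic mean.
#' @export
aggregate_axes <- function(per_axis) {
  if (length(per_axis) != 3L || anyNA(per_axis) || !all(is.finite(per_axis))) {
    stopf("`per_axis` must be three finite values")
  }
  mean(per_axis)
}

#' Extract sensor-level kinematic features from a raw trial
#'
#' Runs the fixed conditioning pipeline - spike removal, zero-phase band-pass
#' filtering, decimation - then computes SD of acceleration and approximate
#' entropy per axis and averages across the x, y, z axes to one value per
#' feature per sensor. The full processing provenance (filter spec,
#' decimation factor, ApEn parameters, despiking settings) is retained.
#'
#' @param trial a raw [accel_trial()].
#' @param filter a [filter_spec()].
#' @param apen an [apen_spec()].
#' @param despike_window,despike_threshold Hampel settings passed to
#'   [remove_spikes()].
#' @param decimate_to target rate (Hz) for [decimate_trial()]; capped at the
#'   trial's sampling rate (a trial already at or below the target is left
#'   undecimated).
#' @return an object of class `sensor_features`: sensor/task/subject labels,
#'   axis-averaged `sd_accel` and `apen`, the per-axis values, and
#'   `provenance`.
#' @export
extract_sensor_features <- function(trial, filter = filter_spec(),
                                    apen = apen_spec(),
                                    despike_window = 11,
                                    despike_threshold = 5,
                                    decimate_to = 200) {
  stopifnot(inherits(trial, "accel_trial"))
  tr <- remove_spikes(trial, window = despike_window,
                      threshold = despike_threshold)
  tr <- bandpass_filter(tr, filter)
  target <- min(decimate_to, tr$sampling_rate)
  tr <- decimate_trial(tr, target_rate = target)
  per_axis <- data.frame(axis = colnames(tr$axes),
                         sd_accel = NA_real_, apen = NA_real_)
  for (i in seq_len(3L)) {
    x <- tr$axes[, i]
    per_axis$sd_accel[i] <- acceleration_sd(x)
    per_axis$apen[i] <- if (stats::sd(x) == 0) 0 else approximate_entropy(x, apen)
  }
  structure(
    list(sensor_label = tr$sensor_label, task_label = tr$task_label,
         subject_id = tr$subject_id,
         sd_accel = aggregate_axes(per_axis$sd_accel),
         apen = aggregate_axes(per_axis$apen),
         per_axis = per_axis,
         provenance = c(tr$provenance, list(apen_spec = unclass(apen)))),
    class = "sensor_features")
}

#' @export
print.sensor_features <- function(x, ...) {
  cat(sprintf(
    "<sensor_features> subject %s, sensor %s, task %s\n  sd_accel = %.5g g, apen = %.5g\n",
    x$subject_id, x$sensor_label, x$task_label, x$sd_accel, x$apen))
  invisible(x)
}

#' Bind sensor features into a table
#'
#' @param features a list of `sensor_features` objects.
#' @return a data.frame with one row per object (subject, sensor, task,
#'   sd_accel, apen).
#' @export
features_table <- function(features) {
  stopifnot(all(vapply(features, inherits, TRUE, "sensor_features")))
  do.call(rbind, lapply(features, function(f) {
    data.frame(subject = f$subject_id, sensor = f$sensor_label,
               task = f$task_label, sd_accel = f$sd_accel, apen = f$apen,
               stringsAsFactors = FALSE)
  }))
}
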