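#' Triaxial accelerometer trial
#'
#' Container for one sensor's triaxial acceleration record during one
#' pegboard task: three equal-length axis series (x, y, z, in g), the
#' sampling rate, and identifying metadata. All processing steps
#' ([remove_spikes()], [bandpass_filter()], [decimate_trial()]) accept and
#' return this class and append to its `provenance` list.
#'
#' @param x,y,z numeric axis series in g; equal length, at least 2 samples,
#'   no missing values.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param sensor_label sensor placement, one of `"NDH"`, `"NDB"`, `"DH"`,
#'   `"DB"`, `"HD"` (non-dominant hand / brachioradialis, dominant hand /
#'   brachioradialis, head).
#' @param task_label pegboard task, one of `"dominant"`, `"nondominant"`,
#'   `"both"`, `"assembly"`.
#' @param subject_id opaque subject identifier.
#' @param provenance list of processing records (internal use).
#' @return an object of class `accel_trial` with elements `axes` (n x 3
#'   matrix, columns x/y/z), `sampling_rate`, `sensor_label`, `task_label`,
#'   `subject_id`, `provenance`.
#' @examples
#' tr <- accel_trial(rnorm(100), rnorm(100), rnorm(100), sampling_rate = 100)
#' n_samples(tr)
#' @export
accel_trial <- function(x, y, z, sampling_rate,
                        sensor_label = "DH", task_label = "dominant",
                        subject_id = "S01", provenance = list()) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stopf("`sampling_rate` must be a single positive number")
  }
  n <- length(x)
  if (n < 2L || length(y) != n || length(z) != n) {
    stopf("axis series must have equal length >= 2 (got %d, %d, %d)",
          length(x), length(y), length(z))
  }
  axes <- cbind(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (anyNA(axes) || !all(is.finite(axes))) {
    bad <- which(!is.finite(axes), arr.ind = TRUE)[1L, ]
    stopf("non-finite sample at row %d, axis %s", bad[1L],
          colnames(axes)[bad[2L]])
  }
  sensor_label <- match.arg(sensor_label, SENSOR_LABELS)
  task_label <- match.arg(task_label, TASK_LABELS)
  structure(
    list(axes = axes, sampling_rate = sampling_rate,
         sensor_label = sensor_label, task_label = task_label,
         subject_id = as.character(subject_id), provenance = provenance),
    class = "accel_trial")
}

#' @rdname accel_trial
#' @param trial an `accel_trial` object.
#' @export
n_samples <- function(trial) {
  stopifnot(inherits(trial, "accel_trial"))
  nrow(trial$axes)
}

#' @rdname accel_trial
#' @export
trial_duration <- function(trial) {
  n_samples(trial) / trial$sampling_rate
}

#' @export
print.accel_trial <- function(x, ...) {
  cat(sprintf(
    "<accel_trial> subject %s, sensor %s, task %s\n  %d samples @ %g Hz (%.3g s)\n",
    x$subject_id, x$sensor_label, x$task_label,
    n_samples(x), x$sampling_rate, trial_duration(x)))
  if (length(x$provenance)) {
    cat("  processing:", paste(names(x$provenance), collapse = " -> "), "\n")
  }
  invisible(x)
}

# replace axis data, preserving metadata and appending a provenance record
update_axes <- function(trial, axes, step = NULL, record = NULL,
                        sampling_rate = trial$sampling_rate) {
  trial$axes <- axes
  trial$sampling_rate <- sampling_rate
  if (!is.null(step)) trial$provenance[[step]] <- record
  trial
}
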