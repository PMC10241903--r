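#' Band-pass filter specification
#'
#' Butterworth band-pass used to condition pegboard accelerometry: 1-50 Hz,
#' 4th order, applied forward and backward (dual pass), which squares the
#' magnitude response and cancels phase delay.
#'
#' @param low_cut,high_cut corner frequencies, Hz (`0 < low_cut < high_cut`).
#' @param order filter order (>= 1).
#' @param zero_phase apply dual-pass (zero-phase) filtering; single forward
#'   pass if `FALSE`.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 1, high_cut = 50, order = 4,
                        zero_phase = TRUE) {
  if (low_cut <= 0 || high_cut <= low_cut) {
    stopf("need 0 < low_cut < high_cut (got %g, %g)", low_cut, high_cut)
  }
  if (order < 1) stopf("`order` must be >= 1")
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Remove spike artifacts with a Hampel running-median filter
#'
#' Per axis, samples deviating from the centered running median by more than
#' `threshold * 1.4826 * MAD` (MAD computed in the same window) are replaced
#' by that median; all other samples are untouched. Edge samples without a
#' full window are left unchanged. The replaced indices are recorded in
#' `$provenance$despike$indices` (one integer vector per axis).
#'
#' @param trial an [accel_trial()].
#' @param window full window length in samples; odd, >= 3, shorter than the
#'   series.
#' @param threshold MAD-multiple flagging threshold (> 0).
#' @return a new `accel_trial` with spikes replaced.
#' @export
remove_spikes <- function(trial, window = 11, threshold = 5) {
  stopifnot(inherits(trial, "accel_trial"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stopf("`window` must be an odd integer >= 3")
  }
  if (threshold <= 0) stopf("`threshold` must be > 0")
  n <- n_samples(trial)
  if (window >= n) stopf("`window` (%d) must be shorter than the series (%d)",
                         window, n)
  halfwin <- window %/% 2L
  axes <- trial$axes
  idx <- list()
  for (a in colnames(axes)) {
    # iterate to a fixed point: replacing a spike can unmask a neighbour
    # that the spike's inflated MAD had shielded, so one sweep is not
    # idempotent; convergence is fast (spikes are isolated)
    y <- axes[, a]
    flagged <- integer(0)
    for (pass in 1:20) {
      res <- hampel_kernel(y, halfwin, threshold)
      if (!length(res$ind)) break
      y <- res$y
      flagged <- union(flagged, as.integer(res$ind))
    }
    axes[, a] <- y
    idx[[a]] <- sort(flagged)
  }
  update_axes(trial, axes, step = "despike",
              record = list(window = window, threshold = threshold,
                            indices = idx,
                            n_replaced = sum(lengths(idx))))
}

# zero-phase IIR application with odd (reflective) end padding; pad samples
# are trimmed after the backward pass
filtfilt_reflect <- function(bf, x, pad) {
  n <- length(x)
  pad <- max(1L, min(as.integer(pad), n - 1L))
  xe <- c(2 * x[1L] - x[(pad + 1L):2L], x,
          2 * x[n] - x[(n - 1L):(n - pad)])
  y <- as.numeric(signal::filter(bf, xe))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(pad + 1L):(pad + n)]
}

#' Band-pass filter an accelerometer trial
#'
#' Applies the Butterworth band-pass of `spec` to each axis. With
#' `zero_phase = TRUE` (default) the filter runs forward and backward, giving
#' a squared magnitude response and zero net phase; edge transients are
#' suppressed by odd-reflection padding of length `10 * fs / low_cut`
#' (capped at the series length), long enough for the 1 Hz corner's settling
#' transient to decay below 1e-6.
#'
#' @param trial an [accel_trial()].
#' @param spec a [filter_spec()]; `high_cut` must lie below the Nyquist
#'   frequency of the trial.
#' @return the filtered `accel_trial` (same length as the input).
#' @export
bandpass_filter <- function(trial, spec = filter_spec()) {
  stopifnot(inherits(trial, "accel_trial"), inherits(spec, "filter_spec"))
  fs <- trial$sampling_rate
  if (spec$high_cut >= fs / 2) {
    stopf("high_cut (%g Hz) must be below the Nyquist frequency (%g Hz)",
          spec$high_cut, fs / 2)
  }
  bf <- signal::butter(spec$order, c(spec$low_cut, spec$high_cut) / (fs / 2),
                       type = "pass")
  pad <- as.integer(ceiling(10 * fs / spec$low_cut))
  axes <- trial$axes
  for (a in colnames(axes)) {
    if (spec$zero_phase) {
      axes[, a] <- filtfilt_reflect(bf, axes[, a], pad)
    } else {
      n <- length(axes[, a])
      x <- axes[, a]
      padc <- max(1L, min(pad, n - 1L))
      xe <- c(2 * x[1L] - x[(padc + 1L):2L], x)
      axes[, a] <- as.numeric(signal::filter(bf, xe))[(padc + 1L):(padc + n)]
    }
  }
  update_axes(trial, axes, step = "filter", record = unclass(spec))
}

#' Power spectrum of a trial
#'
#' One-sided magnitude-squared discrete Fourier spectrum of each (demeaned)
#' axis, normalized by the record length; a diagnostic output, no downstream
#' feature depends on it. Interior bins are doubled so that `sum(power)`
#' equals `N * mean((x - mean(x))^2)` (Parseval identity on the demeaned
#' series).
#'
#' @param trial an [accel_trial()].
#' @return a data.frame with columns `frequency` (Hz, 0..Nyquist) and
#'   `power_x`, `power_y`, `power_z`.
#' @export
power_spectrum <- function(trial) {
  stopifnot(inherits(trial, "accel_trial"))
  n <- n_samples(trial)
  fs <- trial$sampling_rate
  nkeep <- floor(n / 2) + 1L
  out <- data.frame(frequency = (seq_len(nkeep) - 1L) * fs / n)
  for (a in colnames(trial$axes)) {
    x <- trial$axes[, a]
    p <- Mod(fft(x - mean(x)))^2 / n
    ps <- p[seq_len(nkeep)]
    dbl <- 2:(nkeep - 1L)
    if (n %% 2L == 1L) dbl <- 2:nkeep  # odd n: no unpaired Nyquist bin
    ps[dbl] <- 2 * ps[dbl]
    out[[paste0("power_", a)]] <- ps
  }
  out
}

#' Decimate a filtered trial by an integer factor
#'
#' Integer-factor downsampling applied after band-pass filtering, to make the
#' O(N^2) entropy computation tractable. The passband must end below the new
#' Nyquist frequency (`target_rate >= 2 * high_cut` of the applied filter),
#' so no additional anti-alias filter is needed.
#'
#' @param trial a band-passed [accel_trial()].
#' @param target_rate new sampling rate, Hz; `sampling_rate / target_rate`
#'   must be a positive integer.
#' @return the decimated `accel_trial`; the decimation factor is recorded in
#'   provenance.
#' @export
decimate_trial <- function(trial, target_rate = 200) {
  stopifnot(inherits(trial, "accel_trial"))
  fs <- trial$sampling_rate
  fac <- fs / target_rate
  if (abs(fac - round(fac)) > 1e-9 || fac < 1) {
    stopf("sampling_rate / target_rate must be a positive integer (got %g)", fac)
  }
  filt <- trial$provenance$filter
  if (!is.null(filt) && target_rate < 2 * filt$high_cut) {
    stopf("target_rate (%g Hz) must be >= twice the filter high_cut (%g Hz)",
          target_rate, filt$high_cut)
  }
  fac <- as.integer(round(fac))
  if (fac == 1L) {
    return(update_axes(trial, trial$axes, step = "decimate",
                       record = list(factor = 1L, target_rate = fs)))
  }
  idx <- seq.int(1L, n_samples(trial), by = fac)
  update_axes(trial, trial$axes[idx, , drop = FALSE],
              step = "decimate",
              record = list(factor = fac, target_rate = target_rate),
              sampling_rate = target_rate)
}
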