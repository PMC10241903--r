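test_that("despiking leaves a clean constant series untouched", {
  tr <- make_trial(rep(1, 100), fs = 100)
  out <- remove_spikes(tr)
  expect_identical(out$axes, tr$axes)
  expect_equal(out$provenance$despike$n_replaced, 0)
})

test_that("a single outlier in a flat series is replaced by the median", {
  x <- rep(0, 200)
  x[57] <- 10
  out <- remove_spikes(make_trial(x, fs = 100))
  expect_equal(as.numeric(out$axes[57, "x"]), 0)
  expect_identical(out$provenance$despike$indices$x, 57L)
})

test_that("despiking recovers planted spikes with few false alarms", {
  prof <- accel_profile(amplitude = 0.1, irregularity = 0.2,
                        spike_rate = 0.4, spike_magnitude = 10,
                        duration = 30, sampling_rate = 2000)
  tr <- generate_accel_trial(prof, seed = 101)
  out <- remove_spikes(tr, window = 11, threshold = 5)
  for (a in c("x", "y", "z")) {
    truth <- tr$spike_indices[[a]]
    flagged <- out$provenance$despike$indices[[a]]
    expect_gte(length(intersect(flagged, truth)), 11L)  # >= 11 of 12
    false_alarms <- setdiff(flagged, truth)
    expect_lte(length(false_alarms), 0.001 * (n_samples(tr) - 12L))
  }
})

test_that("despiking is idempotent on its own output", {
  prof <- accel_profile(amplitude = 0.1, irregularity = 0.3,
                        spike_rate = 0.3, spike_magnitude = 8,
                        duration = 10, sampling_rate = 200)
  tr <- generate_accel_trial(prof, seed = 77)
  once <- remove_spikes(tr)
  twice <- remove_spikes(once)
  expect_identical(twice$axes, once$axes)
})

test_that("despiking matches an established Hampel implementation", {
  set.seed(5)
  x <- sin(seq(0, 40, length.out = 3000)) + rnorm(3000, 0, 0.1)
  x[c(150, 900, 2222)] <- x[c(150, 900, 2222)] + 6
  ours <- remove_spikes(make_trial(x, fs = 100), window = 11, threshold = 3)
  # reference: pracma's Hampel swept to the same fixed point
  ref_y <- x
  ref_ind <- integer(0)
  repeat {
    ref <- pracma::hampel(ref_y, k = 5, t0 = 3)
    if (!length(ref$ind)) break
    ref_y <- ref$y
    ref_ind <- union(ref_ind, as.integer(ref$ind))
  }
  expect_equal(unname(ours$axes[, "x"]), ref_y)
  expect_identical(ours$provenance$despike$indices$x, sort(ref_ind))
})

test_that("despiking rejects invalid windows", {
  tr <- make_trial(rnorm(50), fs = 100)
  expect_error(remove_spikes(tr, window = 4), "odd")
  expect_error(remove_spikes(tr, window = 51), "shorter than the series")
})

test_that("the band-pass suppresses DC below 1e-6 of input level", {
  tr <- make_trial(rep(1, 60000), fs = 2000)
  out <- bandpass_filter(tr)
  expect_lt(max(abs(out$axes)), 1e-6)
})

test_that("dual-pass passband gain and stopband rejection match theory", {
  fs <- 2000
  tr <- make_trial(sine_series(10, fs, 30), fs)
  out <- bandpass_filter(tr)
  mid <- out$axes[20000:40000, "x"]
  expect_equal((max(mid) - min(mid)) / 2, 1.0, tolerance = 0.01)
  tr2 <- make_trial(sine_series(200, fs, 30), fs)
  out2 <- bandpass_filter(tr2)
  expect_lt(max(abs(out2$axes[20000:40000, "x"])), 1e-4)
})

test_that("dual-pass filtering introduces zero phase lag", {
  fs <- 1000
  x <- sine_series(10, fs, 10)
  out <- bandpass_filter(make_trial(x, fs))
  cc <- ccf(out$axes[, "x"], x, lag.max = 25, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filtering is linear", {
  fs <- 200
  set.seed(8)
  x <- rnorm(5000); y <- rnorm(5000)
  fx <- bandpass_filter(make_trial(x, fs))$axes[, "x"]
  fy <- bandpass_filter(make_trial(y, fs))$axes[, "x"]
  fmix <- bandpass_filter(make_trial(2 * x - 3 * y, fs))$axes[, "x"]
  expect_equal(fmix, 2 * fx - 3 * fy, tolerance = 1e-9)
})

test_that("filter specs are validated against the trial", {
  tr <- make_trial(rnorm(100), fs = 80)
  expect_error(bandpass_filter(tr), "Nyquist")
  expect_error(filter_spec(low_cut = 0), "low_cut")
  expect_error(filter_spec(low_cut = 60, high_cut = 50), "low_cut")
})

test_that("the power spectrum localizes a sinusoid and satisfies Parseval", {
  fs <- 500
  tr <- make_trial(sine_series(10, fs, 8), fs)
  ps <- power_spectrum(tr)
  peak <- ps$frequency[which.max(ps$power_x)]
  expect_lt(abs(peak - 10), fs / n_samples(tr) + 1e-9)
  x <- tr$axes[, "x"]
  pop_var <- mean((x - mean(x))^2)
  expect_equal(sum(ps$power_x), n_samples(tr) * pop_var,
               tolerance = 1e-6)
})

test_that("white noise has a flat spectrum across 2-40 Hz", {
  set.seed(13)
  tr <- make_trial(rnorm(20000), fs = 200)
  ps <- power_spectrum(tr)
  band <- ps[ps$frequency >= 2 & ps$frequency <= 40, ]
  fit <- summary(lm(power_x ~ frequency, data = band))
  expect_lt(abs(fit$coefficients["frequency", "t value"]), 3)
})

test_that("decimation preserves band-limited signal SD", {
  fs <- 2000
  tr <- bandpass_filter(make_trial(sine_series(10, fs, 10), fs))
  dec <- decimate_trial(tr, 200)
  expect_equal(dec$sampling_rate, 200)
  expect_equal(sd(dec$axes[, "x"]), sd(tr$axes[, "x"]), tolerance = 0.005)
  expect_equal(dec$provenance$decimate$factor, 10L)
})

test_that("decimating filtered broadband noise preserves SD within 2%", {
  set.seed(17)
  tr <- bandpass_filter(make_trial(rnorm(40000), fs = 2000))
  dec <- decimate_trial(tr, 200)
  expect_equal(sd(dec$axes[, "x"]), sd(tr$axes[, "x"]), tolerance = 0.02)
})

test_that("decimation validates its factor and factor 1 is the identity", {
  tr <- make_trial(rnorm(1000), fs = 200)
  expect_error(decimate_trial(tr, 150), "integer")
  same <- decimate_trial(tr, 200)
  expect_identical(same$axes, tr$axes)
  filt <- bandpass_filter(make_trial(rnorm(1000), fs = 300),
                          filter_spec(high_cut = 50))
  expect_error(decimate_trial(filt, 75), "high_cut")
})
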