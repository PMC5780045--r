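# Wavelet bank, transform identities, normalization, band averaging, phase.

test_that("default wavelet bank matches the closed form", {
  bank <- build_wavelet_bank()
  expect_length(bank$frequencies, 47)
  expect_equal(bank$frequencies[1], 2)
  expect_equal(bank$frequencies[9] / bank$frequencies[1], 2) # one octave
  expect_equal(bank$frequencies[47], 2 * 2^(46 / 8), tolerance = 1e-12)
  expect_equal(bank$frequencies[47], 107.63, tolerance = 1e-4)
  rat <- bank$frequencies[-1] / bank$frequencies[-47]
  expect_true(all(abs(rat - 2^(1 / 8)) < 1e-12))
})

test_that("unit sinusoid at a grid frequency has unit flat power", {
  fs <- 500
  bank <- build_wavelet_bank(5, 8, 25) # 5 .. 40 Hz, includes 20? 5*2^(3)=40
  rec <- sine_recording(20, fs, dur_s = 20)
  ev <- data.frame(onset = c(5000, 9000, 13000), block = 1, trial_in_block = 1:3,
                   condition = factor("target", levels = c("target", "distractor")),
                   correct = TRUE)
  tf <- epoch_tf(wavelet_transform_recording(rec, bank, 1), ev,
                 crop = c(-250, 1250))
  pow <- Mod(tf$values)^2
  k <- which.min(abs(bank$frequencies - 20))
  # 20 Hz is not exactly on this grid; use the response at the nearest bin
  expect_equal(bank$frequencies[which.max(apply(pow, 2, mean))],
               bank$frequencies[k])
  # exact grid frequency: amplitude 1 within 2%, flat over time
  bank20 <- build_wavelet_bank(20, 8, 1)
  tf20 <- epoch_tf(wavelet_transform_recording(rec, bank20, 1), ev,
                   crop = c(-250, 1250))
  a <- Mod(tf20$values[1, 1, ])
  expect_lt(max(abs(a - 1)), 0.02)
  expect_lt((max(a) - min(a)) / mean(a), 0.02)
})

test_that("two sinusoids resolve with < 1% cross-leak", {
  fs <- 500
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  rec <- recording(matrix(cos(2 * pi * 5 * t) + cos(2 * pi * 40 * t), 1), fs,
                   data.frame(name = "a", role = "stn-macro", group = "stn"))
  bank <- build_wavelet_bank(5, 8, 25) # grid holds exactly 5 and 40 Hz
  ev <- data.frame(onset = 6000, block = 1, trial_in_block = 1,
                   condition = factor("target", levels = c("target", "distractor")),
                   correct = TRUE)
  tf <- epoch_tf(wavelet_transform_recording(rec, bank, 1), ev,
                 crop = c(0, 1000))
  pow <- apply(Mod(tf$values)^2, 2, mean)
  k5 <- which(abs(bank$frequencies - 5) < 1e-9)
  k40 <- which(abs(bank$frequencies - 40) < 1e-9)
  kmid <- which.min(abs(bank$frequencies - 14))
  expect_lt(abs(pow[k5] - 1), 0.02)
  expect_lt(abs(pow[k40] - 1), 0.02)
  expect_lt(pow[kmid], 0.01)
})

test_that("power and normalization arithmetic", {
  # crafted power tensors: trials x freqs x time
  p <- array(1, c(2, 3, 100))
  times <- seq(-500, 490, by = 10)
  ptf <- tf_tensor(p, c(5, 10, 20), times, "power")
  np <- normalize_to_baseline(ptf)
  expect_true(all(abs(np$values) < 1e-12))
  p2 <- p
  p2[, , times >= 0] <- 2
  np2 <- normalize_to_baseline(tf_tensor(p2, c(5, 10, 20), times, "power"))
  expect_true(all(abs(np2$values[, , times >= 0] - 100) < 1e-9))
  # zero baseline is degenerate
  p3 <- p; p3[1, 1, times < 0] <- 0
  expect_error(normalize_to_baseline(tf_tensor(p3, c(5, 10, 20), times, "power")),
               "zero baseline")
  # |W|^2 equals the squared magnitude path
  z <- array(complex(real = rnorm(60), imaginary = rnorm(60)), c(2, 3, 10))
  ctf <- tf_tensor(z, c(5, 10, 20), 1:10, "complex")
  expect_equal(tf_power(ctf)$values, Mod(z)^2)
})

test_that("normalization is invariant to signal rescaling", {
  s <- quick_session(3, ground_truth(), fs = 250, seed = 4)
  np1 <- session_normpower(s$recording, s$events, small_bank(), 1, time_step = 20)
  rec2 <- recording(7.3 * s$recording$data, s$recording$fs,
                    s$recording$channels)
  np2 <- session_normpower(rec2, s$events, small_bank(), 1, time_step = 20)
  expect_equal(np1$values, np2$values, tolerance = 1e-10)
})

test_that("band averaging selects the right grid frequencies", {
  bank <- small_bank()
  v <- array(7, c(2, 12, 20))
  tf <- tf_tensor(v, bank$frequencies, 1:20, "normpower")
  ba <- band_average(tf, c(15, 30))
  expect_true(all(ba$freqs_used >= 15 & ba$freqs_used <= 30))
  expect_true(all(ba$values == 7))
  # single grid frequency band degenerates to that row
  v2 <- array(rnorm(2 * 12 * 20), c(2, 12, 20))
  tf2 <- tf_tensor(v2, bank$frequencies, 1:20, "normpower")
  f1 <- bank$frequencies[5]
  ba2 <- band_average(tf2, c(f1, f1))
  expect_equal(ba2$values, v2[, 5, ])
  expect_error(band_average(tf2, c(100, 200)), "intersect")
})

test_that("instantaneous phase advances at 2 pi f and flips under negation", {
  fs <- 500
  rec <- sine_recording(20, fs, dur_s = 10)
  bank20 <- build_wavelet_bank(20, 8, 1)
  ev <- data.frame(onset = 4000, block = 1, trial_in_block = 1,
                   condition = factor("target", levels = c("target", "distractor")),
                   correct = TRUE)
  tf <- epoch_tf(wavelet_transform_recording(rec, bank20, 1), ev, crop = c(0, 1000))
  ph <- instantaneous_phase(tf)
  expect_true(all(ph$values > -pi & ph$values <= pi))
  unw <- cumsum(c(ph$values[1, 1, 1],
                  wrap_phase(diff(ph$values[1, 1, ]))))
  slope <- stats::coef(stats::lm(unw ~ seq_along(unw)))[2] # rad per 2 ms
  expect_lt(abs(slope - 2 * pi * 20 / fs), 1e-3)
  recn <- recording(-rec$data, fs, rec$channels)
  tfn <- epoch_tf(wavelet_transform_recording(recn, bank20, 1), ev, crop = c(0, 1000))
  dd <- wrap_phase(instantaneous_phase(tfn)$values - ph$values)
  expect_lt(max(abs(abs(dd) - pi)), 1e-6)
  # zero signal: flagged, no crash
  rec0 <- recording(matrix(0, 1, 5000), fs, rec$channels)
  tf0 <- epoch_tf(wavelet_transform_recording(rec0, bank20, 1),
                  transform(ev, onset = 2000), crop = c(0, 1000))
  ph0 <- instantaneous_phase(tf0)
  expect_gt(attr(ph0, "n_zero_magnitude"), 0)
})

test_that("band power of a unit sinusoid is invariant to trial count and jitter", {
  fs <- 500
  rec <- sine_recording(20, fs, dur_s = 40)
  bank20 <- build_wavelet_bank(20, 8, 1)
  mk_ev <- function(onsets) data.frame(onset = onsets, block = 1,
                                       trial_in_block = seq_along(onsets),
                                       condition = factor("target", levels = c("target", "distractor")),
                                       correct = TRUE)
  cont <- wavelet_transform_recording(rec, bank20, 1)
  p2 <- mean(Mod(epoch_tf(cont, mk_ev(c(5000, 9000)), crop = c(0, 1000))$values)^2)
  p5 <- mean(Mod(epoch_tf(cont, mk_ev(c(4000 + 337, 11000 + 71, 15000, 21000 + 13, 30000)),
                          crop = c(0, 1000))$values)^2)
  expect_equal(p2, p5, tolerance = 1e-4)
})

test_that("buffers protect the analysis window (exact at 8 Hz, bounded at 2 Hz)", {
  # at 8 Hz the kernel (4 sigma ~ 0.48 s) sits fully inside a 1 s buffer:
  # growing the buffer cannot change anything
  s <- quick_session(6, null_ground_truth(), fs = 250, seed = 5,
                     isi_mean = 1500)
  ev <- s$events[-nrow(s$events), ]
  b8 <- build_wavelet_bank(8, 8, 1)
  p1 <- Mod(wavelet_transform(epoch_recording(s$recording, ev, buffer = 1000),
                              b8, 1, crop = c(-250, 1250))$values)^2
  p2 <- Mod(wavelet_transform(epoch_recording(s$recording, ev, buffer = 2000),
                              b8, 1, crop = c(-250, 1250))$values)^2
  expect_equal(p1, p2, tolerance = 1e-10)
  # at 2 Hz the wavenumber-6 kernel outgrows the buffer; the median change
  # stays below 0.5% and the mean below 3% (see decisions notes)
  b2 <- build_wavelet_bank(2, 8, 1)
  q1 <- Mod(wavelet_transform(epoch_recording(s$recording, ev, buffer = 1000),
                              b2, 1, crop = c(-250, 1250))$values)^2
  q2 <- Mod(wavelet_transform(epoch_recording(s$recording, ev, buffer = 2000),
                              b2, 1, crop = c(-250, 1250))$values)^2
  rel <- abs(q1 - q2) / q2
  expect_lt(stats::median(rel), 0.01)
  expect_lt(mean(rel), 0.03)
})

test_that("transform rejects banks above Nyquist", {
  s <- quick_session(2, null_ground_truth(), fs = 250, seed = 1)
  ep <- epoch_recording(s$recording, s$events)
  expect_error(wavelet_transform(ep, build_wavelet_bank(2, 8, 57), 1),
               "Nyquist")
})
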