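# Synthetic-data generator: event schema, oscillator ground truth, spike
# statistics.

test_that("event tables have the block structure and seeded determinism", {
  ev <- generate_task_events(task_config(seed = 7))
  expect_equal(nrow(ev), 240)
  expect_equal(sum(ev$condition == "target"), 120)
  expect_equal(sum(ev$condition == "distractor"), 120)
  tab <- table(ev$block, ev$condition)
  expect_true(all(tab == 4))
  expect_equal(ev$trial_in_block, rep(1:8, 30))
  expect_true(all(diff(ev$onset) > 0))
  # determinism and seed sensitivity
  expect_identical(ev, generate_task_events(task_config(seed = 7)))
  ev2 <- generate_task_events(task_config(seed = 8))
  expect_false(identical(ev$condition, ev2$condition))
})

test_that("inter-onset intervals respect the jitter bounds over 10,000 draws", {
  ev <- generate_task_events(task_config(n_blocks = 1430, seed = 3))
  iv <- unlist(lapply(split(ev$onset, ev$block), diff))
  expect_gte(length(iv), 10000)
  expect_true(all(iv >= 900 & iv <= 1100))
  # jitter is uniform-ish: spread fills the range
  expect_lt(min(iv), 910)
  expect_gt(max(iv), 1090)
})

test_that("degenerate task configs behave as specified", {
  ev0 <- generate_task_events(task_config(n_blocks = 0))
  expect_equal(nrow(ev0), 0)
  expect_named(ev0, c("onset", "block", "trial_in_block", "condition", "correct"))
  expect_error(task_config(n_target_per_block = 9), "exceed")
  expect_error(task_config(stim_duration = -1), "duration")
})

test_that("null configuration gives stationary band power", {
  s <- quick_session(20, null_ground_truth(), seed = 11)
  np <- session_normpower(s$recording, s$events, small_bank(), 1,
                          time_step = 20)
  ba <- band_average(np, c(15, 30))
  post <- mean(ba$values[, ba$times >= 0 & ba$times <= 1000])
  expect_lt(abs(post), 8) # percent units; ~2-3 SD of the trial-mean noise
})

test_that("perfect coupling gives identical channels up to the phase lag", {
  ch <- default_channels(1, 1, 0)
  tr <- ground_truth(coupling_strength = 1, coupling_gain_distractor = 0,
                     noise_sd = 0, theta_amp = 0, erd_depth_target = 0,
                     erd_depth_distractor = 0, block_slope = 0, theta_gain = 0,
                     coupling_phase_lag = pi / 4)
  s <- quick_session(3, tr, fs = 500, seed = 5, channels = ch)
  ta <- epoch_tf(wavelet_transform_recording(s$recording, small_bank(), "stn1"),
                 s$events, crop = c(0, 1000))
  tb <- epoch_tf(wavelet_transform_recording(s$recording, small_bank(), "lat1"),
                 s$events, crop = c(0, 1000))
  coh <- sliding_coherence(ta, tb, 250, 20)
  k20 <- which.min(abs(coh$freqs - 20))
  expect_true(all(coh$values[, k20, ] > 0.999))
  dphi <- Arg(ta$values[, k20, 100] * Conj(tb$values[, k20, 100]))
  expect_lt(max(abs(dphi - pi / 4)), 0.05)
})

test_that("amplitude ERD of 0.5 yields ~ -75% normalized beta power", {
  # widely spaced trials so each baseline is uncontaminated; the
  # amplitude-to-power squaring oracle gives (1 - 0.5)^2 - 1 = -75%
  ev <- generate_task_events(task_config(n_blocks = 6, isi_mean = 1500, seed = 3))
  tr <- ground_truth(erd_depth_target = 0.5, erd_depth_distractor = 0.5,
                     rebound_latency_target = 600, rebound_latency_distractor = 600,
                     rebound_ramp = 150,
                     theta_amp = 0, noise_sd = 0, block_slope = 0, theta_gain = 0)
  rec <- synthesize_lfp(ev, tr, one_channel(), fs = 500, seed = 2)
  bank <- build_wavelet_bank(15, 8, 9)
  np <- session_normpower(rec, ev, bank, 1)
  pk <- which.min(abs(bank$frequencies - 20))
  hold <- np$times >= 150 & np$times <= 400
  expect_lt(abs(mean(np$values[, pk, hold]) - (-75)), 5)
})

test_that("generated beta peaks at the grid frequency nearest beta_freq", {
  s <- quick_session(4, ground_truth(theta_amp = 0, noise_sd = 0.2),
                     fs = 500, seed = 9)
  bank <- build_wavelet_bank()
  tf <- epoch_tf(wavelet_transform_recording(s$recording, bank, 1), s$events,
                 crop = c(-500, 1250), time_step = 10)
  pow <- apply(Mod(tf$values)^2, 2, mean)
  # restrict to 10-40 Hz so 1/f noise cannot win
  sel <- bank$frequencies > 10 & bank$frequencies < 40
  pk <- bank$frequencies[sel][which.max(pow[sel])]
  near <- which.min(abs(bank$frequencies - 20))
  expect_lte(abs(log2(pk / bank$frequencies[near])), 1 / 8 + 1e-9)
})

test_that("kappa = 0 spiking is homogeneous Poisson at the base rate", {
  ev <- generate_task_events(task_config(n_blocks = 0))
  tr <- null_ground_truth(spike_base_rate = 36)
  ph <- rep(0, 100000) # 100 s at 1 kHz
  st <- synthesize_spikes(ev, ph, tr, fs = 1000, seed = 5)
  n <- length(st$spike_times)
  se <- sqrt(36 / 100)
  expect_lt(abs(n / 100 - 36), 3 * se)
  # exponential inter-spike intervals on 10 of 10 seeds
  pvals <- vapply(1:10, function(sd) {
    sti <- synthesize_spikes(ev, ph, tr, fs = 1000, seed = sd)
    isi <- diff(sti$spike_times)
    suppressWarnings(stats::ks.test(isi, "pexp", rate = 1 / mean(isi))$p.value)
  }, numeric(1))
  expect_true(all(pvals > 0.01))
})

test_that("large kappa concentrates spike phases per the von Mises law", {
  ev <- generate_task_events(task_config(n_blocks = 0))
  phi <- 2 * pi * 20 * (0:99999) / 1000
  wrapped <- (phi + pi) %% (2 * pi) - pi
  r_of_kappa <- function(kappa, seed) {
    tr <- null_ground_truth(kappa = kappa, preferred_phase = 1,
                            spike_base_rate = 36)
    st <- synthesize_spikes(ev, wrapped, tr, fs = 1000, seed = seed)
    ph <- wrapped[pmin(round(st$spike_times) + 1, length(wrapped))]
    Mod(mean(exp(1i * ph)))
  }
  r8 <- r_of_kappa(8, 6)
  expect_lt(abs(r8 - besselI(8, 1) / besselI(8, 0)), 0.01)
  # circular SD shrinks as kappa grows
  sd_circ <- function(r) sqrt(-2 * log(r))
  expect_lt(sd_circ(r8), sd_circ(r_of_kappa(2, 7)))
  # mean direction is the preferred phase
  tr <- null_ground_truth(kappa = 8, preferred_phase = 1, spike_base_rate = 36)
  st <- synthesize_spikes(ev, wrapped, tr, fs = 1000, seed = 8)
  ph <- wrapped[pmin(round(st$spike_times) + 1, length(wrapped))]
  expect_lt(abs(Arg(mean(exp(1i * (ph - 1))))), 0.05)
})

test_that("rate modulation halves the plateau firing rate", {
  ev <- generate_task_events(task_config(n_blocks = 25, seed = 4)) # 200 trials
  tr <- ground_truth(kappa = 0, spike_rate_modulation = -0.5,
                     spike_base_rate = 36)
  ph <- rep(0, 300000)
  st <- synthesize_spikes(ev, ph, tr, fs = 1000, seed = 8)
  s <- st$spike_times
  plateau <- sum(vapply(ev$onset, function(o) sum(s >= o + 250 & s < o + 550),
                        numeric(1))) / (nrow(ev) * 0.3)
  expect_lt(abs(plateau - 18), 2.5)
  expect_error(synthesize_spikes(ev, ph, ground_truth(spike_base_rate = -1)),
               "spike_base_rate")
})

test_that("null_dataset is deterministic and effect-free", {
  nd1 <- null_dataset(task_config(n_blocks = 3), seed = 42, fs = 250)
  nd2 <- null_dataset(task_config(n_blocks = 3), seed = 42, fs = 250)
  expect_identical(nd1$recording$data, nd2$recording$data)
  expect_identical(nd1$spikes$spike_times, nd2$spikes$spike_times)
  expect_equal(nd1$truth$erd_depth_target, 0)
  expect_equal(nd1$truth$kappa, 0)
  nd3 <- null_dataset(task_config(n_blocks = 3), seed = 43, fs = 250)
  expect_false(identical(nd1$recording$data, nd3$recording$data))
})

test_that("error trials adopt distractor physiology", {
  tr <- ground_truth(error_fraction = 0.25)
  s <- quick_session(10, tr, seed = 13)
  phys <- s$recording$aux$physio
  cond <- as.character(s$events$condition)
  flipped <- phys != cond
  expect_true(all(cond[flipped] == "target"))
  expect_equal(sum(flipped), round(0.25 * sum(cond == "target")))
  expect_true(all(!s$recording$aux$correct[flipped]))
})

test_that("coupling pair validation rejects unknown channels", {
  ev <- generate_task_events(task_config(n_blocks = 1))
  expect_error(synthesize_lfp(ev, ground_truth(), one_channel(),
                              fs = 250, couple = c("stn1", "nope")),
               "undefined")
  expect_error(synthesize_lfp(ev, ground_truth(beta_freq = 100), one_channel(),
                              fs = 250), "fs")
})
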