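# Synthetic session generator. Emulates the statistical structure the
# analysis assumes: blocks of 8 stimuli (4 targets + 4 distractors randomly
# interleaved, 500 ms stimulus + 500 +/- 100 ms blank), event-locked beta
# (15-30 Hz) desynchronization with an earlier rebound on distractor trials,
# theta increases, a progressive within-block beta decline, a shared beta
# source coupling one cortical and one STN channel, and STN spike trains with
# rate modulation and von Mises beta-phase locking.

#' Task configuration
#'
#' @param n_blocks Number of blocks (default 30, a full session).
#' @param trials_per_block Stimuli per block (default 8).
#' @param n_target_per_block Target stimuli per block (default 4).
#' @param stim_duration Stimulus duration, ms (default 500).
#' @param isi_mean Mean post-stimulus blank, ms (default 500).
#' @param isi_jitter Half-width of the uniform blank jitter, ms (default 100).
#' @param block_gap Dead time between blocks, ms (default 4000; stands in for
#'   the retrieval/feedback period and guarantees non-overlapping epochs).
#' @param t_start Onset of the first stimulus, ms (default 3000, so epoch
#'   buffers never run off the start of the recording).
#' @param seed Integer seed; identical seeds give identical event tables.
#' @return An object of class `fp_taskconfig`.
#' @export
task_config <- function(n_blocks = 30, trials_per_block = 8,
                        n_target_per_block = 4, stim_duration = 500,
                        isi_mean = 500, isi_jitter = 100, block_gap = 4000,
                        t_start = 3000, seed = 1) {
  if (n_target_per_block > trials_per_block)
    stop("n_target_per_block must not exceed trials_per_block")
  if (stim_duration <= 0 || isi_mean <= 0 || isi_jitter < 0 ||
      isi_jitter >= stim_duration + isi_mean)
    stop("invalid durations")
  structure(list(n_blocks = max(0L, as.integer(n_blocks)),
                 trials_per_block = as.integer(trials_per_block),
                 n_target_per_block = as.integer(n_target_per_block),
                 stim_duration = stim_duration, isi_mean = isi_mean,
                 isi_jitter = isi_jitter, block_gap = block_gap,
                 t_start = t_start, seed = as.integer(seed)),
            class = "fp_taskconfig")
}

#' Ground-truth effect parameters for the generator
#'
#' Defaults are the package's stated world: the paper describes the effects
#' qualitatively, so sizes are fixed here once at values that give comfortable
#' statistical power at ~90 trials per condition (see the methods vignette).
#'
#' @param beta_freq Beta oscillator frequency, Hz.
#' @param theta_freq Theta oscillator frequency, Hz.
#' @param beta_amp,theta_amp,noise_sd Component amplitudes (arbitrary units).
#' @param noise_exponent 1/f spectral slope of the background noise.
#' @param erd_depth_target,erd_depth_distractor Fractional beta *amplitude*
#'   drop during the desynchronization (in \[0, 1\]; a drop d gives a
#'   (1-d)^2 - 1 fractional *power* change).
#' @param rebound_latency_target,rebound_latency_distractor Time after
#'   stimulus onset, ms, at which the beta envelope has returned to
#'   baseline. The distractor default is earlier (the condition effect is an
#'   early termination of the beta decrease).
#' @param rebound_ramp Length of the cosine recovery ramp ending at the
#'   rebound latency, ms.
#' @param theta_gain Fractional theta amplitude increase during the trial.
#' @param block_slope Fractional decline of task-window beta amplitude per
#'   trial-in-block position.
#' @param coupling_strength Mixing weight in \[0, 1\] of the shared beta
#'   source in the coupled cortical channel.
#' @param coupling_phase_lag Phase lag (radians) of the cortical copy of the
#'   shared beta source.
#' @param coupling_gain_distractor Fractional increase of coupling strength
#'   during distractor trials (0 = none).
#' @param spike_base_rate Baseline firing rate, spikes/s.
#' @param spike_rate_modulation Signed fractional rate change during the
#'   trial epoch (e.g. -0.3 = 30% drop).
#' @param kappa von Mises phase-concentration of spike timing (>= 0).
#' @param preferred_phase Preferred beta phase of spiking, radians.
#' @param error_fraction Fraction of target trials assigned distractor
#'   physiology (failed-encoding errors).
#' @return An object of class `fp_groundtruth`.
#' @export
ground_truth <- function(beta_freq = 20, theta_freq = 5,
                         beta_amp = 1, theta_amp = 0.6,
                         noise_sd = 1, noise_exponent = 1,
                         erd_depth_target = 0.35, erd_depth_distractor = 0.35,
                         rebound_latency_target = 700,
                         rebound_latency_distractor = 500,
                         rebound_ramp = 300,
                         theta_gain = 0.3, block_slope = 0.03,
                         coupling_strength = 0.6,
                         coupling_phase_lag = pi / 4,
                         coupling_gain_distractor = 0.25,
                         spike_base_rate = 36, spike_rate_modulation = -0.3,
                         kappa = 1, preferred_phase = pi,
                         error_fraction = 0) {
  if (coupling_strength < 0 || coupling_strength > 1)
    stop("coupling_strength must lie in [0, 1]")
  if (kappa < 0) stop("kappa must be >= 0")
  if (erd_depth_target < 0 || erd_depth_target > 1 ||
      erd_depth_distractor < 0 || erd_depth_distractor > 1)
    stop("erd depths must lie in [0, 1]")
  if (spike_base_rate < 0) stop("spike_base_rate must be >= 0")
  structure(as.list(environment()), class = "fp_groundtruth")
}

#' Null ground truth (all effect parameters zero)
#'
#' Used by type-I-error calibration: target and distractor trials are drawn
#' from an identical generative law.
#' @param ... Overrides passed on to [ground_truth()].
#' @return An `fp_groundtruth`.
#' @export
null_ground_truth <- function(...) {
  args <- list(erd_depth_target = 0, erd_depth_distractor = 0,
               theta_gain = 0, block_slope = 0, coupling_strength = 0,
               coupling_gain_distractor = 0, spike_rate_modulation = 0,
               kappa = 0, error_fraction = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(ground_truth, args)
}

#' Generate the trial/event table for a session
#'
#' Each block holds `trials_per_block` stimuli, exactly `n_target_per_block`
#' of them targets, randomly interleaved. Inter-onset intervals are
#' `stim_duration + isi_mean +/- isi_jitter` (uniform).
#'
#' @param config An [task_config()] object.
#' @return `data.frame` with columns `onset` (ms), `block`, `trial_in_block`,
#'   `condition` (factor target/distractor), `correct`.
#' @export
generate_task_events <- function(config) {
  stopifnot(inherits(config, "fp_taskconfig"))
  empty <- data.frame(onset = numeric(0), block = integer(0),
                      trial_in_block = integer(0),
                      condition = factor(character(0),
                                         levels = c("target", "distractor")),
                      correct = logical(0))
  if (config$n_blocks == 0) return(empty)
  with_seed(config$seed, {
    tpb <- config$trials_per_block
    rows <- vector("list", config$n_blocks)
    t <- config$t_start
    for (b in seq_len(config$n_blocks)) {
      cond <- rep("distractor", tpb)
      cond[sample.int(tpb, config$n_target_per_block)] <- "target"
      onsets <- numeric(tpb)
      for (k in seq_len(tpb)) {
        onsets[k] <- t
        t <- t + config$stim_duration + config$isi_mean +
          stats::runif(1, -config$isi_jitter, config$isi_jitter)
      }
      t <- t + config$block_gap
      rows[[b]] <- data.frame(onset = onsets, block = b,
                              trial_in_block = seq_len(tpb),
                              condition = factor(cond, levels = c("target", "distractor")),
                              correct = TRUE)
    }
    do.call(rbind, rows)
  })
}

#' Default channel layout for synthetic sessions
#'
#' @param n_stn,n_lateral,n_anterior Channel counts per group.
#' @return `data.frame(name, role, group)`.
#' @export
default_channels <- function(n_stn = 3, n_lateral = 8, n_anterior = 0) {
  rbind(
    if (n_stn > 0) data.frame(name = paste0("stn", seq_len(n_stn)),
                              role = "stn-macro", group = "stn"),
    if (n_lateral > 0) data.frame(name = paste0("lat", seq_len(n_lateral)),
                                  role = "lateral-pfc", group = "lateral"),
    if (n_anterior > 0) data.frame(name = paste0("ant", seq_len(n_anterior)),
                                   role = "anterior-pfc", group = "anterior"))
}

# Per-trial envelopes over the continuous session time base.
# Returns list(beta_env, task_bump, distractor_ind, physio) where physio is
# the per-trial physiological condition (errors get distractor physiology).
session_envelopes <- function(events, truth, n, fs, seed) {
  dt <- 1000 / fs
  beta_env <- rep(1, n)
  task_bump <- numeric(n)
  distractor_ind <- numeric(n)
  physio <- as.character(events$condition)
  if (truth$error_fraction > 0) {
    tgt <- which(events$condition == "target")
    n_err <- round(truth$error_fraction * length(tgt))
    if (n_err > 0) {
      err <- with_seed(derive_seed(seed, "errors"),
                       sample(tgt, n_err))
      physio[err] <- "distractor"
      events$correct[err] <- FALSE
    }
  }
  for (i in seq_len(nrow(events))) {
    o <- events$onset[i]
    cond <- physio[i]
    depth <- if (cond == "target") truth$erd_depth_target else truth$erd_depth_distractor
    reb <- if (cond == "target") truth$rebound_latency_target else truth$rebound_latency_distractor
    i0 <- floor(o / dt) + 1
    # task bump: transient plateau over 0..800 ms (200 ms raised-cosine
    # ramps), so it has decayed before the next trial's baseline window
    nb <- round(800 / dt)
    if (i0 + nb - 1 <= n) {
      g <- smooth_plateau(nb, round(200 / dt))
      idx <- i0:(i0 + nb - 1)
      task_bump[idx] <- pmax(task_bump[idx], g)
      if (cond == "distractor") distractor_ind[idx] <- pmax(distractor_ind[idx], g)
    }
    # beta envelope: 100 ms attack to (1 - depth), hold, then a cosine
    # recovery ramp of rebound_ramp ms finishing at the rebound latency
    # (the transient shape real event-related desynchronization shows;
    # a long hold would park the next trial's baseline inside the dip)
    ner <- round(reb / dt)
    if (i0 + ner - 1 <= n && depth > 0) {
      tt <- (seq_len(ner) - 1) * dt
      hold_end <- max(100, reb - truth$rebound_ramp)
      s <- rep(1, ner)
      atk <- tt < 100
      s[atk] <- 0.5 * (1 - cos(pi * tt[atk] / 100))
      dec <- tt >= hold_end
      s[dec] <- 0.5 * (1 + cos(pi * (tt[dec] - hold_end) / (reb - hold_end)))
      idx <- i0:(i0 + ner - 1)
      beta_env[idx] <- pmin(beta_env[idx], 1 - depth * s)
    }
    # within-block decline of task-window beta amplitude
    if (truth$block_slope != 0 && i0 + nb - 1 <= n) {
      s <- 1 - truth$block_slope * (events$trial_in_block[i] - 1)
      idx <- i0:(i0 + nb - 1)
      beta_env[idx] <- beta_env[idx] *
        (1 - (1 - s) * smooth_plateau(nb, round(200 / dt)))
    }
  }
  list(beta_env = beta_env, task_bump = task_bump,
       distractor_ind = distractor_ind, physio = physio,
       correct = events$correct)
}

#' Synthesize a multichannel LFP/iEEG session
#'
#' Each channel is 1/f-coloured noise plus theta and beta oscillators whose
#' envelopes carry the ground-truth effects. The designated channel pair
#' shares a common beta source mixed with weight `coupling_strength` and a
#' fixed phase lag.
#'
#' @param events Event table from [generate_task_events()].
#' @param truth A [ground_truth()] object.
#' @param channels `data.frame(name, role, group)`; see [default_channels()].
#' @param fs Sampling rate, Hz (must be at least 4x `beta_freq`).
#' @param couple Length-2 character vector naming the (STN, cortical) coupled
#'   pair, or `NULL` for no coupling. Defaults to the first STN and first
#'   lateral channel when both exist.
#' @param seed Integer seed; identical inputs give bit-identical output.
#' @return An [recording()] whose `aux` holds the true beta phase of each
#'   STN macro channel, the per-trial physiological condition, and the truth.
#' @export
synthesize_lfp <- function(events, truth, channels = default_channels(),
                           fs = 1000, couple = NULL, seed = 1) {
  stopifnot(inherits(truth, "fp_groundtruth"))
  if (fs < 4 * truth$beta_freq) stop("fs must be >= 4 * beta_freq")
  if (is.null(couple)) {
    stn <- channels$name[channels$role == "stn-macro"]
    ctx <- channels$name[channels$role %in% c("lateral-pfc", "anterior-pfc")]
    if (length(stn) && length(ctx) && truth$coupling_strength > 0)
      couple <- c(stn[1], ctx[1])
  }
  if (!is.null(couple) && !all(couple %in% channels$name))
    stop("coupling pair names undefined in channel spec: ",
         paste(setdiff(couple, channels$name), collapse = ", "))
  t_end <- if (nrow(events)) max(events$onset) + 2600 else 5000
  n <- ceiling(t_end * fs / 1000)
  tsec <- (seq_len(n) - 1) / fs
  env <- session_envelopes(events, truth, n, fs, seed)
  with_seed(derive_seed(seed, "lfp"), {
    common_phi0 <- stats::runif(1, 0, 2 * pi)
    phi_common <- 2 * pi * truth$beta_freq * tsec + common_phi0
    w <- truth$coupling_strength *
      (1 + truth$coupling_gain_distractor * env$distractor_ind)
    w <- pmin(w, 1)
    dat <- matrix(0, nrow(channels), n)
    beta_phase <- list()
    for (ci in seq_len(nrow(channels))) {
      nm <- channels$name[ci]
      phi0 <- stats::runif(1, 0, 2 * pi)
      phi_own <- 2 * pi * truth$beta_freq * tsec + phi0
      if (!is.null(couple) && nm == couple[1]) {
        beta_sig <- cos(phi_common)
        phi_ch <- phi_common
      } else if (!is.null(couple) && nm == couple[2]) {
        beta_sig <- w * cos(phi_common - truth$coupling_phase_lag) +
          sqrt(1 - w^2) * cos(phi_own)
        phi_ch <- phi_common - truth$coupling_phase_lag
      } else {
        beta_sig <- cos(phi_own)
        phi_ch <- phi_own
      }
      th_phi0 <- stats::runif(1, 0, 2 * pi)
      theta_sig <- (1 + truth$theta_gain * env$task_bump) *
        cos(2 * pi * truth$theta_freq * tsec + th_phi0)
      dat[ci, ] <- truth$beta_amp * env$beta_env * beta_sig +
        truth$theta_amp * theta_sig +
        colored_noise(n, fs, truth$noise_exponent, truth$noise_sd)
      if (channels$role[ci] == "stn-macro")
        beta_phase[[nm]] <- wrap_phase(phi_ch)
    }
    recording(dat, fs, channels,
              aux = list(beta_phase = beta_phase, physio = env$physio,
                         correct = env$correct, truth = truth))
  })
}

#' Synthesize an STN spike train phase-locked to a beta oscillation
#'
#' Inhomogeneous Poisson process with intensity
#' `lambda(t) = r(t) * exp(kappa * cos(phi(t) - phi0)) / I0(kappa)` where
#' `r(t) = spike_base_rate * (1 + spike_rate_modulation * g(t))` and `g` is a
#' smooth within-trial plateau over 0-1000 ms. The Bessel normalization keeps
#' the phase factor mean-1 over uniform phase, so `spike_base_rate` is the
#' out-of-trial rate regardless of `kappa`.
#'
#' @param events Event table (defines the within-trial bump `g`).
#' @param beta_phase Radian phase time series covering the session (e.g. from
#'   `synthesize_lfp()$aux$beta_phase`).
#' @param truth A [ground_truth()].
#' @param fs Sampling rate of `beta_phase`, Hz.
#' @param seed Integer seed.
#' @param cluster_id,depth_pct,paired_macro Metadata for the returned train.
#' @return An [spike_train()].
#' @export
synthesize_spikes <- function(events, beta_phase, truth, fs = 1000, seed = 1,
                              cluster_id = "clu1", depth_pct = 50,
                              paired_macro = NA_character_) {
  stopifnot(inherits(truth, "fp_groundtruth"))
  if (truth$spike_base_rate < 0) stop("negative base rate")
  n <- length(beta_phase)
  t_max <- n / fs * 1000
  g <- session_envelopes(events, truth, n, fs, seed)$task_bump
  rate <- truth$spike_base_rate * (1 + truth$spike_rate_modulation * g)
  vm <- exp(truth$kappa * cos(beta_phase - truth$preferred_phase)) /
    besselI(truth$kappa, 0)
  lambda <- pmax(rate * vm, 0)
  lam_max <- max(lambda)
  with_seed(derive_seed(seed, "spikes", cluster_id), {
    n_cand <- stats::rpois(1, lam_max * t_max / 1000)
    cand <- sort(stats::runif(n_cand, 0, t_max))
    idx <- pmin(pmax(round(cand * fs / 1000) + 1, 1), n)
    keep <- stats::runif(n_cand) < lambda[idx] / lam_max
    spike_train(cand[keep], cluster_id = cluster_id, depth_pct = depth_pct,
                paired_macro = paired_macro, t_max = t_max)
  })
}

#' Generate a fully null dataset (type-I calibration harness)
#'
#' All ground-truth effect parameters are zero: target and distractor trials
#' are drawn from an identical generative law, spiking is homogeneous Poisson
#' with no phase preference.
#'
#' @param config A [task_config()].
#' @param seed Integer seed.
#' @param channels Channel spec (default one STN macro channel).
#' @param fs Sampling rate, Hz.
#' @return `list(recording, events, spikes, truth)`.
#' @export
null_dataset <- function(config, seed = 1,
                         channels = default_channels(1, 0, 0), fs = 1000) {
  truth <- null_ground_truth()
  cfg <- config
  cfg$seed <- derive_seed(seed, "events")
  events <- generate_task_events(cfg)
  rec <- synthesize_lfp(events, truth, channels, fs = fs,
                        seed = derive_seed(seed, "lfp"))
  ph <- rec$aux$beta_phase[[1]] %||% rep(0, ncol(rec$data))
  spikes <- synthesize_spikes(events, ph, truth, fs = fs,
                              seed = derive_seed(seed, "spk"),
                              paired_macro = names(rec$aux$beta_phase)[1] %||% NA_character_)
  list(recording = rec, events = events, spikes = spikes, truth = truth)
}
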