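# End-to-end orchestration: simulate -> preprocess -> spectral -> stats ->
# connectivity -> spiking, with a validated config, deterministic seed
# fan-out, and a JSON-serializable run report.

#' Default pipeline configuration
#'
#' All module parameters at their standard values (the analysis defaults:
#' 47-wavelet bank, 200 permutations, theta 2-8 Hz / beta 15-30 Hz bands,
#' 250 ms coherence windows, 50 ms rate kernels).
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    n_sessions = 6,
    out = NULL,
    stages = list(simulate = TRUE, preprocess = TRUE, spectral = TRUE,
                  stats = TRUE, connect = TRUE, spikes = TRUE),
    task = list(n_blocks = 30, trials_per_block = 8, n_target_per_block = 4,
                stim_duration = 500, isi_mean = 500, isi_jitter = 100,
                block_gap = 4000, t_start = 3000),
    truth = unclass(ground_truth()),
    recording = list(fs = 1000, n_stn = 3, n_lateral = 4, n_anterior = 0,
                     generate_fs = NULL),
    preprocess = list(low = 1, high = 500, notch = 60, target_fs = 1000,
                      z_thresh = 6),
    spectral = list(fmin = 2, scales_per_octave = 8, n_freqs = 47,
                    wavenumber = 6, baseline = c(-500, 0), per_trial = TRUE,
                    crop = c(-500, 1250)),
    stats = list(n_perm = 200, threshold = 0.05, alpha = 0.05,
                 time_step = 10,
                 bands = list(theta = c(2, 8), beta = c(15, 30))),
    connectivity = list(window = 250, step = 10, baseline = c(-500, 0),
                        select_contacts = TRUE),
    spiking = list(n_clusters = 2, kernel_sd = 50, bin = 1,
                   window = c(-500, 1000), phase_window = c(0, 1000),
                   n_surr = 200, exclude_sd = 10, min_trials = 10)
  )
}

merge_validate <- function(user, def, path = "") {
  if (!is.list(user)) stop("config section must be a list: ", path)
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (nm in names(user)) {
    if (is.list(def[[nm]]) && !is.null(names(def[[nm]])) &&
        !nm %in% c("bands")) {
      def[[nm]] <- merge_validate(user[[nm]], def[[nm]], paste0(path, ".", nm))
    } else {
      def[[nm]] <- user[[nm]]
    }
  }
  def
}

#' Validate a pipeline configuration
#'
#' Accepts a JSON file path or a nested list; unknown keys, wrong types, and
#' out-of-range values are named validation errors. Missing keys are filled
#' with the defaults of [default_config()].
#'
#' @param x Path to a JSON config file, a list, or `NULL` (pure defaults).
#' @return The validated, completed config (class `fp_config`).
#' @export
validate_config <- function(x = NULL) {
  user <- if (is.null(x)) list()
  else if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x)
    txt <- paste(readLines(x, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list() else
      jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else x
  cfg <- merge_validate(user, default_config())
  chk <- function(cond, msg) if (!cond) stop("config validation: ", msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be a number")
  chk(cfg$n_sessions >= 1, "n_sessions must be >= 1")
  for (bn in names(cfg$stats$bands)) {
    b <- cfg$stats$bands[[bn]]
    chk(length(b) == 2 && b[1] < b[2],
        sprintf("band '%s' must be an increasing pair", bn))
  }
  chk(cfg$stats$n_perm >= 1, "n_perm must be >= 1")
  chk(cfg$spectral$fmin > 0 && cfg$spectral$n_freqs >= 1, "invalid wavelet bank")
  chk(cfg$truth$erd_depth_target >= 0 && cfg$truth$erd_depth_target <= 1 &&
      cfg$truth$erd_depth_distractor >= 0 && cfg$truth$erd_depth_distractor <= 1,
      "erd depths must lie in [0, 1]")
  chk(cfg$truth$coupling_strength >= 0 && cfg$truth$coupling_strength <= 1,
      "coupling_strength must lie in [0, 1]")
  chk(cfg$truth$kappa >= 0, "kappa must be >= 0")
  chk(cfg$preprocess$target_fs > 0 && cfg$recording$fs > 0, "invalid rates")
  structure(cfg, class = c("fp_config", "list"))
}

#' Simulate one complete session (events, signals, spike clusters)
#'
#' @param cfg Validated config.
#' @param session Session index (drives the seed substream).
#' @return `list(events, recording, spikes)` where `spikes` is a list of
#'   [spike_train()]s paired to the first STN macro channel.
#' @export
simulate_session <- function(cfg, session = 1) {
  truth <- do.call(ground_truth, cfg$truth)
  tcfg <- do.call(task_config,
                  c(cfg$task, list(seed = derive_seed(cfg$seed, "task", session))))
  events <- generate_task_events(tcfg)
  ch <- default_channels(cfg$recording$n_stn, cfg$recording$n_lateral,
                         cfg$recording$n_anterior)
  fs <- cfg$recording$generate_fs %||% cfg$recording$fs
  rec <- synthesize_lfp(events, truth, ch, fs = fs,
                        seed = derive_seed(cfg$seed, "lfp", session))
  macro <- names(rec$aux$beta_phase)[1]
  spikes <- lapply(seq_len(cfg$spiking$n_clusters), function(k) {
    synthesize_spikes(events, rec$aux$beta_phase[[macro]], truth, fs = fs,
                      seed = derive_seed(cfg$seed, "spk", session, k),
                      cluster_id = sprintf("s%d_clu%d", session, k),
                      depth_pct = 30 + 40 * (k - 1) / max(1, cfg$spiking$n_clusters - 1),
                      paired_macro = macro)
  })
  list(events = events, recording = rec, spikes = spikes)
}

#' Normalized-power tensor of one channel of a session
#'
#' Convenience wrapper: continuous wavelet transform, epoching of the
#' coefficients, squared magnitude, percent-change baseline normalization,
#' optional time decimation.
#'
#' @param rec An [recording()] (already preprocessed).
#' @param events Event table.
#' @param bank An [build_wavelet_bank()].
#' @param channel Channel name or index.
#' @param crop Retained window, ms.
#' @param time_step Decimation step for permutation maps, ms (`NULL` = none).
#' @param baseline Baseline window, ms.
#' @param per_trial Per-trial (default) or pooled baseline.
#' @return An `fp_tf` of kind `"normpower"`.
#' @export
session_normpower <- function(rec, events, bank, channel = 1,
                              crop = c(-500, 1250), time_step = NULL,
                              baseline = c(-500, 0), per_trial = TRUE) {
  cont <- wavelet_transform_recording(rec, bank, channel)
  tf <- epoch_tf(cont, events, crop = crop, time_step = time_step)
  normalize_to_baseline(tf_power(tf), baseline = baseline,
                        per_trial = per_trial)
}

#' Run the full analysis pipeline on simulated sessions
#'
#' Executes the enabled stages in dependency order and reproduces the
#' analysis surfaces of the study design on synthetic data: per-region
#' vs-baseline spectrograms with cluster correction, band-limited condition
#' contrasts, the within-block beta-decline regression and repeated-measures
#' ANOVA, the STN-cortical coherence contrast, firing-rate tests, and the
#' population spike-phase locking spectrum.
#'
#' @param config Anything [validate_config()] accepts.
#' @return A run report (class `fp_report`): per-stage summaries, cluster
#'   tables, seeds, wall-clock. If `config$out` is set, artifacts (events
#'   TSV, spikes TSV, config echo and report JSON, tensors RDS) are written
#'   there.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "fp_config")) config else validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  report <- list(config = unclass(cfg), stages = list())
  out <- cfg$out
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!cfg$stages$simulate) {
    report$wall_clock_s <- proc.time()[["elapsed"]] - t0
    return(structure(report, class = "fp_report"))
  }
  sessions <- lapply(seq_len(cfg$n_sessions), function(i) {
    stage_log("simulate", sprintf("session %d", i))
    simulate_session(cfg, i)
  })
  report$stages$simulate <- list(
    n_sessions = cfg$n_sessions,
    n_trials = vapply(sessions, function(s) nrow(s$events), integer(1)))
  if (!is.null(out)) {
    for (i in seq_along(sessions)) {
      write_events_tsv(sessions[[i]]$events,
                       file.path(out, sprintf("events_s%02d.tsv", i)))
      for (sp in sessions[[i]]$spikes)
        write_spikes_tsv(sp, file.path(out, sprintf("spikes_%s.tsv", sp$cluster_id)))
    }
    jsonlite::write_json(unclass(cfg), file.path(out, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  # ---- preprocess ---------------------------------------------------------
  if (cfg$stages$preprocess) {
    nrej <- integer(0)
    for (i in seq_along(sessions)) {
      rec <- sessions[[i]]$recording
      if (rec$fs > cfg$preprocess$target_fs)
        rec <- bandpass_notch_downsample(rec, cfg$preprocess$low,
                                         cfg$preprocess$high,
                                         cfg$preprocess$notch,
                                         cfg$preprocess$target_fs)
      if (sum(rec$channels$group == "stn") >= 2)
        rec <- rereference_common_average(rec, "stn")
      lat <- rec$channels$name[rec$channels$group == "lateral"]
      lat_rec <- if (length(lat) >= 2) rereference_bipolar(rec, lat) else NULL
      ep <- epoch_recording(rec, sessions[[i]]$events)
      ep <- reject_artifact_trials(ep, cfg$preprocess$z_thresh)
      sessions[[i]]$rec_pp <- rec
      sessions[[i]]$rec_lat <- lat_rec
      sessions[[i]]$keep_trials <- !ep$rejected
      nrej <- c(nrej, sum(ep$rejected))
      if (!is.null(out)) { # audit trail of rejection decisions
        utils::write.table(
          data.frame(session = i, trial = seq_along(ep$rejected),
                     rejected = ep$rejected, reason = ep$reject_reason),
          file.path(out, sprintf("rejections_s%02d.tsv", i)),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
      stage_log("preprocess", sprintf("session %d: %d trial(s) rejected", i, sum(ep$rejected)))
    }
    report$stages$preprocess <- list(rejected_trials = nrej)
  } else {
    for (i in seq_along(sessions)) {
      sessions[[i]]$rec_pp <- sessions[[i]]$recording
      sessions[[i]]$rec_lat <- NULL
      sessions[[i]]$keep_trials <- rep(TRUE, nrow(sessions[[i]]$events))
    }
  }

  # ---- spectral -----------------------------------------------------------
  if (!cfg$stages$spectral) {
    report$wall_clock_s <- proc.time()[["elapsed"]] - t0
    return(structure(report, class = "fp_report"))
  }
  bank <- build_wavelet_bank(cfg$spectral$fmin, cfg$spectral$scales_per_octave,
                             cfg$spectral$n_freqs, cfg$spectral$wavenumber)
  regions <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    ev <- s$events[s$keep_trials, , drop = FALSE]
    region_np <- function(rec, chans) {
      # per-channel power -> percent-change normalization (per-trial and
      # pooled baselines) -> average across the region's channels
      pw <- lapply(chans, function(ch) {
        cont <- wavelet_transform_recording(rec, bank, ch)
        tf_power(epoch_tf(cont, ev, crop = cfg$spectral$crop,
                          time_step = cfg$stats$time_step))
      })
      avg <- function(per_trial) {
        nps <- lapply(pw, normalize_to_baseline,
                      baseline = cfg$spectral$baseline, per_trial = per_trial)
        v <- nps[[1]]$values
        if (length(nps) > 1) for (k in 2:length(nps)) v <- v + nps[[k]]$values
        tf_tensor(v / length(nps), nps[[1]]$freqs, nps[[1]]$times,
                  "normpower", nps[[1]]$trial_index)
      }
      list(per_trial = avg(cfg$spectral$per_trial), pooled = avg(FALSE))
    }
    stn_ch <- s$rec_pp$channels$name[s$rec_pp$channels$group == "stn"]
    np <- region_np(s$rec_pp, stn_ch)
    sessions[[i]]$np_stn <- np$per_trial
    sessions[[i]]$np_stn_pooled <- np$pooled
    if (!is.null(s$rec_lat))
      sessions[[i]]$np_lat <- region_np(s$rec_lat, s$rec_lat$channels$name)$per_trial
    stage_log("spectral", sprintf("session %d decomposed", i))
  }
  report$stages$spectral <- list(
    n_freqs = length(bank$frequencies),
    time_step = cfg$stats$time_step)

  # ---- stats --------------------------------------------------------------
  if (cfg$stages$stats) {
    st <- cfg$stats
    np_list <- lapply(sessions, `[[`, "np_stn")
    analysis_sel <- np_list[[1]]$times >= -250
    sess_maps <- lapply(np_list, function(np)
      apply(np$values[, , analysis_sel, drop = FALSE], c(2, 3), mean))
    sm <- signflip_test(sess_maps, n_perm = st$n_perm,
                        seed = derive_seed(cfg$seed, "stats", 1))
    cl <- cluster_correct(sm, st$threshold, st$alpha)
    band_results <- list()
    for (bn in names(st$bands)) {
      series <- lapply(np_list, function(np) {
        ba <- band_average(np, st$bands[[bn]])
        colMeans(ba$values[, analysis_sel, drop = FALSE])
      })
      bt <- band_cluster_test(series, "vs-baseline", n_perm = st$n_perm,
                              seed = derive_seed(cfg$seed, "stats", bn))
      band_results[[bn]] <- list(vs_baseline = bt$clusters$clusters)
    }
    # condition contrast on the beta band
    beta_ab <- list(
      a = lapply(seq_along(sessions), function(i) {
        np <- np_list[[i]]
        ev <- sessions[[i]]$events[sessions[[i]]$keep_trials, , drop = FALSE]
        ba <- band_average(np, st$bands$beta)
        colMeans(ba$values[ev$condition[np$trial_index] == "target", analysis_sel, drop = FALSE])
      }),
      b = lapply(seq_along(sessions), function(i) {
        np <- np_list[[i]]
        ev <- sessions[[i]]$events[sessions[[i]]$keep_trials, , drop = FALSE]
        ba <- band_average(np, st$bands$beta)
        colMeans(ba$values[ev$condition[np$trial_index] == "distractor", analysis_sel, drop = FALSE])
      }))
    bc <- band_cluster_test(beta_ab, "a-vs-b", n_perm = st$n_perm,
                            seed = derive_seed(cfg$seed, "stats", "cond"))
    # within-block decline: regression + one-way RM ANOVA on the
    # pooled-baseline normalization (a per-trial baseline would absorb the
    # block-wise decline; see the methods vignette)
    task_sel <- np_list[[1]]$times >= 0 & np_list[[1]]$times <= 1000
    pw <- lapply(seq_along(sessions), function(i) {
      np <- sessions[[i]]$np_stn_pooled
      ba <- band_average(np, st$bands$beta)
      rowMeans(ba$values[, task_sel, drop = FALSE])
    })
    pos <- lapply(seq_along(sessions), function(i) {
      ev <- sessions[[i]]$events[sessions[[i]]$keep_trials, , drop = FALSE]
      ev$trial_in_block[np_list[[i]]$trial_index]
    })
    reg <- regress_band_vs_trialnum(pw, pos)
    posmat <- t(vapply(seq_along(pw), function(i)
      vapply(split(pw[[i]], pos[[i]]), mean, numeric(1)),
      numeric(length(unique(pos[[1]])))))
    aov_res <- if (cfg$n_sessions >= 2) rm_anova_trialnum(posmat) else NULL
    report$stages$stats <- list(
      vs_baseline_clusters = cl$clusters,
      band = band_results,
      beta_condition_clusters = bc$clusters$clusters,
      trialnum_regression = reg[c("rho", "t", "df", "p")],
      trialnum_anova = aov_res)
    stage_log("stats", sprintf("%d significant vs-baseline cluster(s)",
                               sum(cl$clusters$significant)))
  }

  # ---- connectivity -------------------------------------------------------
  if (cfg$stages$connect && !is.null(sessions[[1]]$rec_lat)) {
    cn <- cfg$connectivity
    maps_t <- list(); maps_d <- list()
    used <- logical(length(sessions))
    for (i in seq_along(sessions)) {
      s <- sessions[[i]]
      ev <- s$events[s$keep_trials, , drop = FALSE]
      # mirror the contact-selection step: only cortical contacts with a
      # significant trial-level condition difference in beta power feed
      # the group contrast (configurable off for sensitivity analysis)
      lat_names <- s$rec_lat$channels$name
      pick <- 1L
      if (isTRUE(cn$select_contacts)) {
        ba_by_contact <- lapply(lat_names, function(ch) {
          np <- session_normpower(s$rec_lat, ev, bank, ch,
                                  crop = cfg$spectral$crop,
                                  time_step = cfg$stats$time_step,
                                  baseline = cfg$spectral$baseline)
          ba <- band_average(np, cfg$stats$bands$beta)
          lapply(seq_len(nrow(ba$values)), function(j) ba$values[j, ])
        })
        names(ba_by_contact) <- lat_names
        pet <- per_electrode_tests(ba_by_contact, as.character(ev$condition),
                                   n_perm = cfg$stats$n_perm,
                                   seed = derive_seed(cfg$seed, "select", i))
        sig <- which(pet$testable & pet$sig_condition)
        if (!length(sig)) {
          stage_log("connect", sprintf(
            "session %d: no contact with a significant condition difference; excluded", i))
          next
        }
        pick <- sig[1]
      }
      used[i] <- TRUE
      stn_ch <- s$rec_pp$channels$name[s$rec_pp$channels$group == "stn"][1]
      ca <- epoch_tf(wavelet_transform_recording(s$rec_pp, bank, stn_ch), ev,
                     crop = cfg$spectral$crop)
      cb <- epoch_tf(wavelet_transform_recording(s$rec_lat, bank, pick), ev,
                     crop = cfg$spectral$crop)
      coh <- sliding_coherence(ca, cb, cn$window, cn$step)
      nc <- normalize_coherence(coh, cn$baseline)
      cm <- condition_means(nc, ev$condition[nc$trial_index])
      maps_t[[length(maps_t) + 1]] <- cm$target
      maps_d[[length(maps_d) + 1]] <- cm$distractor
      stage_log("connect", sprintf("session %d coherence done", i))
    }
    report$stages$connect <- if (length(maps_t) >= 2) {
      ccc <- coherence_condition_contrast(maps_t, maps_d,
                                          n_perm = cfg$stats$n_perm,
                                          seed = derive_seed(cfg$seed, "connect"))
      list(condition_clusters = ccc$clusters$clusters,
           n_sessions_used = sum(used))
    } else {
      stage_log("connect", "fewer than 2 usable sessions; contrast skipped")
      list(condition_clusters = NULL, n_sessions_used = sum(used))
    }
  }

  # ---- spiking ------------------------------------------------------------
  if (cfg$stages$spikes) {
    sp <- cfg$spiking
    zr <- list(); Rmat <- NULL
    for (i in seq_along(sessions)) {
      s <- sessions[[i]]
      macro <- names(s$recording$aux$beta_phase)[1]
      ph_cont <- wavelet_transform_recording(s$recording, bank, macro)
      ph_cont$coefs <- ph_cont$coefs # phase from raw synthetic channel
      ptf <- instantaneous_phase(epoch_tf(ph_cont, s$events,
                                          crop = c(sp$window[1], sp$window[2])))
      for (tr in s$spikes) {
        ts <- extract_trial_spikes(tr, s$events, window = sp$window,
                                   exclude_sd = sp$exclude_sd)
        cr <- continuous_rate(ts, sp$kernel_sd, sp$bin)
        nr <- normalize_rate(cr, keep = ts$keep)
        zr[[length(zr) + 1]] <- list(
          z = nr$z[nr$included, , drop = FALSE],
          condition = s$events$condition[nr$included],
          name = tr$cluster_id)
        spl <- spike_phase_locking(ts, ptf, window = sp$phase_window,
                                   n_surr = sp$n_surr,
                                   seed = derive_seed(cfg$seed, "spl", i, tr$cluster_id))
        Rmat <- rbind(Rmat, spl$R)
      }
    }
    rate_res <- cluster_rate_tests(zr, times = seq(sp$window[1] + sp$bin / 2,
                                                   sp$window[2], by = sp$bin),
                                   n_perm = cfg$stats$n_perm,
                                   seed = derive_seed(cfg$seed, "rates"),
                                   min_trials = sp$min_trials)
    popR <- population_R_test(Rmat, n_perm = cfg$stats$n_perm,
                              seed = derive_seed(cfg$seed, "popR"))
    report$stages$spikes <- list(
      per_cluster = rate_res$per_cluster,
      population_rate_clusters = rate_res$population$clusters$clusters,
      frac_sig_baseline = rate_res$frac_sig_baseline,
      population_R_clusters = popR$clusters$clusters,
      R_freqs = bank$frequencies)
    stage_log("spikes", sprintf("%d cluster(s) analysed", nrow(rate_res$per_cluster)))
  }

  report$wall_clock_s <- proc.time()[["elapsed"]] - t0
  rep_obj <- structure(report, class = "fp_report")
  if (!is.null(out)) {
    jsonlite::write_json(report_to_json(rep_obj), file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  rep_obj
}

report_to_json <- function(report) {
  rapply(unclass(report), function(x) x, how = "replace")
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' @export
print.fp_report <- function(x, ...) {
  cat("<fp_report>\n")
  cat(sprintf("  sessions: %d; wall clock: %.1f s\n",
              x$config$n_sessions, x$wall_clock_s))
  if (!is.null(x$stages$stats)) {
    cl <- x$stages$stats$vs_baseline_clusters
    cat(sprintf("  vs-baseline: %d cluster(s), %d significant\n",
                nrow(cl), sum(cl$significant)))
    bc <- x$stages$stats$beta_condition_clusters
    cat(sprintf("  beta condition contrast: %d cluster(s), %d significant\n",
                nrow(bc), sum(bc$significant)))
    cat(sprintf("  trial-number regression: mean rho = %.3f, p = %.3g\n",
                mean(x$stages$stats$trialnum_regression$rho, na.rm = TRUE),
                x$stages$stats$trialnum_regression$p))
  }
  if (!is.null(x$stages$connect))
    cat(sprintf("  coherence condition contrast: %d significant cluster(s)\n",
                sum(x$stages$connect$condition_clusters$significant)))
  if (!is.null(x$stages$spikes))
    cat(sprintf("  population R: %d significant frequency cluster(s)\n",
                sum(x$stages$spikes$population_R_clusters$significant)))
  invisible(x)
}
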