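# Trial-wise sliding-window cortico-subthalamic coupling: magnitude
# coherence from window-averaged cross/auto spectra, its percent-change
# baseline normalization, and its decomposition into phase synchrony (the
# amplitude-insensitive part) and across-trial power correlation.
#
# The denominator is the SQUARE ROOT of the product of the window-averaged
# autospectra: standard magnitude coherence, guaranteed to lie in [0, 1].

# shared window machinery over the time axis of two aligned complex tensors
sliding_cross_stat <- function(tfa, tfb, window, step, unit_normalize) {
  stopifnot(inherits(tfa, "fp_tf"), inherits(tfb, "fp_tf"),
            tfa$kind == "complex", tfb$kind == "complex",
            identical(dim(tfa$values), dim(tfb$values)),
            isTRUE(all.equal(tfa$times, tfb$times)))
  d <- dim(tfa$values)
  dt <- if (length(tfa$times) > 1) diff(tfa$times[1:2]) else 1
  w <- round(window / dt)
  if (w > d[3]) stop("window exceeds epoch span")
  stepn <- max(1L, round(step / dt))
  ntw <- d[3] - w + 1
  sel <- seq(1, ntw, by = stepn)
  # flatten (trial, freq) onto columns, time on rows
  flat <- function(x) matrix(aperm(x, c(3, 1, 2)), nrow = d[3])
  cross <- flat(tfa$values * Conj(tfb$values))
  if (unit_normalize) {
    mg <- Mod(cross)
    unit <- cross
    unit[mg > 0] <- cross[mg > 0] / mg[mg > 0]
    num <- Mod(running_mean(unit, w)$values)[sel, , drop = FALSE]
    out <- num
    centers <- running_mean(matrix(0, d[3], 1), w)$centers[sel]
  } else {
    rmc <- running_mean(cross, w)
    pa <- Re(running_mean(flat(Mod(tfa$values)^2), w)$values)
    pb <- Re(running_mean(flat(Mod(tfb$values)^2), w)$values)
    out <- Mod(rmc$values) / sqrt(pa * pb)
    out <- out[sel, , drop = FALSE]
    centers <- rmc$centers[sel]
  }
  out <- pmin(out, 1)
  vals <- aperm(array(out, c(length(sel), d[1], d[2])), c(2, 3, 1))
  list(values = vals, times = tfa$times[centers])
}

#' Sliding-window magnitude coherence between two channels
#'
#' Per trial, frequency, and window center:
#' `|<Wa conj(Wb)>_win| / sqrt(<|Wa|^2>_win <|Wb|^2>_win)`.
#'
#' @param tfa,tfb Complex `fp_tf` tensors sharing trial/frequency/time axes.
#' @param window Window length, ms (default 250).
#' @param step Step size, ms (default 1).
#' @return An `fp_tf` of kind `"coherence"`, values in \[0, 1\], time axis at
#'   the window centers.
#' @export
sliding_coherence <- function(tfa, tfb, window = 250, step = 1) {
  st <- sliding_cross_stat(tfa, tfb, window, step, unit_normalize = FALSE)
  tf_tensor(st$values, tfa$freqs, st$times, "coherence", tfa$trial_index)
}

#' Sliding-window phase synchrony between two channels
#'
#' Same windows as [sliding_coherence()], but on the unit-magnitude
#' cross-spectrum: `|<exp(i * dphi)>_win|` where `dphi` is the angle of the
#' cross-spectrum (the instantaneous phase difference). Amplitude
#' modulation cannot affect it.
#'
#' @inheritParams sliding_coherence
#' @return An `fp_tf` of kind `"phase_synchrony"`, values in \[0, 1\].
#' @export
phase_synchrony <- function(tfa, tfb, window = 250, step = 1) {
  st <- sliding_cross_stat(tfa, tfb, window, step, unit_normalize = TRUE)
  tf_tensor(st$values, tfa$freqs, st$times, "phase_synchrony", tfa$trial_index)
}

#' Percent-change baseline normalization of coherence (or phase synchrony)
#'
#' `100 * (C - Cbase) / Cbase` per frequency, with `Cbase` the mean over the
#' baseline window pooled across trials (one baseline per channel pair and
#' frequency).
#'
#' @param coh An `fp_tf` of kind `"coherence"` or `"phase_synchrony"`.
#' @param baseline Length-2 baseline window, ms.
#' @return An `fp_tf` of the same kind with `"norm_"` prefixed.
#' @export
normalize_coherence <- function(coh, baseline = c(-500, 0)) {
  stopifnot(inherits(coh, "fp_tf"),
            coh$kind %in% c("coherence", "phase_synchrony"))
  bsel <- coh$times >= baseline[1] & coh$times < baseline[2]
  if (!any(bsel)) stop("baseline window not covered by the window centers")
  base <- colMeans(apply(coh$values[, , bsel, drop = FALSE], 2, as.vector))
  if (length(base) == 1) base <- mean(coh$values[, 1, bsel])
  if (any(base == 0)) stop("zero baseline coherence")
  out <- 100 * (coh$values / array(rep(base, each = dim(coh$values)[1]),
                                   dim(coh$values)) - 1)
  tf_tensor(out, coh$freqs, coh$times, paste0("norm_", coh$kind),
            coh$trial_index)
}

#' Across-trial Spearman correlation of power between two channels
#'
#' Each trial's power time series is first smoothed with a `smooth` ms boxcar
#' (per frequency); at every frequency x time point the Spearman rank
#' correlation across trials between the two channels is computed.
#'
#' @param power_a,power_b `fp_tf` tensors of kind `"power"` (or
#'   `"normpower"`) with matching axes.
#' @param smooth Boxcar length, ms (default 250).
#' @return List with `rho` (frequencies x time matrix), `times`, `freqs`,
#'   `n_undefined` (points with zero across-trial variance, `NA` in `rho`).
#' @export
power_correlation <- function(power_a, power_b, smooth = 250) {
  stopifnot(inherits(power_a, "fp_tf"), inherits(power_b, "fp_tf"),
            identical(dim(power_a$values), dim(power_b$values)))
  d <- dim(power_a$values)
  if (d[1] < 10) stop("need >= 10 trials")
  dt <- if (length(power_a$times) > 1) diff(power_a$times[1:2]) else 1
  w <- max(1L, round(smooth / dt))
  sm <- function(x) {
    flatm <- matrix(aperm(x, c(3, 1, 2)), nrow = d[3])
    rm <- running_mean(flatm, w)
    list(v = aperm(array(rm$values, c(length(rm$centers), d[1], d[2])),
                   c(2, 3, 1)),
         centers = rm$centers)
  }
  sa <- sm(power_a$values)
  sb <- sm(power_b$values)
  ntw <- dim(sa$v)[3]
  rho <- matrix(NA_real_, d[2], ntw)
  for (k in seq_len(d[2])) {
    A <- sa$v[, k, , drop = TRUE]
    B <- sb$v[, k, , drop = TRUE]
    if (is.null(dim(A))) { A <- matrix(A, nrow = d[1]); B <- matrix(B, nrow = d[1]) }
    ra <- apply(A, 2, rank)
    rb <- apply(B, 2, rank)
    ra <- sweep(ra, 2, colMeans(ra))
    rb <- sweep(rb, 2, colMeans(rb))
    den <- sqrt(colSums(ra^2) * colSums(rb^2))
    num <- colSums(ra * rb)
    ok <- den > 0
    rho[k, ok] <- num[ok] / den[ok]
  }
  list(rho = rho, freqs = power_a$freqs, times = power_a$times[sa$centers],
       n_undefined = sum(is.na(rho)))
}

#' Session-level condition contrast of a coherence measure
#'
#' Delegates to the paired condition-label permutation with exceedance-mass
#' cluster correction: each session contributes its trial-averaged
#' normalized coherence (or phase synchrony / power correlation) map per
#' condition.
#'
#' @param maps_target,maps_distractor Lists of per-session frequency x time
#'   matrices.
#' @param n_perm,seed,threshold,alpha Permutation parameters.
#' @return `list(statmap, clusters)`.
#' @export
coherence_condition_contrast <- function(maps_target, maps_distractor,
                                         n_perm = 200, seed = NULL,
                                         threshold = 0.05, alpha = 0.05) {
  sm <- label_permutation_test(maps_target, maps_distractor, n_perm = n_perm,
                               seed = seed, paired = TRUE)
  list(statmap = sm, clusters = cluster_correct(sm, threshold, alpha))
}

#' Trial-average a tensor by condition
#'
#' Convenience used before session-level contrasts: averages a tensor's
#' trials within each condition.
#'
#' @param tf An `fp_tf` with numeric values.
#' @param conditions Per-trial condition labels aligned with
#'   `tf$trial_index`.
#' @return Named list of frequency x time matrices, one per condition level.
#' @export
condition_means <- function(tf, conditions) {
  conditions <- as.character(conditions)
  stopifnot(length(conditions) == dim(tf$values)[1])
  out <- lapply(unique(conditions), function(cc) {
    sel <- conditions == cc
    apply(tf$values[sel, , , drop = FALSE], c(2, 3), mean)
  })
  names(out) <- unique(conditions)
  out
}
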