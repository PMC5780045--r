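# Filtering, referencing, and epoching of continuous recordings.
#
# Filtering is zero-phase by construction: the transfer function is applied
# in the frequency domain (raised-cosine transition bands, spectral notch),
# so event latencies are never shifted. Downsampling is Fourier resampling,
# which handles non-integer rate ratios (e.g. 1502.4 Hz -> 1000 Hz) exactly.

# Zero-phase frequency response for a bandpass + notch, evaluated at freqs f.
bandpass_response <- function(f, low, high, notch, notch_halfwidth = 2,
                              trans_low = NULL, trans_high = NULL) {
  trans_low <- trans_low %||% max(low / 2, 0.25)
  trans_high <- trans_high %||% max(high * 0.1, 5)
  h <- rep(1, length(f))
  # highpass edge: 0 below low - trans_low, raised cosine up to low
  lo0 <- max(low - trans_low, 0)
  h[f <= lo0] <- 0
  ramp <- f > lo0 & f < low
  h[ramp] <- 0.5 * (1 - cos(pi * (f[ramp] - lo0) / (low - lo0)))
  # lowpass edge: 1 up to high, raised cosine down to high + trans_high
  hi1 <- high + trans_high
  h[f >= hi1] <- 0
  ramp <- f > high & f < hi1
  h[ramp] <- 0.5 * (1 + cos(pi * (f[ramp] - high) / trans_high))
  # notch: zero inside +/- notch_halfwidth with 1 Hz cosine tapers
  if (!is.null(notch) && notch > 0) {
    nz <- abs(f - notch) <= notch_halfwidth
    h[nz] <- 0
    tp <- abs(f - notch) > notch_halfwidth & abs(f - notch) < notch_halfwidth + 1
    h[tp] <- 0.5 * (1 - cos(pi * (abs(f[tp] - notch) - notch_halfwidth) / 1))
  }
  h
}

#' Bandpass filter, notch, and downsample a recording
#'
#' Zero-phase spectral filtering between `low` and `high` Hz with a notch at
#' the line frequency, followed by Fourier resampling to `target_fs`.
#'
#' @param rec An [recording()].
#' @param low,high Passband edges, Hz. `high` is clipped to `0.45 * fs` when
#'   the recording cannot support it.
#' @param notch Line frequency to remove, Hz (`NULL` to skip).
#' @param target_fs Output sampling rate, Hz; must not exceed the input rate.
#' @return A filtered [recording()] at `target_fs`.
#' @export
bandpass_notch_downsample <- function(rec, low = 1, high = 500, notch = 60,
                                      target_fs = 1000) {
  stopifnot(inherits(rec, "fp_recording"))
  if (target_fs > rec$fs) stop("target_fs exceeds recording rate (no upsampling)")
  # clip the upper edge below both the input and the output Nyquist
  high <- min(high, 0.45 * rec$fs, 0.45 * target_fs)
  n <- ncol(rec$data)
  f <- seq(0, n - 1) * rec$fs / n
  f <- pmin(f, rec$fs - f)
  h <- bandpass_response(f, low, high, notch)
  m <- round(n * target_fs / rec$fs)
  out <- matrix(0, nrow(rec$data), m)
  # Fourier resampling: keep the m lowest-frequency bins of the filtered
  # spectrum (filter bandwidth is below the new Nyquist already)
  half <- floor(m / 2)
  for (ci in seq_len(nrow(rec$data))) {
    X <- stats::fft(rec$data[ci, ]) * h
    Y <- complex(length.out = m)
    Y[1:(half + 1)] <- X[1:(half + 1)]
    Y[(m - half + 1):m] <- X[(n - half + 1):n]
    # 1/n (not 1/m): reconstructs the band-limited signal at the new rate
    # with unchanged amplitude
    out[ci, ] <- Re(stats::fft(Y, inverse = TRUE)) / n
  }
  recording(out, target_fs, rec$channels, aux = rec$aux)
}

#' Common-average re-referencing within a channel group
#'
#' Subtracts the instantaneous mean of the group from every channel in the
#' group (other channels untouched).
#'
#' @param rec An [recording()].
#' @param group Group label (matched against `channels$group`) or a character
#'   vector of channel names.
#' @return An [recording()] with the group re-referenced.
#' @export
rereference_common_average <- function(rec, group) {
  stopifnot(inherits(rec, "fp_recording"))
  idx <- if (length(group) == 1 && group %in% rec$channels$group) {
    which(rec$channels$group == group)
  } else chan_index(rec, group)
  if (length(idx) < 2) stop("common-average reference needs >= 2 channels")
  avg <- colMeans(rec$data[idx, , drop = FALSE])
  dat <- rec$data
  dat[idx, ] <- sweep(dat[idx, , drop = FALSE], 2, avg)
  recording(dat, rec$fs, rec$channels, aux = rec$aux)
}

#' Bipolar re-referencing along an ordered strip
#'
#' n contacts yield n - 1 bipolar channels; channel i is contact i minus
#' contact i + 1, named `"a-b"` after both parents.
#'
#' @param rec An [recording()].
#' @param strip Character vector of contact names in geometric order.
#' @return An [recording()] holding only the bipolar channels.
#' @export
rereference_bipolar <- function(rec, strip) {
  stopifnot(inherits(rec, "fp_recording"))
  if (length(strip) < 2) stop("strip needs >= 2 contacts")
  if (anyDuplicated(strip)) stop("duplicate contacts in strip")
  idx <- chan_index(rec, strip)
  k <- length(idx) - 1
  dat <- rec$data[idx[1:k], , drop = FALSE] - rec$data[idx[2:(k + 1)], , drop = FALSE]
  ch <- data.frame(name = paste0(strip[1:k], "-", strip[2:(k + 1)]),
                   role = rec$channels$role[idx[1:k]],
                   group = rec$channels$group[idx[1:k]])
  recording(dat, rec$fs, ch, aux = rec$aux)
}

#' Epoch a continuous recording around stimulus onsets
#'
#' Extracts `window` (default -250..1250 ms) around each onset plus `buffer`
#' ms of real data on both sides (retained through the spectral transform to
#' eliminate edge effects, then cropped). Half-open sample indexing at the
#' recording's resolution; the onset sample is t = 0.
#'
#' @param rec An [recording()].
#' @param events Event table.
#' @param window Length-2 analysis window, ms relative to onset.
#' @param buffer Buffer on each side, ms.
#' @return An object of class `fp_epochs`: `data` (trials x channels x
#'   samples), `times` (ms, includes buffers), `window`, `buffer`, `fs`,
#'   `trial_index`, `rejected`, `reject_reason`.
#' @export
epoch_recording <- function(rec, events, window = c(-250, 1250), buffer = 1000) {
  stopifnot(inherits(rec, "fp_recording"), window[1] < window[2], buffer >= 0)
  dt <- 1000 / rec$fs
  times <- seq(window[1] - buffer, window[2] + buffer - dt, by = dt)
  ns <- length(times)
  nt <- nrow(events)
  nc <- nrow(rec$data)
  dat <- array(0, c(nt, nc, ns))
  rejected <- logical(nt)
  reason <- character(nt)
  total <- ncol(rec$data)
  for (i in seq_len(nt)) {
    s0 <- round(events$onset[i] / dt) + 1 + round((window[1] - buffer) / dt)
    s1 <- s0 + ns - 1
    if (s0 < 1 || s1 > total) {
      rejected[i] <- TRUE
      reason[i] <- "out_of_bounds"
    } else {
      dat[i, , ] <- rec$data[, s0:s1, drop = FALSE]
    }
  }
  structure(list(data = dat, times = times, window = window, buffer = buffer,
                 fs = rec$fs, channels = rec$channels,
                 trial_index = seq_len(nt), events = events,
                 rejected = rejected, reject_reason = reason),
            class = "fp_epochs")
}

#' @export
print.fp_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fp_epochs> %d trials x %d channels x %d samples @ %g Hz; window (%g, %g) ms + %g ms buffers; %d rejected\n",
              d[1], d[2], d[3], x$fs, x$window[1], x$window[2], x$buffer,
              sum(x$rejected)))
  invisible(x)
}

#' Flag artifact trials by extreme peak amplitude
#'
#' A trial is flagged when, on any channel, its peak absolute amplitude lies
#' more than `z_thresh` robust standard deviations (MAD) above the median of
#' that channel's per-trial peak distribution. Flag only; data are retained.
#'
#' @param epochs An `fp_epochs`.
#' @param z_thresh Robust z threshold (default 6; `Inf` disables).
#' @return The epochs with updated `rejected` / `reject_reason`.
#' @export
reject_artifact_trials <- function(epochs, z_thresh = 6) {
  stopifnot(inherits(epochs, "fp_epochs"))
  d <- dim(epochs$data)
  if (d[1] < 2) stop("need >= 2 trials")
  if (!is.finite(z_thresh)) return(epochs)
  for (ci in seq_len(d[2])) {
    peaks <- apply(abs(epochs$data[, ci, , drop = FALSE]), 1, max)
    med <- stats::median(peaks)
    s <- stats::mad(peaks)
    if (s == 0) next
    bad <- (peaks - med) / s > z_thresh
    newly <- bad & !epochs$rejected
    epochs$rejected[newly] <- TRUE
    epochs$reject_reason[newly] <- "artifact"
  }
  epochs
}
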