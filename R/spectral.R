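# Morlet wavelet decomposition, power/phase extraction, percent-change
# baseline normalization, and band averaging.
#
# Morlet definition: complex exponential times a Gaussian with
# sigma_t = wavenumber / (2 pi f). Amplitude normalization is chosen so a
# unit sinusoid at a grid frequency yields unit peak coefficient magnitude.

#' Build a logarithmically spaced Morlet wavelet bank
#'
#' `f_k = fmin * 2^(k / scales_per_octave)`, k = 0..n-1. The defaults give 47
#' frequencies from 2 Hz to ~107.6 Hz at 8 scales per octave.
#'
#' @param fmin Lowest frequency, Hz.
#' @param scales_per_octave Grid density (consecutive ratio `2^(1/s)`).
#' @param n Number of frequencies.
#' @param wavenumber Wavelet width in cycles (default 6).
#' @return An object of class `fp_bank`.
#' @export
build_wavelet_bank <- function(fmin = 2, scales_per_octave = 8, n = 47,
                               wavenumber = 6) {
  stopifnot(fmin > 0, n >= 1, scales_per_octave > 0, wavenumber > 0)
  freqs <- fmin * 2^((seq_len(n) - 1) / scales_per_octave)
  structure(list(frequencies = freqs, wavenumber = wavenumber,
                 scales_per_octave = scales_per_octave, fmin = fmin,
                 fmax = freqs[n]),
            class = "fp_bank")
}

#' @export
print.fp_bank <- function(x, ...) {
  cat(sprintf("<fp_bank> %d wavelets, %.3g-%.4g Hz, %g scales/octave, wavenumber %g\n",
              length(x$frequencies), x$fmin, x$fmax, x$scales_per_octave,
              x$wavenumber))
  invisible(x)
}

# Sampled Morlet kernel at frequency f (complex, unit response to a unit
# sinusoid at f). Support +/- 4 sigma_t.
morlet_kernel <- function(f, fs, wavenumber) {
  sigma <- wavenumber / (2 * pi * f)
  half <- ceiling(4 * sigma * fs)
  t <- (-half:half) / fs
  amp <- 2 / (sigma * sqrt(2 * pi) * fs)
  amp * exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma^2))
}

# Kernel spectra are cached per (npad, fs, bank): calibration experiments
# transform thousands of equally sized sessions with one bank.
.fp_kernel_cache <- new.env(parent = emptyenv())

kernel_spectra <- function(npad, fs, freqs, wavenumber) {
  key <- paste(npad, fs, wavenumber, paste(signif(freqs, 10), collapse = ","),
               sep = "|")
  if (!is.null(.fp_kernel_cache[[key]])) return(.fp_kernel_cache[[key]])
  halves <- ceiling(4 * wavenumber / (2 * pi * freqs) * fs)
  Ks <- lapply(seq_along(freqs), function(k) {
    ker <- morlet_kernel(freqs[k], fs, wavenumber)
    h <- halves[k]
    kv <- complex(length.out = npad)
    kv[1:(h + 1)] <- ker[(h + 1):(2 * h + 1)]   # center + right half
    kv[(npad - h + 1):npad] <- ker[1:h]         # left half wrapped
    stats::fft(kv)
  })
  if (length(ls(.fp_kernel_cache)) > 8) # bound the cache
    rm(list = ls(.fp_kernel_cache)[1], envir = .fp_kernel_cache)
  assign(key, Ks, envir = .fp_kernel_cache)
  Ks
}

# Core convolution: complex coefficients for a samples x series matrix.
# Returns a list of samples x series complex matrices, one per frequency.
wavelet_convolve <- function(m, fs, freqs, wavenumber) {
  ns <- nrow(m)
  halves <- ceiling(4 * wavenumber / (2 * pi * freqs) * fs)
  npad <- stats::nextn(ns + 2 * max(halves), c(2, 3))
  M <- rbind(m, matrix(0, npad - ns, ncol(m)))
  FM <- stats::mvfft(M + 0i)
  Ks <- kernel_spectra(npad, fs, freqs, wavenumber)
  lapply(seq_along(freqs), function(k) {
    out <- stats::mvfft(FM * Ks[[k]], inverse = TRUE) / npad
    out[1:ns, , drop = FALSE]
  })
}

#' Morlet wavelet transform of an epoch set
#'
#' Convolution is computed over the buffered data; the buffers are then
#' cropped. The retained time axis defaults to (-500, 1250) ms so the 500 ms
#' pre-stimulus baseline is available to the normalization step.
#'
#' @param epochs An `fp_epochs` (with buffers).
#' @param bank An [build_wavelet_bank()] object.
#' @param channel Channel name or index to transform (one channel per call).
#' @param crop Length-2 retained window, ms; `NULL` keeps the buffered axis.
#' @param drop_rejected Drop trials flagged rejected (default TRUE).
#' @return An [tf_tensor()] of kind `"complex"`.
#' @export
wavelet_transform <- function(epochs, bank, channel = 1,
                              crop = c(-500, 1250), drop_rejected = TRUE) {
  stopifnot(inherits(epochs, "fp_epochs"), inherits(bank, "fp_bank"))
  if (max(bank$frequencies) > epochs$fs / 2)
    stop("bank frequency above Nyquist")
  ci <- if (is.character(channel)) match(channel, epochs$channels$name) else channel
  if (is.na(ci)) stop("unknown channel")
  keep <- if (drop_rejected) which(!epochs$rejected) else seq_len(dim(epochs$data)[1])
  m <- t(epochs$data[keep, ci, , drop = FALSE][, 1, ]) # samples x trials
  if (length(keep) == 1) m <- matrix(epochs$data[keep, ci, ], ncol = 1)
  coefs <- wavelet_convolve(m, epochs$fs, bank$frequencies, bank$wavenumber)
  times <- epochs$times
  tsel <- if (is.null(crop)) seq_along(times) else
    which(times >= crop[1] & times <= crop[2])
  vals <- array(0i, c(length(keep), length(bank$frequencies), length(tsel)))
  for (k in seq_along(coefs))
    vals[, k, ] <- t(coefs[[k]][tsel, , drop = FALSE])
  tf_tensor(vals, bank$frequencies, times[tsel], "complex", trial_index = keep)
}

#' Morlet wavelet transform of a continuous recording
#'
#' Fast path for long synthetic sessions: transforms the whole recording in
#' one FFT per frequency; combine with [epoch_tf()] to obtain the same
#' trial tensors as the epoch-then-transform route (the buffers are simply
#' the surrounding recording).
#'
#' @param rec An [recording()].
#' @param bank An [build_wavelet_bank()].
#' @param channel Channel name or index.
#' @return List with `coefs` (freqs x samples complex matrix), `freqs`,
#'   `times` (ms), `fs`.
#' @export
wavelet_transform_recording <- function(rec, bank, channel = 1) {
  stopifnot(inherits(rec, "fp_recording"), inherits(bank, "fp_bank"))
  if (max(bank$frequencies) > rec$fs / 2) stop("bank frequency above Nyquist")
  ci <- if (is.character(channel)) chan_index(rec, channel) else channel
  m <- matrix(rec$data[ci, ], ncol = 1)
  coefs <- wavelet_convolve(m, rec$fs, bank$frequencies, bank$wavenumber)
  cf <- do.call(rbind, lapply(coefs, function(x) x[, 1]))
  list(coefs = cf, freqs = bank$frequencies,
       times = (seq_len(ncol(cf)) - 1) * 1000 / rec$fs, fs = rec$fs)
}

#' Epoch continuous wavelet coefficients around stimulus onsets
#'
#' @param cont Output of [wavelet_transform_recording()].
#' @param events Event table.
#' @param crop Retained window, ms relative to onset.
#' @param time_step Optional decimation step, ms (e.g. 20 ms for permutation
#'   maps); `NULL` keeps the native resolution.
#' @return An [tf_tensor()] of kind `"complex"`; trials whose window falls
#'   outside the recording are dropped.
#' @export
epoch_tf <- function(cont, events, crop = c(-500, 1250), time_step = NULL) {
  dt <- 1000 / cont$fs
  step <- if (is.null(time_step)) 1L else max(1L, round(time_step / dt))
  rel <- seq(round(crop[1] / dt), round(crop[2] / dt), by = step)
  ntot <- ncol(cont$coefs)
  ok <- logical(nrow(events))
  rows <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    c0 <- round(events$onset[i] / dt) + 1
    idx <- c0 + rel
    if (idx[1] < 1 || idx[length(idx)] > ntot) next
    ok[i] <- TRUE
    rows[[i]] <- cont$coefs[, idx, drop = FALSE]
  }
  keep <- which(ok)
  vals <- array(0i, c(length(keep), length(cont$freqs), length(rel)))
  for (j in seq_along(keep)) vals[j, , ] <- rows[[keep[j]]]
  tf_tensor(vals, cont$freqs, rel * dt, "complex", trial_index = keep)
}

#' Instantaneous power from complex coefficients
#'
#' @param tf An `fp_tf` of kind `"complex"`.
#' @return An `fp_tf` of kind `"power"` (squared coefficient magnitude).
#' @export
tf_power <- function(tf) {
  stopifnot(inherits(tf, "fp_tf"), tf$kind == "complex")
  tf_tensor(Mod(tf$values)^2, tf$freqs, tf$times, "power", tf$trial_index)
}

#' Percent-change baseline normalization of power
#'
#' `100 * (P - Pbase) / Pbase` per frequency, where `Pbase` is the mean power
#' over the baseline window. By default the baseline is each trial's own
#' 500 ms pre-stimulus window; `per_trial = FALSE` pools the baseline across
#' trials (one value per frequency).
#'
#' @param power An `fp_tf` of kind `"power"`.
#' @param baseline Length-2 baseline window, ms.
#' @param per_trial Per-trial (default) or pooled baseline.
#' @return An `fp_tf` of kind `"normpower"`.
#' @export
normalize_to_baseline <- function(power, baseline = c(-500, 0),
                                  per_trial = TRUE) {
  stopifnot(inherits(power, "fp_tf"), power$kind == "power")
  bsel <- power$times >= baseline[1] & power$times < baseline[2]
  if (!any(bsel)) stop("baseline window outside epoch time axis")
  p <- power$values
  base <- apply(p[, , bsel, drop = FALSE], c(1, 2), mean)
  if (!per_trial) base <- matrix(colMeans(base), nrow(base), ncol(base), byrow = TRUE)
  if (any(base == 0)) stop("zero baseline power (degenerate input)")
  out <- 100 * (p / array(base, dim(p)) - 1)
  tf_tensor(out, power$freqs, power$times, "normpower", power$trial_index)
}

#' Average a tensor across a frequency band
#'
#' Unweighted mean across the grid frequencies lying inside `band`.
#'
#' @param tf An `fp_tf` (any numeric kind).
#' @param band Length-2 frequency interval, Hz.
#' @return List with `values` (trials x time matrix), `times`, `band`,
#'   `freqs_used`; class `fp_bandseries`.
#' @export
band_average <- function(tf, band) {
  stopifnot(inherits(tf, "fp_tf"), band[1] <= band[2])
  sel <- which(tf$freqs >= band[1] & tf$freqs <= band[2])
  if (!length(sel)) stop("band does not intersect the wavelet bank")
  v <- tf$values[, sel, , drop = FALSE]
  out <- apply(v, c(1, 3), mean)
  if (is.null(dim(out))) out <- matrix(out, nrow = dim(v)[1])
  structure(list(values = out, times = tf$times, band = band,
                 freqs_used = tf$freqs[sel], trial_index = tf$trial_index),
            class = "fp_bandseries")
}

#' Instantaneous phase from complex coefficients
#'
#' @param tf An `fp_tf` of kind `"complex"`.
#' @return An `fp_tf` of kind `"phase"`, values in (-pi, pi]. Samples with
#'   exactly zero magnitude are counted in attribute `"n_zero_magnitude"`
#'   (their angle is the angle of numerical zero, i.e. 0).
#' @export
instantaneous_phase <- function(tf) {
  stopifnot(inherits(tf, "fp_tf"), tf$kind == "complex")
  ph <- Arg(tf$values)
  out <- tf_tensor(ph, tf$freqs, tf$times, "phase", tf$trial_index)
  attr(out, "n_zero_magnitude") <- sum(Mod(tf$values) == 0)
  out
}
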