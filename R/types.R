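# Core containers. Deliberately lightweight S3: a recording is a channels x
# samples matrix plus metadata, an epoch set is a trials x channels x samples
# array, a time-frequency tensor is trials x frequencies x time. This mirrors
# how the field's toolboxes hold epoched data.

#' Construct a continuous multichannel recording
#'
#' @param data Numeric matrix, channels x samples (volts, arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param channels `data.frame` with columns `name`, `role`, `group`; one row
#'   per channel. Roles used by the pipeline: `"stn-macro"`, `"anterior-pfc"`,
#'   `"lateral-pfc"`, `"micro"`.
#' @param aux Optional list of generator ground-truth side information (for
#'   synthetic recordings: oscillator phases, per-trial physiological
#'   condition).
#' @return An object of class `fp_recording`.
#' @export
recording <- function(data, fs, channels, aux = NULL) {
  data <- as.matrix(data)
  stopifnot(is.numeric(fs), fs > 0, nrow(channels) == nrow(data))
  channels$name <- as.character(channels$name)
  if (anyDuplicated(channels$name)) stop("channel names must be unique")
  if (anyNA(data)) stop("recording contains NaN/NA samples")
  structure(list(data = data, fs = fs, channels = channels, aux = aux),
            class = "fp_recording")
}

#' @export
print.fp_recording <- function(x, ...) {
  cat(sprintf("<fp_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  roles:", paste(unique(x$channels$role), collapse = ", "), "\n")
  invisible(x)
}

# Number of samples / duration helpers
rec_duration_ms <- function(rec) ncol(rec$data) / rec$fs * 1000

chan_index <- function(rec, name) {
  i <- match(name, rec$channels$name)
  if (anyNA(i)) stop("unknown channel: ", paste(name[is.na(i)], collapse = ", "))
  i
}

#' Construct a time-frequency tensor
#'
#' @param values trials x frequencies x time array (complex or numeric).
#' @param freqs Frequencies in Hz.
#' @param times Time axis in ms relative to stimulus onset.
#' @param kind One of `"complex"`, `"power"`, `"normpower"`, `"phase"`,
#'   `"coherence"`, `"phase_synchrony"`.
#' @param trial_index Integer indices linking trials to event-table rows.
#' @return An object of class `fp_tf`.
#' @export
tf_tensor <- function(values, freqs, times, kind, trial_index = NULL) {
  stopifnot(length(dim(values)) == 3,
            dim(values)[2] == length(freqs),
            dim(values)[3] == length(times))
  structure(list(values = values, freqs = freqs, times = times, kind = kind,
                 trial_index = trial_index %||% seq_len(dim(values)[1])),
            class = "fp_tf")
}

#' @export
print.fp_tf <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<fp_tf:%s> %d trials x %d freqs (%.3g-%.3g Hz) x %d times (%g..%g ms)\n",
              x$kind, d[1], d[2], min(x$freqs), max(x$freqs), d[3],
              min(x$times), max(x$times)))
  invisible(x)
}

# Index of the time axis sample nearest to t (ms)
nearest_time <- function(times, t) {
  vapply(t, function(tt) which.min(abs(times - tt)), integer(1))
}

#' Construct a spike train
#'
#' @param spike_times Numeric vector of spike times in ms (absolute, sorted).
#' @param cluster_id Identifier of the neuronal cluster (one microelectrode
#'   recording, possibly multi-unit).
#' @param depth_pct Relative depth between the dorsal (0) and ventral (100)
#'   border of the STN, or `NA`.
#' @param paired_macro Name of the simultaneously recorded macro channel used
#'   for spike-phase analysis, or `NA`.
#' @param t_max Optional recording end time (ms), used to drop trials whose
#'   extraction window exceeds the recording.
#' @return An object of class `fp_spiketrain`.
#' @export
spike_train <- function(spike_times, cluster_id = "clu1", depth_pct = NA_real_,
                        paired_macro = NA_character_, t_max = NA_real_) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times)) spike_times <- sort(spike_times)
  if (length(spike_times) && spike_times[1] < 0)
    stop("spike times must be non-negative")
  if (!is.na(depth_pct) && (depth_pct < 0 || depth_pct > 100))
    stop("depth_pct must lie in [0, 100]")
  structure(list(spike_times = spike_times, cluster_id = cluster_id,
                 depth_pct = depth_pct, paired_macro = paired_macro,
                 t_max = t_max),
            class = "fp_spiketrain")
}

#' @export
print.fp_spiketrain <- function(x, ...) {
  cat(sprintf("<fp_spiketrain> %s: %d spikes", x$cluster_id, length(x$spike_times)))
  if (length(x$spike_times))
    cat(sprintf(" over %.1f s (%.1f sp/s)", diff(range(x$spike_times)) / 1000,
                length(x$spike_times) / diff(range(x$spike_times)) * 1000))
  cat("\n")
  invisible(x)
}
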