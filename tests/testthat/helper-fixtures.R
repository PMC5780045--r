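# Shared fixtures. Simulations in the test suite run at 250 Hz with a
# reduced 12-wavelet bank (6-40.4 Hz, 4 scales/octave) so the suite stays
# desk-scale; the full 47-wavelet configuration is exercised by the
# bank-exactness and spectral tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

small_bank <- function() build_wavelet_bank(6, 4, 12)

one_channel <- function() default_channels(1, 0, 0)

# one synthetic session: events + single STN channel recording
quick_session <- function(n_blocks = 10, truth = ground_truth(), fs = 250,
                          seed = 1, channels = one_channel(), ...) {
  ev <- generate_task_events(task_config(n_blocks = n_blocks, ...,
                                         seed = derive_seed(seed, "ev")))
  rec <- synthesize_lfp(ev, truth, channels, fs = fs,
                        seed = derive_seed(seed, "rec"))
  list(events = ev, recording = rec)
}

# sine-wave recording for filter / spectral identities
sine_recording <- function(freq, fs, dur_s = 10, amp = 1, dc = 0) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  recording(matrix(amp * cos(2 * pi * freq * t) + dc, 1), fs,
            data.frame(name = "a", role = "stn-macro", group = "stn"))
}

# complex tf tensors built directly (for connectivity identities)
fake_complex_tf <- function(values, freqs = 20, times = NULL) {
  d <- dim(values)
  times <- times %||% (seq_len(d[3]) - 1)
  tf_tensor(values, freqs, times, "complex")
}

# amplitude of a sinusoid at frequency f in a sampled signal
sine_amplitude <- function(x, f, fs) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  2 * Mod(mean(x * exp(-2i * pi * f * t)))
}
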