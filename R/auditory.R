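# Single-channel cochlear model and first-echo detector. The receiver chain
# is: 4th-order gammatone bandpass at the carrier -> half-wave rectification
# -> power-law compression (exponent 0.4) -> 1 kHz low-pass, yielding a
# smooth non-negative envelope. The earliest supra-threshold envelope peak
# in either ear dates the first echo; a fixed 1 ms window centered on it
# integrates per-ear onset energy (the level-difference cue), and the peak
# delay gives the nearest-obstacle distance estimate d_hat = c t / 2.

#' Cochlear model parameters
#'
#' @param center_frequency gammatone center frequency, Hz.
#' @param compression_exponent power-law compression applied to the
#'   rectified band signal, in (0, 1].
#' @param lowpass_cutoff envelope smoothing cutoff, Hz.
#' @param sample_rate Hz.
#' @param gammatone_order filter order; 4 is the standard auditory choice.
#' @return list of class `cochlear_params`.
#' @export
cochlear_params <- function(center_frequency = 40000,
                            compression_exponent = 0.4,
                            lowpass_cutoff = 1000,
                            sample_rate = 300000,
                            gammatone_order = 4) {
  stopifnot(compression_exponent > 0, compression_exponent <= 1,
            lowpass_cutoff < center_frequency, sample_rate > 0)
  structure(list(center_frequency = center_frequency,
                 compression_exponent = compression_exponent,
                 lowpass_cutoff = lowpass_cutoff,
                 sample_rate = sample_rate,
                 gammatone_order = gammatone_order),
            class = "cochlear_params")
}

# Equivalent rectangular bandwidth (Glasberg & Moore) at frequency f (Hz).
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

# Causal FIR gammatone kernel t^(n-1) exp(-2 pi b t) cos(2 pi f t),
# b = 1.019 ERB(f), truncated where its envelope has decayed to 1e-7 of the
# peak and normalized to unit gain at the center frequency.
gammatone_kernel <- function(params) {
  fs <- params$sample_rate
  f <- params$center_frequency
  n <- params$gammatone_order
  b <- 1.019 * erb_bandwidth(f)
  t <- seq(0, 0.005, by = 1 / fs)
  envl <- t^(n - 1) * exp(-2 * pi * b * t)
  keep <- seq_len(max(which(envl >= 1e-7 * max(envl))))
  t <- t[keep]
  g <- envl[keep] * cos(2 * pi * f * t)
  gain <- Mod(sum(g * exp(-2i * pi * f * (seq_along(g) - 1) / fs)))
  g / gain
}

butter_lowpass <- function(params) {
  key <- paste("butter", params$lowpass_cutoff, params$sample_rate, sep = "_")
  cache_get(key, function() {
    signal::butter(2, params$lowpass_cutoff / (params$sample_rate / 2), "low")
  })
}

#' Run a waveform through the cochlear model
#'
#' Gammatone bandpass at the center frequency, half-wave rectification,
#' power-law compression, then a causal (forward-only) 2nd-order Butterworth
#' low-pass, matching a real-time receiver. The output is a non-negative
#' envelope of the same length as the input.
#'
#' @param waveform numeric vector sampled at `params$sample_rate`.
#' @param params a [cochlear_params()].
#' @return non-negative envelope, same length as `waveform`.
#' @export
cochlear_model <- function(waveform, params = cochlear_params()) {
  n <- length(waveform)
  if (n == 0) return(numeric(0))
  key <- paste("gt", params$center_frequency, params$sample_rate,
               params$gammatone_order, sep = "_")
  kernel <- cache_get(key, function() gammatone_kernel(params))
  y <- fft_conv(waveform, kernel, key, n)
  y <- pmax(y, 0)^params$compression_exponent
  bf <- butter_lowpass(params)
  y <- as.numeric(signal::filter(bf, y))
  pmax(y, 0)
}

#' Subtract the emission's own envelope from a cochlear envelope
#'
#' The emitter's direct path dominates the start of every recording; its
#' known cochlear envelope (aligned to the call onset) is subtracted and the
#' residual clipped at zero over the emission window, so only echoes remain
#' for peak detection. Samples beyond the emission window are untouched.
#'
#' @param envelope cochlear envelope of the full recording.
#' @param emission_envelope cochlear envelope of the bare emission, aligned
#'   to the call onset; its length defines the emission window.
#' @return non-negative envelope, same length as `envelope`.
#' @export
remove_emission <- function(envelope, emission_envelope) {
  m <- min(length(envelope), length(emission_envelope))
  if (m > 0) {
    envelope[seq_len(m)] <- pmax(envelope[seq_len(m)] -
                                   emission_envelope[seq_len(m)], 0)
  }
  envelope
}

#' Cochlear envelope of the direct emission, for subtraction
#'
#' Helper producing the `emission_envelope` argument of [remove_emission()]:
#' the cochlear response to the bare burst at the given direct-path gain,
#' padded so the filter ringing is included in the emission window.
#'
#' @param emission an [emission_model()].
#' @param params a [cochlear_params()].
#' @param gain direct-path amplitude of the emission at each ear.
#' @param pad_samples extra samples of ringing to cover (default 2 ms).
#' @return non-negative envelope.
#' @export
emission_envelope_template <- function(emission = emission_model(),
                                       params = cochlear_params(),
                                       gain = 0.05,
                                       pad_samples = round(0.002 * params$sample_rate)) {
  pulse <- emitted_pulse(emission, params$sample_rate)
  cochlear_model(c(gain * pulse, numeric(pad_samples)), params)
}

# Indices of local maxima: strictly greater than the previous sample and at
# least equal to the next (plateau ties resolve to the earlier sample).
find_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

#' Detect the first echo and integrate its binaural onset energy
#'
#' Local maxima are located in each ear's envelope; the earliest peak
#' exceeding `threshold` in either ear is taken as the arrival of the first
#' echo. Both envelopes are then integrated over the same 1 ms window (300
#' samples at 300 kHz) starting 150 samples before that peak (truncated at
#' the array bounds), yielding the left/right onset energies. The peak delay
#' converts to the nearest-obstacle distance estimate `d_hat = c t / 2`.
#'
#' @param envelope_left,envelope_right cochlear envelopes (emission already
#'   removed), equal length.
#' @param threshold detection threshold in envelope units; see
#'   [detection_threshold()].
#' @param params a [cochlear_params()].
#' @param call_index optional call counter carried through to the reading.
#' @param speed_of_sound m/s.
#' @return object of class `sonar_reading`: list with `detected`,
#'   `first_echo_time` (s from emission onset), `d_hat` (m), `energy_left`,
#'   `energy_right`, `call_index`.
#' @export
detect_first_echo <- function(envelope_left, envelope_right, threshold,
                              params = cochlear_params(),
                              call_index = NA_integer_,
                              speed_of_sound = 343) {
  stopifnot(length(envelope_left) == length(envelope_right))
  fs <- params$sample_rate
  pl <- find_peaks(envelope_left)
  pr <- find_peaks(envelope_right)
  pl <- pl[envelope_left[pl] > threshold]
  pr <- pr[envelope_right[pr] > threshold]
  cand <- c(pl, pr)
  if (length(cand) == 0) {
    return(structure(list(detected = FALSE, first_echo_time = NA_real_,
                          d_hat = NA_real_, energy_left = 0, energy_right = 0,
                          call_index = call_index),
                     class = "sonar_reading"))
  }
  idx <- min(cand)
  t <- (idx - 1) / fs
  half <- 150L
  win_len <- 300L
  from <- max(1L, idx - half)
  to <- min(length(envelope_left), from + win_len - 1L)
  w <- from:to
  structure(list(detected = TRUE, first_echo_time = t,
                 d_hat = speed_of_sound * t / 2,
                 energy_left = sum(envelope_left[w]),
                 energy_right = sum(envelope_right[w]),
                 call_index = call_index),
            class = "sonar_reading")
}

#' Calibrate the echo-detection threshold from the noise floor
#'
#' The threshold defaults to `factor` times the RMS of the cochlear output
#' on a pure-noise calibration call at the configured receiver noise level
#' (a fixed internal calibration seed makes the value reproducible). When
#' the receiver is noiseless a tiny positive floor is returned so that
#' detection still requires a genuine peak.
#'
#' @param params a [cochlear_params()].
#' @param noise_rms receiver noise standard deviation.
#' @param factor multiple of the noise-floor RMS (default 10).
#' @param duration calibration call length, s.
#' @return threshold in envelope units.
#' @export
detection_threshold <- function(params = cochlear_params(), noise_rms = 1e-4,
                                factor = 10, duration = 0.035) {
  if (noise_rms <= 0) return(1e-12)
  key <- paste("thr", params$center_frequency, params$compression_exponent,
               params$lowpass_cutoff, params$sample_rate, noise_rms, factor,
               duration, sep = "_")
  cache_get(key, function() {
    s <- rng_stream(90210, "threshold-calibration")
    n <- round(duration * params$sample_rate)
    noise <- stream_draw(s, function() stats::rnorm(n, 0, noise_rms))
    y <- cochlear_model(noise, params)
    factor * sqrt(mean(y^2))
  })
}
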