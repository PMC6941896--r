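# Call synthesis: a 40 kHz tone burst shaped by a raised-cosine envelope is
# emitted through a circular-piston beam; every scatterer in the frontal
# hemisphere returns a delayed, attenuated copy into each ear. Ear gains are
# mirrored Gaussians in azimuth, giving a monotone interaural level
# difference over the frontal field; no interaural time difference is
# modeled (both ears sit at the robot center) because the controllers use
# level cues only.

#' Emission model parameters
#'
#' @param carrier_frequency carrier of the narrowband call, Hz.
#' @param effective_duration duration of the radiated burst, s. The 0.3 ms
#'   electrical excitation rings the transducer for about 1.5 ms; the model
#'   generates the radiated burst directly.
#' @param excitation_duration informational; the electrical drive duration, s.
#' @param source_level peak linear amplitude of the radiated burst.
#' @param emitter_diameter piston diameter, m; 10 mm matches piston fits to
#'   measured bat emission beams.
#' @return list of class `emission_model`.
#' @export
emission_model <- function(carrier_frequency = 40000,
                           effective_duration = 1.5e-3,
                           excitation_duration = 0.3e-3,
                           source_level = 1,
                           emitter_diameter = 0.010) {
  stopifnot(carrier_frequency > 0, effective_duration > 0,
            emitter_diameter > 0, source_level >= 0)
  structure(list(carrier_frequency = carrier_frequency,
                 effective_duration = effective_duration,
                 excitation_duration = excitation_duration,
                 source_level = source_level,
                 emitter_diameter = emitter_diameter),
            class = "emission_model")
}

#' Binaural gain model parameters
#'
#' Mirrored Gaussian approximation to a bat-like head-related transfer
#' function at the carrier frequency: the right ear peaks at `+peak_offset`
#' degrees azimuth, the left at `-peak_offset`, so a lateral reflector is
#' always louder in the ear on its own side.
#'
#' @param peak_offset azimuth of each ear's gain maximum, degrees.
#' @param beam_width_sigma Gaussian width of the gain lobe, degrees.
#' @param ear_separation informational, m; both ears are collocated
#'   acoustically (pure level-difference model).
#' @return list of class `binaural_gain_model`.
#' @export
binaural_gain_model <- function(peak_offset = 25, beam_width_sigma = 40,
                                ear_separation = 0.04) {
  stopifnot(peak_offset >= 0, beam_width_sigma > 0)
  structure(list(peak_offset = peak_offset,
                 beam_width_sigma = beam_width_sigma,
                 ear_separation = ear_separation),
            class = "binaural_gain_model")
}

#' Generate the emitted tone burst
#'
#' A `carrier_frequency` tone of `effective_duration`, shaped by a raised
#' cosine (Hann) envelope and scaled so the peak amplitude equals
#' `source_level`.
#'
#' @param model an [emission_model()].
#' @param sample_rate sampling rate, Hz; must be at least four times the
#'   carrier.
#' @return numeric waveform.
#' @export
emitted_pulse <- function(model = emission_model(), sample_rate = 300000) {
  if (sample_rate < 4 * model$carrier_frequency) {
    stop("emitted_pulse: sample_rate must be >= 4 x carrier_frequency")
  }
  n <- round(model$effective_duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  env <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  w <- env * sin(2 * pi * model$carrier_frequency * t)
  m <- max(abs(w))
  if (m > 0) w <- w / m * model$source_level
  w
}

#' Circular-piston emitter directivity
#'
#' Normalized far-field beam pattern `|2 J1(x)/x|` with
#' `x = k a sin(azimuth)`, `a` the piston radius and `k` the wavenumber at
#' the carrier. For a 10 mm piston at 40 kHz the first null lies beyond 90
#' degrees, so the gain decreases monotonically over the frontal hemisphere.
#'
#' @param azimuth angle(s) from the emission axis, degrees, |az| <= 90.
#' @param model an [emission_model()].
#' @param speed_of_sound m/s.
#' @return gain in (0, 1], 1 on-axis.
#' @export
emitter_directivity <- function(azimuth, model = emission_model(),
                                speed_of_sound = 343) {
  stopifnot(all(abs(azimuth) <= 90 + 1e-9))
  ka <- 2 * pi * model$carrier_frequency / speed_of_sound *
    (model$emitter_diameter / 2)
  x <- ka * sin(abs(deg2rad(azimuth)))
  g <- ifelse(x < 1e-8, 1, abs(2 * besselJ(x, 1) / x))
  g
}

#' Azimuth-dependent ear gain
#'
#' @param azimuth angle(s) relative to the gaze direction, degrees,
#'   CCW-positive (+ = left of the gaze in world convention, but note the
#'   right ear peaks at positive azimuth as seen from above with +azimuth
#'   toward the right ear's side; see Details).
#' @param side `"left"` or `"right"`.
#' @param model a [binaural_gain_model()].
#' @details Azimuth here is signed so that positive angles lie on the right
#'   ear's side of the midline: `gain(az, right) = gain(-az, left)`, the two
#'   gains are equal at the midline, and for azimuths in (0, 60] the right
#'   ear gain exceeds the left, giving the monotone level-difference cue the
#'   controllers rely on.
#' @return gain in (0, 1].
#' @export
ear_directivity <- function(azimuth, side = c("left", "right"),
                            model = binaural_gain_model()) {
  side <- match.arg(side)
  stopifnot(all(abs(azimuth) <= 180 + 1e-9))
  mu <- if (side == "right") model$peak_offset else -model$peak_offset
  exp(-((azimuth - mu)^2) / (2 * model$beam_width_sigma^2))
}

# Map world-frame azimuths (CCW-positive) to the ear convention used by
# ear_directivity: a reflector to the right of the gaze (negative CCW
# azimuth) must be louder in the right ear, so the ear-frame azimuth is the
# negated CCW gaze-relative angle.
ear_azimuth <- function(az_ccw) -az_ccw

#' Synthesize the binaural echo train for one call
#'
#' Every scatterer at range `r` and gaze-relative azimuth `az` inside the
#' frontal hemisphere contributes the emitted burst delayed by `2 r / c`,
#' scaled by its strength, the piston emitter gain, the per-ear gain,
#' two-way spherical spreading `r^-2`, and round-trip atmospheric absorption
#' `10^(-alpha 2 r / 20)`. Contributions superpose linearly; independent
#' Gaussian receiver noise is added per channel.
#'
#' @param position robot (emitter) position, length-2, inside the bounds.
#' @param gaze_direction world-frame gaze angle, degrees CCW.
#' @param env a `sonar_env`.
#' @param emission an [emission_model()].
#' @param ears a [binaural_gain_model()].
#' @param noise_rms receiver noise standard deviation (linear amplitude).
#' @param seed optional integer seed for the noise (ignored when `rng` is
#'   given); the same seed reproduces the noise exactly.
#' @param rng optional internal `rng_stream` (used by the simulator so noise
#'   draws come from the trial's named stream).
#' @param sample_rate receiver sampling rate, Hz.
#' @param speed_of_sound m/s.
#' @param absorption_db_per_m atmospheric absorption at the carrier, dB/m;
#'   set 0 to disable.
#' @param range_cap scatterers beyond this range are ignored, m; bounds the
#'   recording window (two-way travel plus the burst) well inside the 50 ms
#'   interpulse interval.
#' @param direct_emission_gain amplitude of the emitter's direct path into
#'   each ear (a copy of the burst at zero delay). Default 0: the recording
#'   contains echoes and noise only. The closed-loop simulator raises this so
#'   the emission-subtraction stage of the auditory pipeline is exercised.
#' @return object of class `binaural_recording`: list with `sample_rate`,
#'   `left`, `right`, `call_time`.
#' @export
synthesize_echoes <- function(position, gaze_direction, env,
                              emission = emission_model(),
                              ears = binaural_gain_model(),
                              noise_rms = 0, seed = NULL, rng = NULL,
                              sample_rate = 300000, speed_of_sound = 343,
                              absorption_db_per_m = 1.3, range_cap = 6,
                              direct_emission_gain = 0) {
  stopifnot(inherits(env, "sonar_env"), length(position) == 2)
  pulse <- emitted_pulse(emission, sample_rate)
  np <- length(pulse)
  n_total <- ceiling(2 * range_cap / speed_of_sound * sample_rate) + np

  trainL <- numeric(n_total)
  trainR <- numeric(n_total)
  sc <- env$scatterers
  if (nrow(sc) > 0) {
    dx <- sc$x - position[1]
    dy <- sc$y - position[2]
    r <- sqrt(dx * dx + dy * dy)
    az <- wrap180(rad2deg(atan2(dy, dx)) - gaze_direction)
    keep <- r > 1e-6 & r <= range_cap & abs(az) <= 90
    if (any(keep)) {
      r <- r[keep]
      az <- az[keep]
      amp <- sc$strength[keep] *
        emitter_directivity(az, emission, speed_of_sound) *
        r^-2 * 10^(-absorption_db_per_m * 2 * r / 20)
      aze <- ear_azimuth(az)
      ampL <- amp * ear_directivity(aze, "left", ears)
      ampR <- amp * ear_directivity(aze, "right", ears)
      ds <- 2 * r / speed_of_sound * sample_rate
      i0 <- floor(ds) + 1L
      frac <- ds - (i0 - 1L)
      idx <- c(i0, i0 + 1L)
      wl <- c(ampL * (1 - frac), ampL * frac)
      wr <- c(ampR * (1 - frac), ampR * frac)
      ok <- idx >= 1L & idx <= n_total
      aggL <- rowsum(wl[ok], idx[ok])
      aggR <- rowsum(wr[ok], idx[ok])
      ii <- as.integer(rownames(aggL))
      trainL[ii] <- trainL[ii] + aggL[, 1]
      trainR[ii] <- trainR[ii] + aggR[, 1]
    }
  }
  if (direct_emission_gain > 0) {
    trainL[1] <- trainL[1] + direct_emission_gain
    trainR[1] <- trainR[1] + direct_emission_gain
  }

  key <- paste("pulse", emission$carrier_frequency, emission$effective_duration,
               emission$source_level, sample_rate, sep = "_")
  left <- fft_conv(trainL, pulse, key, n_total)
  right <- fft_conv(trainR, pulse, key, n_total)

  if (noise_rms > 0) {
    draw <- function() stats::rnorm(2L * n_total, 0, noise_rms)
    noise <- if (!is.null(rng)) {
      stream_draw(rng, draw)
    } else if (!is.null(seed)) {
      s <- rng_stream(seed, "noise")
      stream_draw(s, draw)
    } else {
      draw()
    }
    left <- left + noise[seq_len(n_total)]
    right <- right + noise[n_total + seq_len(n_total)]
  }

  structure(list(sample_rate = sample_rate, left = left, right = right,
                 call_time = NA_real_),
            class = "binaural_recording")
}
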