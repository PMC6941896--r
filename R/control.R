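# Per-call steering laws. All three strategies share the same cue set (the
# first-echo distance estimate d_hat and the side of the louder ear) and the
# same sign convention: positive rotations are counterclockwise (left), and
# steering is always directed away from the louder ear.

#' Shared kinematic law endpoints
#'
#' All four laws are linear with clamping between their endpoints over the
#' distance range `[d_near, d_far]` (the printed curves give endpoints, not
#' breakpoints). With the 50 ms interpulse interval these choices imply head
#' rotation rates spanning 500-1000 deg/s and per-call displacements of
#' 5-15 cm.
#'
#' @param d_near,d_far distance clamps, m.
#' @param rotation_at_near,rotation_at_far per-call rotation magnitude at
#'   the near/far clamp, degrees.
#' @param speed_at_near,speed_at_far distance-law speeds, m/s.
#' @param speed_at_gaze0,speed_at_gaze45 gaze-law speeds at 0 and 45 degrees
#'   head angle, m/s.
#' @param ipi interpulse interval, s (the control cycle).
#' @return list of class `kinematic_laws`.
#' @export
kinematic_laws <- function(d_near = 0.3, d_far = 1.5,
                           rotation_at_near = 50, rotation_at_far = 25,
                           speed_at_near = 1, speed_at_far = 3,
                           speed_at_gaze0 = 3, speed_at_gaze45 = 1,
                           ipi = 0.05) {
  stopifnot(d_near < d_far, rotation_at_near >= rotation_at_far,
            rotation_at_far > 0, speed_at_near > 0, speed_at_far > 0,
            speed_at_gaze0 > 0, speed_at_gaze45 > 0, ipi > 0)
  structure(list(d_near = d_near, d_far = d_far,
                 rotation_at_near = rotation_at_near,
                 rotation_at_far = rotation_at_far,
                 speed_at_near = speed_at_near, speed_at_far = speed_at_far,
                 speed_at_gaze0 = speed_at_gaze0,
                 speed_at_gaze45 = speed_at_gaze45, ipi = ipi),
            class = "kinematic_laws")
}

#' Gaze-scanning (DLAL) controller parameters
#'
#' @param k delayed-law gain. By default (`gain_units = "per_second"`) `k`
#'   is a turning-rate gain in 1/s: the body turns toward where the head
#'   pointed a delay `tau` earlier at a rate proportional to that angle,
#'   giving `k * phi_tau * ipi` degrees per call. `gain_units = "per_call"`
#'   applies `k * phi_tau` degrees in a single call instead.
#' @param tau delay at which the past head angle is read, s.
#' @param head_limit head angle clamp, degrees.
#' @param gain_units `"per_second"` (default) or `"per_call"`; see `k`.
#' @param rate_clamp when `TRUE`, the per-call body rotation is limited to
#'   what the g-force bound allows at the commanded speed,
#'   `|delta_theta| <= Omega(v) * ipi` with [max_body_rotation_rate()];
#'   off by default (the delayed law itself is not rate-limited).
#' @param rate_clamp_G load-factor limit used by the clamp.
#' @param laws a [kinematic_laws()].
#' @return list of class `dlal_params`.
#' @export
dlal_params <- function(k = 10, tau = 0.05, head_limit = 90,
                        gain_units = c("per_second", "per_call"),
                        rate_clamp = FALSE, rate_clamp_G = 4,
                        laws = kinematic_laws()) {
  stopifnot(k > 0, tau > 0, head_limit > 0)
  structure(list(k = k, tau = tau, head_limit = head_limit,
                 gain_units = match.arg(gain_units),
                 rate_clamp = rate_clamp, rate_clamp_G = rate_clamp_G,
                 laws = laws),
            class = "dlal_params")
}

#' Random-walk baseline parameters
#'
#' @param speed fixed speed, m/s.
#' @param rotation_low,rotation_high per-call rotation magnitude bounds,
#'   degrees (the same range the steered strategies use).
#' @return list of class `random_walk_params`.
#' @export
random_walk_params <- function(speed = 2.0, rotation_low = 25,
                               rotation_high = 50) {
  stopifnot(0 < rotation_low, rotation_low < rotation_high, speed > 0)
  structure(list(speed = speed, rotation_low = rotation_low,
                 rotation_high = rotation_high),
            class = "random_walk_params")
}

control_command <- function(delta_theta, delta_phi, speed) {
  list(delta_theta = delta_theta, delta_phi = delta_phi, speed = speed)
}

#' Distance-dependent rotation magnitude
#'
#' Linear from `rotation_at_near` (at or below `d_near`) to
#' `rotation_at_far` (at or beyond `d_far`): closer obstacles command
#' sharper turns.
#'
#' @param d_hat nearest-obstacle distance estimate, m (>= 0).
#' @param laws a [kinematic_laws()].
#' @return rotation magnitude, degrees per call.
#' @export
rotation_magnitude <- function(d_hat, laws = kinematic_laws()) {
  stopifnot(all(d_hat >= 0))
  f <- clamp((d_hat - laws$d_near) / (laws$d_far - laws$d_near), 0, 1)
  laws$rotation_at_near + f * (laws$rotation_at_far - laws$rotation_at_near)
}

#' Distance-dependent speed (Fixed Head law)
#'
#' Linear from `speed_at_near` (at or below `d_near`) to `speed_at_far` (at
#' or beyond `d_far`): the robot slows down near obstacles.
#'
#' @inheritParams rotation_magnitude
#' @return speed, m/s.
#' @export
speed_from_distance <- function(d_hat, laws = kinematic_laws()) {
  stopifnot(all(d_hat >= 0))
  f <- clamp((d_hat - laws$d_near) / (laws$d_far - laws$d_near), 0, 1)
  laws$speed_at_near + f * (laws$speed_at_far - laws$speed_at_near)
}

#' Gaze-dependent speed (DLAL law)
#'
#' Even in the head angle: `speed_at_gaze0` when looking straight ahead,
#' falling linearly to `speed_at_gaze45` at 45 degrees and clamped there
#' beyond (a large gaze angle heralds a sharp turn, so the robot slows).
#'
#' @param phi head angle relative to the body, degrees, |phi| <= 90.
#' @param laws a [kinematic_laws()].
#' @return speed, m/s.
#' @export
speed_from_gaze <- function(phi, laws = kinematic_laws()) {
  stopifnot(all(abs(phi) <= 90 + 1e-9))
  f <- clamp(abs(phi) / 45, 0, 1)
  laws$speed_at_gaze0 + f * (laws$speed_at_gaze45 - laws$speed_at_gaze0)
}

# Turn direction away from the louder ear: left ear louder -> turn right
# (negative), right ear louder -> turn left (positive). Exact ties draw a
# fair sign from the trial's stream; a missed detection keeps the previous
# call's sign (straight-ish flight toward open space) and reads d_far.
steering_inputs <- function(reading, laws, rng = NULL, prev_sign = 1) {
  if (!isTRUE(reading$detected)) {
    return(list(d = laws$d_far, sign = prev_sign))
  }
  s <- if (reading$energy_left > reading$energy_right) {
    -1
  } else if (reading$energy_right > reading$energy_left) {
    +1
  } else if (!is.null(rng)) {
    stream_draw(rng, function() sample(c(-1, 1), 1))
  } else {
    sample(c(-1, 1), 1)
  }
  list(d = reading$d_hat, sign = s)
}

#' Update the head angle from one sonar reading (DLAL)
#'
#' The head rotates away from the louder ear by the distance-dependent
#' magnitude, clamped to the head limit.
#'
#' @param reading a `sonar_reading` from the current call.
#' @param current_phi current head angle, degrees (body-relative).
#' @param params a [dlal_params()].
#' @param rng optional `rng_stream` for the exact-tie coin flip.
#' @param prev_sign turn sign of the previous call, used when no echo was
#'   detected.
#' @return list with `phi` (new clamped head angle), `delta_phi` (realized
#'   rotation) and `sign` (the turn direction used).
#' @export
dlal_head_update <- function(reading, current_phi, params = dlal_params(),
                             rng = NULL, prev_sign = 1) {
  si <- steering_inputs(reading, params$laws, rng, prev_sign)
  mag <- rotation_magnitude(si$d, params$laws)
  phi <- clamp(current_phi + si$sign * mag, -params$head_limit,
               params$head_limit)
  list(phi = phi, delta_phi = phi - current_phi, sign = si$sign)
}

#' Delayed linear body rotation (DLAL)
#'
#' Reads the head angle a delay `tau` before `now` by linear interpolation
#' of the head history (0 when the history does not reach back that far)
#' and converts it to the per-call body rotation via the gain `k` (see
#' [dlal_params()] for the two gain unit conventions).
#'
#' @param history head history: data.frame with columns `time` (s, strictly
#'   increasing) and `phi` (degrees); see [head_history()].
#' @param now current call time, s.
#' @param params a [dlal_params()].
#' @param speed commanded speed this call, m/s; only used by the optional
#'   rate clamp.
#' @return body rotation for this call, degrees.
#' @export
dlal_body_update <- function(history, now, params = dlal_params(),
                             speed = NULL) {
  phi_tau <- interpolate_head_history(history, now - params$tau)
  dtheta <- params$k * phi_tau
  if (params$gain_units == "per_second") dtheta <- dtheta * params$laws$ipi
  if (isTRUE(params$rate_clamp) && !is.null(speed)) {
    lim <- rad2deg(max_body_rotation_rate(speed, params$rate_clamp_G)) *
      params$laws$ipi
    dtheta <- clamp(dtheta, -lim, lim)
  }
  dtheta
}

#' Create / extend a head-angle history
#'
#' @param time,phi numeric vectors of timestamps (s) and head angles
#'   (degrees).
#' @return data.frame with columns `time`, `phi`.
#' @export
head_history <- function(time = numeric(0), phi = numeric(0)) {
  stopifnot(length(time) == length(phi), !is.unsorted(time, strictly = TRUE))
  data.frame(time = time, phi = phi)
}

# phi at time t, linearly interpolated between samples; 0 before the first
# sample, last value after the last.
interpolate_head_history <- function(history, t) {
  n <- nrow(history)
  if (n == 0 || t < history$time[1]) return(0)
  if (t >= history$time[n]) return(history$phi[n])
  stats::approx(history$time, history$phi, xout = t)$y
}

#' One Fixed Head control step
#'
#' Gaze and drive direction coincide (`delta_phi` is always 0); the body
#' rotates away from the louder ear by the distance-dependent magnitude and
#' the speed follows the distance law.
#'
#' @inheritParams dlal_head_update
#' @param laws a [kinematic_laws()].
#' @return a control command: list with `delta_theta`, `delta_phi`, `speed`,
#'   plus the `sign` used.
#' @export
fixed_head_step <- function(reading, laws = kinematic_laws(), rng = NULL,
                            prev_sign = 1) {
  si <- steering_inputs(reading, laws, rng, prev_sign)
  cmd <- control_command(si$sign * rotation_magnitude(si$d, laws), 0,
                         speed_from_distance(si$d, laws))
  cmd$sign <- si$sign
  cmd
}

#' One Random Walk control step
#'
#' The body rotates by a magnitude drawn uniformly from the steered
#' strategies' rotation range with a fair random sign, at fixed speed.
#'
#' @param rng an `rng_stream` (seeded; same stream, same command sequence).
#' @param params a [random_walk_params()].
#' @return a control command.
#' @export
random_walk_step <- function(rng, params = random_walk_params()) {
  mag <- stream_draw(rng, function() stats::runif(1, params$rotation_low,
                                                  params$rotation_high))
  s <- stream_draw(rng, function() sample(c(-1, 1), 1))
  control_command(s * mag, 0, params$speed)
}

#' Maximum sustainable body rotation rate at a given speed
#'
#' The g-force bound on flight-path curvature: `Omega = G * 9.81 / v` rad/s,
#' with `G` the maximum tolerated load factor (4 across measured species).
#'
#' @param v speed, m/s (> 0).
#' @param G dimensionless load-factor limit.
#' @return maximum rotation rate, rad/s.
#' @export
max_body_rotation_rate <- function(v, G = 4) {
  if (any(v <= 0)) stop("max_body_rotation_rate: v must be > 0")
  G * 9.81 / v
}

#' Check the Fixed Head steering law against the turn-rate bound
#'
#' Over a grid of distances in `[d_near, d_far]`, compares the commanded
#' body rotation rate (`rotation_magnitude / ipi`) with the g-force bound at
#' the distance-law speed, both in degrees per second.
#'
#' @param laws a [kinematic_laws()].
#' @param G load-factor limit passed to [max_body_rotation_rate()].
#' @param n_grid grid resolution.
#' @return list with `pass` (logical), and the `d`, `commanded`, `limit`,
#'   `margin` curves (deg/s).
#' @export
feasibility_check <- function(laws = kinematic_laws(), G = 4, n_grid = 101) {
  d <- seq(laws$d_near, laws$d_far, length.out = n_grid)
  commanded <- rotation_magnitude(d, laws) / laws$ipi
  limit <- rad2deg(max_body_rotation_rate(speed_from_distance(d, laws), G))
  margin <- limit - commanded
  list(pass = all(margin >= 0), d = d, commanded = commanded, limit = limit,
       margin = margin)
}
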