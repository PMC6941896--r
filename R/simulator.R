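# Closed-loop trials. Each 50 ms control cycle: synthesize the binaural
# echo train at the current pose and gaze, run both channels through the
# cochlear model, subtract the emission, detect the first echo, hand the
# reading to the active strategy, and advance the unicycle kinematics.
# Collisions are checked at the midpoint and endpoint of every step so the
# robot cannot tunnel through thin poles.

#' Trial configuration
#'
#' @param strategy `"fixed_head"`, `"dlal"` or `"random_walk"`.
#' @param n_calls number of calls (control cycles); 600 calls at a 50 ms
#'   interpulse interval is 30 s of simulated flight.
#' @param ipi interpulse interval, s.
#' @param robot_radius robot body radius, m (a 28 x 33 cm platform
#'   approximated by a 16.5 cm disc).
#' @param seed master seed; all trial randomness (receiver noise, tie
#'   breaks, random-walk draws, initial pose) derives from it through named
#'   streams.
#' @param noise_rms receiver noise amplitude per channel.
#' @param initial_pose `"random"` (arena: uniform collision-free position
#'   and heading; corridor: centered at the entrance, heading along the axis
#'   with +/-10 degree jitter) or a list with `x`, `y`, `theta`.
#' @param emission an [emission_model()].
#' @param ears a [binaural_gain_model()].
#' @param cochlear a [cochlear_params()].
#' @param laws a [kinematic_laws()].
#' @param dlal a [dlal_params()]; its `laws` are forced to `laws`.
#' @param random_walk a [random_walk_params()].
#' @param threshold detection threshold; `NULL` calibrates it from the
#'   noise floor via [detection_threshold()].
#' @param direct_emission_gain direct-path emission amplitude at the ears
#'   (exercises the emission-subtraction stage).
#' @param speed_of_sound,absorption_db_per_m,range_cap acoustic constants,
#'   see [synthesize_echoes()].
#' @param turnaround_run corridor only: consecutive backward-heading calls
#'   that terminate the trial as `"turned_around"`.
#' @return list of class `trial_config`.
#' @export
trial_config <- function(strategy = c("fixed_head", "dlal", "random_walk"),
                         n_calls = 600, ipi = 0.05, robot_radius = 0.165,
                         seed = 1, noise_rms = 1e-4,
                         initial_pose = "random",
                         emission = emission_model(),
                         ears = binaural_gain_model(),
                         cochlear = cochlear_params(),
                         laws = kinematic_laws(ipi = ipi),
                         dlal = dlal_params(laws = laws),
                         random_walk = random_walk_params(),
                         threshold = NULL,
                         direct_emission_gain = 0.05,
                         speed_of_sound = 343,
                         absorption_db_per_m = 1.3,
                         range_cap = 6,
                         turnaround_run = 10) {
  strategy <- match.arg(strategy)
  stopifnot(n_calls > 0, robot_radius > 0, ipi > 0)
  dlal$laws <- laws
  structure(list(strategy = strategy, n_calls = as.integer(n_calls),
                 ipi = ipi, robot_radius = robot_radius,
                 seed = as.integer(seed), noise_rms = noise_rms,
                 initial_pose = initial_pose, emission = emission,
                 ears = ears, cochlear = cochlear, laws = laws, dlal = dlal,
                 random_walk = random_walk, threshold = threshold,
                 direct_emission_gain = direct_emission_gain,
                 speed_of_sound = speed_of_sound,
                 absorption_db_per_m = absorption_db_per_m,
                 range_cap = range_cap,
                 turnaround_run = as.integer(turnaround_run)),
            class = "trial_config")
}

#' Advance the unicycle kinematics by one control cycle
#'
#' The body rotation is applied first, the head rotation is clamped to
#' +/-90 degrees, and the robot then translates `speed * ipi` along the new
#' heading (discrete step at the call rate; no slip model).
#'
#' @param state list with `x`, `y`, `theta` (deg), `phi` (deg), `speed`.
#' @param cmd control command with `delta_theta`, `delta_phi`, `speed`.
#' @param ipi control cycle duration, s.
#' @return the new state.
#' @export
step_kinematics <- function(state, cmd, ipi = 0.05) {
  theta <- wrap180(state$theta + cmd$delta_theta)
  phi <- clamp(state$phi + cmd$delta_phi, -90, 90)
  step <- cmd$speed * ipi
  list(x = state$x + step * cos(deg2rad(theta)),
       y = state$y + step * sin(deg2rad(theta)),
       theta = theta, phi = phi, speed = cmd$speed)
}

sample_initial_pose <- function(env, config, rng) {
  if (is.list(config$initial_pose)) {
    p <- config$initial_pose
    st <- list(x = p$x, y = p$y, theta = p$theta, phi = 0, speed = 0)
    if (check_collision(c(st$x, st$y), config$robot_radius, env)$hit) {
      stop("run_trial: initial pose collides with the scene")
    }
    return(st)
  }
  if (env$kind == "corridor") {
    jit <- stream_draw(rng, function() stats::runif(1, -10, 10))
    return(list(x = 0, y = 0, theta = jit, phi = 0, speed = 0))
  }
  b <- env$bounds
  r <- config$robot_radius
  for (i in 1:2000) {
    p <- stream_draw(rng, function() c(
      stats::runif(1, b[1] + r, b[2] - r),
      stats::runif(1, b[3] + r, b[4] - r),
      stats::runif(1, -180, 180)
    ))
    if (nearest_obstacle_distance(p[1:2], env) >= r + 0.02) {
      return(list(x = p[1], y = p[2], theta = p[3], phi = 0, speed = 0))
    }
  }
  stop("run_trial: could not sample a collision-free initial pose")
}

axial_position <- function(env, x, y) {
  a <- env$corridor_axis
  x * a[1] + y * a[2]
}

#' Run one closed-loop trial
#'
#' Arena trials run for exactly `n_calls` calls; after a collision the event
#' is recorded, the robot is turned to face straight away from the contacted
#' surface (heading along the outward contact normal, center nudged to the
#' contact distance plus 1 cm) and the trial resumes -- the deterministic
#' analogue of lifting the robot off the obstacle. Corridor trials end at
#' the goal line (`"completed"`), on first contact (`"collision"`), when
#' the robot has been heading back toward the entrance for
#' `turnaround_run` consecutive calls (`"turned_around"`), or after
#' `n_calls` calls without any of these (`"ran_out_of_calls"`).
#'
#' @param env a `sonar_env`.
#' @param config a [trial_config()].
#' @return object of class `trial_result`: list with `trajectory` (one row
#'   per call: pose, gaze, command, reading, true nearest distance,
#'   collision flag), `collisions`, `termination`, `path_length` (m),
#'   `duration` (s), `n_calls_executed`, `strategy`, `seed`.
#' @export
run_trial <- function(env, config = trial_config()) {
  stopifnot(inherits(env, "sonar_env"), inherits(config, "trial_config"))
  fs <- config$cochlear$sample_rate

  rng_noise <- rng_stream(config$seed, "noise")
  rng_tie <- rng_stream(config$seed, "tiebreak")
  rng_walk <- rng_stream(config$seed, "walk")
  rng_init <- rng_stream(config$seed, "init")

  threshold <- config$threshold %||%
    detection_threshold(config$cochlear, config$noise_rms)
  template <- emission_envelope_template(config$emission, config$cochlear,
                                         gain = config$direct_emission_gain)

  state <- sample_initial_pose(env, config, rng_init)
  history <- head_history()
  prev_sign <- 1
  back_run <- 0L
  prev_axial <- if (env$kind == "corridor") {
    axial_position(env, state$x, state$y)
  } else {
    NA_real_
  }

  n <- config$n_calls
  traj <- data.frame(
    call = seq_len(n), t = (seq_len(n) - 1) * config$ipi,
    x = NA_real_, y = NA_real_, theta = NA_real_, phi = NA_real_,
    speed = NA_real_, delta_theta = NA_real_, delta_phi = NA_real_,
    d_hat = NA_real_, energy_left = NA_real_, energy_right = NA_real_,
    detected = NA, d_true = NA_real_, collision = FALSE
  )
  collisions <- list()
  termination <- "completed"
  executed <- 0L

  for (i in seq_len(n)) {
    now <- (i - 1) * config$ipi
    gaze <- state$theta + state$phi

    rec <- synthesize_echoes(
      c(state$x, state$y), gaze, env,
      emission = config$emission, ears = config$ears,
      noise_rms = config$noise_rms, rng = rng_noise, sample_rate = fs,
      speed_of_sound = config$speed_of_sound,
      absorption_db_per_m = config$absorption_db_per_m,
      range_cap = config$range_cap,
      direct_emission_gain = config$direct_emission_gain
    )
    el <- remove_emission(cochlear_model(rec$left, config$cochlear), template)
    er <- remove_emission(cochlear_model(rec$right, config$cochlear), template)
    reading <- detect_first_echo(el, er, threshold, config$cochlear,
                                 call_index = i,
                                 speed_of_sound = config$speed_of_sound)

    if (config$strategy == "fixed_head") {
      cmd <- fixed_head_step(reading, config$laws, rng_tie, prev_sign)
      prev_sign <- cmd$sign
    } else if (config$strategy == "dlal") {
      hu <- dlal_head_update(reading, state$phi, config$dlal, rng_tie,
                             prev_sign)
      prev_sign <- hu$sign
      history <- rbind(history, data.frame(time = now, phi = hu$phi))
      v <- speed_from_gaze(hu$phi, config$laws)
      cmd <- control_command(
        dlal_body_update(history, now, config$dlal, speed = v),
        hu$delta_phi, v)
    } else {
      cmd <- random_walk_step(rng_walk, config$random_walk)
    }

    traj$x[i] <- state$x
    traj$y[i] <- state$y
    traj$theta[i] <- state$theta
    traj$phi[i] <- state$phi
    traj$speed[i] <- cmd$speed
    traj$delta_theta[i] <- cmd$delta_theta
    traj$delta_phi[i] <- cmd$delta_phi
    traj$d_hat[i] <- reading$d_hat
    traj$energy_left[i] <- reading$energy_left
    traj$energy_right[i] <- reading$energy_right
    traj$detected[i] <- reading$detected
    traj$d_true[i] <- nearest_obstacle_distance(c(state$x, state$y), env)
    executed <- i

    new_state <- step_kinematics(state, cmd, config$ipi)
    mid <- c((state$x + new_state$x) / 2, (state$y + new_state$y) / 2)
    hit <- check_collision(mid, config$robot_radius, env)
    hit_at <- mid
    if (!hit$hit) {
      hit <- check_collision(c(new_state$x, new_state$y),
                             config$robot_radius, env)
      hit_at <- c(new_state$x, new_state$y)
    }

    if (hit$hit) {
      traj$collision[i] <- TRUE
      collisions[[length(collisions) + 1L]] <- data.frame(
        call = i, x = hit_at[1], y = hit_at[2], type = hit$type,
        index = hit$index
      )
      if (env$kind == "corridor") {
        state <- list(x = hit_at[1], y = hit_at[2], theta = new_state$theta,
                      phi = new_state$phi, speed = cmd$speed)
        termination <- "collision"
        break
      }
      # turn away and resume: face the outward normal, back off to contact
      # distance + 1 cm. The intervention restarts the sensorimotor loop:
      # the head is re-centered and the head history cleared, as lifting
      # and re-aiming the whole robot would do.
      n_out <- hit$normal
      pos <- hit$contact_point + n_out * (config$robot_radius + 0.01)
      state <- list(x = pos[1], y = pos[2],
                    theta = rad2deg(atan2(n_out[2], n_out[1])),
                    phi = 0, speed = cmd$speed)
      history <- head_history()
      prev_sign <- 1
    } else {
      state <- new_state
    }

    if (env$kind == "corridor") {
      ax <- axial_position(env, state$x, state$y)
      axis_deg <- rad2deg(atan2(env$corridor_axis[2], env$corridor_axis[1]))
      backward <- cos(deg2rad(state$theta - axis_deg)) < 0 && ax < prev_axial
      back_run <- if (backward) back_run + 1L else 0L
      prev_axial <- ax
      if (ax >= env$goal_line) {
        termination <- "completed"
        break
      }
      if (back_run >= config$turnaround_run) {
        termination <- "turned_around"
        break
      }
      if (i == n) termination <- "ran_out_of_calls"
    }
  }

  traj <- traj[seq_len(executed), , drop = FALSE]
  seg <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  tail_step <- sqrt((state$x - traj$x[executed])^2 +
                    (state$y - traj$y[executed])^2)

  structure(list(
    trajectory = traj,
    collisions = if (length(collisions)) do.call(rbind, collisions) else
      data.frame(call = integer(0), x = numeric(0), y = numeric(0),
                 type = character(0), index = integer(0)),
    termination = termination,
    path_length = sum(seg) + tail_step,
    duration = executed * config$ipi,
    n_calls_executed = executed,
    strategy = config$strategy,
    seed = config$seed,
    final_state = state
  ), class = "trial_result")
}

#' Detect a corridor turn-around in a finished trajectory
#'
#' True when the heading's component along the corridor axis is negative for
#' `run_length` consecutive calls while the axial position decreases over
#' the same run.
#'
#' @param trajectory a `trial_result$trajectory` data.frame (needs `x`, `y`,
#'   `theta`).
#' @param env a corridor `sonar_env`.
#' @param run_length consecutive backward calls required.
#' @return logical flag.
#' @export
detect_turnaround <- function(trajectory, env, run_length = 10) {
  if (!inherits(env, "sonar_env") || env$kind != "corridor") {
    stop("detect_turnaround: corridor environment required")
  }
  n <- nrow(trajectory)
  if (n < 2) return(FALSE)
  axis_deg <- rad2deg(atan2(env$corridor_axis[2], env$corridor_axis[1]))
  ax <- axial_position(env, trajectory$x, trajectory$y)
  backward <- cos(deg2rad(trajectory$theta - axis_deg)) < 0
  flag <- backward[-1] & (diff(ax) < 0)
  r <- rle(flag)
  any(r$values & r$lengths >= run_length)
}

#' Run a batch of independent trials
#'
#' Trial `i` uses seed `base_seed + i` and a freshly sampled initial pose;
#' the environment is either fixed (a `sonar_env`, as when one physical
#' setup hosts all trials) or rebuilt per trial from a factory
#' `function(seed)`.
#'
#' @param env a `sonar_env`, or a function of one integer seed returning one.
#' @param strategy passed to [trial_config()].
#' @param n_trials number of trials.
#' @param base_seed integer; trial seeds are `base_seed + 1 .. base_seed +
#'   n_trials`.
#' @param config optional [trial_config()] template; its `strategy` and
#'   `seed` are overridden per trial.
#' @return list of class `experiment_result` (one `trial_result` per trial).
#' @export
run_experiment <- function(env, strategy, n_trials, base_seed,
                           config = NULL) {
  stopifnot(n_trials > 0)
  if (is.null(config)) config <- trial_config(strategy = strategy)
  config$strategy <- match.arg(strategy,
                               c("fixed_head", "dlal", "random_walk"))
  results <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i)
    env_i <- if (is.function(env)) env(cfg$seed) else env
    results[[i]] <- run_trial(env_i, cfg)
  }
  structure(results, class = "experiment_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("<trial_result> ", x$strategy, ", seed ", x$seed, ": ",
      x$n_calls_executed, " calls, ", nrow(x$collisions), " collisions, ",
      sprintf("%.1f m in %.1f s", x$path_length, x$duration),
      ", termination: ", x$termination, "\n", sep = "")
  invisible(x)
}
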