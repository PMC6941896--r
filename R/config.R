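# Flat YAML run configuration mirroring the type defaults, plus the output
# writers used by the command-line runner: per-trial trajectory CSV, an
# experiment summary JSON and the resolved configuration next to them.

#' Default run configuration
#'
#' A flat named list mirroring every tunable default of the environment,
#' acoustics, auditory and control types; [read_config()] merges a user
#' YAML file over it.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    env = "arena", strategy = "fixed_head", trials = 10, calls = 600,
    seed = 1, ipi = 0.05, robot_radius = 0.165, noise_rms = 1e-4,
    n_obstacles = 11, arena_width = 3, arena_length = 4,
    corridor_width = 0.9, corridor_length = 3,
    obstacle_strength = 0.25, wall_strength = 0.15, strength_sdlog = 0.5,
    scatterers_per_obstacle = 20, wall_spacing = 0.03, wall_jitter = 0.02,
    carrier_frequency = 40000, effective_duration = 1.5e-3, source_level = 1,
    emitter_diameter = 0.010, ear_peak_offset = 25, ear_sigma = 40,
    sample_rate = 300000, compression_exponent = 0.4, lowpass_cutoff = 1000,
    speed_of_sound = 343, absorption_db_per_m = 1.3, range_cap = 6,
    direct_emission_gain = 0.05,
    d_near = 0.3, d_far = 1.5, rotation_at_near = 50, rotation_at_far = 25,
    speed_at_near = 1, speed_at_far = 3, speed_at_gaze0 = 3,
    speed_at_gaze45 = 1, dlal_k = 10, dlal_tau = 0.05, head_limit = 90,
    dlal_gain_units = "per_second", walk_speed = 2, rotation_low = 25,
    rotation_high = 50, turnaround_run = 10
  )
}

#' Read a YAML run configuration
#'
#' @param path YAML file; keys override [default_config()].
#' @return resolved named list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    warning("read_config: ignoring unknown keys: ",
            paste(unknown, collapse = ", "))
  }
  cfg[intersect(names(user), names(cfg))] <-
    user[intersect(names(user), names(cfg))]
  cfg
}

#' Write a resolved configuration as YAML
#'
#' @param config named list (as from [default_config()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Build the environment and trial_config a flat config describes.
config_objects <- function(cfg) {
  laws <- kinematic_laws(
    d_near = cfg$d_near, d_far = cfg$d_far,
    rotation_at_near = cfg$rotation_at_near,
    rotation_at_far = cfg$rotation_at_far,
    speed_at_near = cfg$speed_at_near, speed_at_far = cfg$speed_at_far,
    speed_at_gaze0 = cfg$speed_at_gaze0,
    speed_at_gaze45 = cfg$speed_at_gaze45, ipi = cfg$ipi
  )
  tc <- trial_config(
    strategy = cfg$strategy, n_calls = cfg$calls, ipi = cfg$ipi,
    robot_radius = cfg$robot_radius, seed = cfg$seed,
    noise_rms = cfg$noise_rms,
    emission = emission_model(carrier_frequency = cfg$carrier_frequency,
                              effective_duration = cfg$effective_duration,
                              source_level = cfg$source_level,
                              emitter_diameter = cfg$emitter_diameter),
    ears = binaural_gain_model(peak_offset = cfg$ear_peak_offset,
                               beam_width_sigma = cfg$ear_sigma),
    cochlear = cochlear_params(center_frequency = cfg$carrier_frequency,
                               compression_exponent = cfg$compression_exponent,
                               lowpass_cutoff = cfg$lowpass_cutoff,
                               sample_rate = cfg$sample_rate),
    laws = laws,
    dlal = dlal_params(k = cfg$dlal_k, tau = cfg$dlal_tau,
                       head_limit = cfg$head_limit,
                       gain_units = cfg$dlal_gain_units, laws = laws),
    random_walk = random_walk_params(speed = cfg$walk_speed,
                                     rotation_low = cfg$rotation_low,
                                     rotation_high = cfg$rotation_high),
    direct_emission_gain = cfg$direct_emission_gain,
    speed_of_sound = cfg$speed_of_sound,
    absorption_db_per_m = cfg$absorption_db_per_m,
    range_cap = cfg$range_cap, turnaround_run = cfg$turnaround_run
  )
  env <- if (cfg$env == "arena") {
    make_arena(cfg$seed, n_obstacles = cfg$n_obstacles,
               width = cfg$arena_width, length = cfg$arena_length,
               obstacle_strength = cfg$obstacle_strength,
               wall_strength = cfg$wall_strength,
               strength_sdlog = cfg$strength_sdlog,
               scatterers_per_obstacle = cfg$scatterers_per_obstacle,
               wall_spacing = cfg$wall_spacing, wall_jitter = cfg$wall_jitter)
  } else {
    make_corridor(cfg$seed, width = cfg$corridor_width,
                  length = cfg$corridor_length,
                  robot_radius = cfg$robot_radius,
                  wall_strength = cfg$wall_strength,
                  strength_sdlog = cfg$strength_sdlog,
                  wall_spacing = cfg$wall_spacing,
                  wall_jitter = cfg$wall_jitter)
  }
  list(env = env, trial_config = tc)
}

#' Write a trial's per-call log as CSV
#'
#' @param result a `trial_result`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_trial_csv <- function(result, path) {
  utils::write.csv(result$trajectory, path, row.names = FALSE)
  invisible(path)
}

#' Run a configured experiment and write its outputs
#'
#' Runs `trials` seeded trials of the configured strategy in the configured
#' environment, then writes per-trial trajectory CSVs, an experiment summary
#' JSON (collision rates, terminations) and the resolved configuration YAML
#' into `out_dir`.
#'
#' @param cfg flat config list (see [default_config()] / [read_config()]).
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @return the `experiment_result`, invisibly with attribute `summary`.
#' @export
run_configured_experiment <- function(cfg, out_dir = NULL) {
  obj <- config_objects(cfg)
  results <- run_experiment(obj$env, cfg$strategy, cfg$trials, cfg$seed,
                            config = obj$trial_config)
  rates <- collision_rates(results)
  summary <- list(
    strategy = cfg$strategy, env = cfg$env, trials = cfg$trials,
    seed = cfg$seed,
    collisions = rates$n_collisions,
    collisions_per_second = rates$per_second,
    collisions_per_meter = rates$per_meter,
    total_path_m = rates$total_path, total_duration_s = rates$total_duration,
    terminations = as.list(table(vapply(results, function(r) r$termination,
                                        character(1))))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(results)) {
      write_trial_csv(results[[i]],
                      file.path(out_dir, sprintf("trial_%02d.csv", i)))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_config(cfg, file.path(out_dir, "config.yaml"))
    env_to_json(obj$env, file.path(out_dir, "environment.json"))
  }
  attr(results, "summary") <- summary
  invisible(results)
}
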