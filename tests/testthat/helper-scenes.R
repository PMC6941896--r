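# Programmatic fixtures: minimal scenes built in code.

# An unbounded scene holding explicit point scatterers (no walls, no
# collision geometry) -- the cleanest probe of the acoustic chain.
scene_with_scatterers <- function(x, y, strength) {
  echosteer:::new_environment(
    kind = "arena",
    walls = data.frame(x1 = numeric(0), y1 = numeric(0),
                       x2 = numeric(0), y2 = numeric(0)),
    obstacles = data.frame(x = numeric(0), y = numeric(0),
                           collision_radius = numeric(0),
                           scatter_radius = numeric(0)),
    scatterers = data.frame(x = x, y = y, strength = strength,
                            parent_type = rep("obstacle", length(x)),
                            parent_index = seq_along(x)),
    bounds = c(-10, 10, -10, 10)
  )
}

# One reflector of unit strength at range r, at `az_right` degrees toward
# the robot's right (clockwise from gaze direction 0).
lone_reflector_scene <- function(r, az_right = 0) {
  scene_with_scatterers(r * cos(-az_right * pi / 180),
                        r * sin(-az_right * pi / 180), 1)
}

# Full auditory pipeline for one call at the origin, gaze along +x.
sense_scene <- function(scene, noise_rms = 1e-4, seed = 7,
                        direct_gain = 0.05, cp = cochlear_params()) {
  rec <- synthesize_echoes(c(0, 0), 0, scene, noise_rms = noise_rms,
                           seed = seed, direct_emission_gain = direct_gain)
  tmpl <- emission_envelope_template(gain = direct_gain, params = cp)
  el <- remove_emission(cochlear_model(rec$left, cp), tmpl)
  er <- remove_emission(cochlear_model(rec$right, cp), tmpl)
  detect_first_echo(el, er, detection_threshold(cp, noise_rms), cp)
}

# A sonar_reading literal for control-law tests.
fake_reading <- function(d_hat, energy_left, energy_right, detected = TRUE) {
  structure(list(detected = detected, first_echo_time = 2 * d_hat / 343,
                 d_hat = d_hat, energy_left = energy_left,
                 energy_right = energy_right, call_index = 1L),
            class = "sonar_reading")
}
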