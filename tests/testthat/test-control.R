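laws <- kinematic_laws()

test_that("rotation and speed laws hit their printed endpoints", {
  expect_equal(rotation_magnitude(0.1, laws), 50)
  expect_equal(rotation_magnitude(0.3, laws), 50)
  expect_equal(rotation_magnitude(3.0, laws), 25)
  expect_equal(rotation_magnitude((0.3 + 1.5) / 2, laws), 37.5)
  d <- seq(0, 3, by = 0.05)
  expect_true(all(diff(rotation_magnitude(d, laws)) <= 1e-12))

  expect_equal(speed_from_distance(0.2, laws), 1)
  expect_equal(speed_from_distance(2.0, laws), 3)
  expect_true(all(diff(speed_from_distance(d, laws)) >= -1e-12))

  expect_equal(speed_from_gaze(0, laws), 3)
  expect_equal(speed_from_gaze(45, laws), 1)
  expect_equal(speed_from_gaze(-45, laws), 1)
  expect_equal(speed_from_gaze(22.5, laws), 2)
  expect_equal(speed_from_gaze(80, laws), 1)  # clamped beyond 45 degrees
  expect_equal(speed_from_gaze(30, laws), speed_from_gaze(-30, laws))
})

test_that("per-call displacement spans 5-15 cm across the speed range", {
  d <- seq(0, 3, by = 0.05)
  disp <- speed_from_distance(d, laws) * laws$ipi
  expect_true(all(disp >= 0.05 - 1e-12 & disp <= 0.15 + 1e-12))
  disp_g <- speed_from_gaze(seq(-90, 90, by = 5), laws) * laws$ipi
  expect_true(all(disp_g >= 0.05 - 1e-12 & disp_g <= 0.15 + 1e-12))
})

test_that("head rotation rates span 500-1000 deg/s under defaults", {
  d <- seq(0, 3, by = 0.01)
  rates <- rotation_magnitude(d, laws) / laws$ipi
  expect_equal(range(rates), c(500, 1000))
})

test_that("the head turns away from the louder ear and clamps at 90", {
  p <- dlal_params()
  # left louder, close obstacle: full -50 from zero
  up <- dlal_head_update(fake_reading(0.1, 2, 1), 0, p)
  expect_equal(up$phi, -50)
  expect_equal(up$sign, -1)
  # right louder: positive (leftward) rotation
  up2 <- dlal_head_update(fake_reading(0.1, 1, 2), 0, p)
  expect_equal(up2$phi, 50)
  # clamp at the +/-90 head limit
  up3 <- dlal_head_update(fake_reading(0.1, 1, 2), 80, p)
  expect_equal(up3$phi, 90)
  expect_equal(up3$delta_phi, 10)
})

test_that("exact energy ties break by a reproducible fair coin", {
  p <- dlal_params()
  draws <- function(seed) {
    rng <- echosteer:::rng_stream(seed, "tiebreak")
    vapply(1:40, function(i) {
      dlal_head_update(fake_reading(1, 1, 1), 0, p, rng = rng)$sign
    }, numeric(1))
  }
  a <- draws(3)
  expect_identical(a, draws(3))
  expect_true(all(a %in% c(-1, 1)))
  expect_true(any(a == 1) && any(a == -1))
})

test_that("missed detections keep the previous turn direction at d_far", {
  nd <- fake_reading(NA, 0, 0, detected = FALSE)
  cmd <- fixed_head_step(nd, laws, prev_sign = -1)
  expect_equal(cmd$delta_theta, -rotation_magnitude(laws$d_far, laws))
  expect_equal(cmd$speed, speed_from_distance(laws$d_far, laws))
})

test_that("delayed body law interpolates the head history", {
  p_rate <- dlal_params(gain_units = "per_second")
  p_call <- dlal_params(gain_units = "per_call")
  now <- 1.0
  h <- head_history(time = c(now - 0.060, now - 0.040), phi = c(10, 20))
  # phi at now - tau interpolates to 15 degrees
  expect_equal(echosteer:::interpolate_head_history(h, now - 0.05), 15)
  # literal per-call gain: k * phi_tau
  expect_equal(dlal_body_update(h, now, p_call), 150)
  # turning-rate default: k * phi_tau * ipi
  expect_equal(dlal_body_update(h, now, p_rate), 150 * 0.05)
  expect_equal(dlal_body_update(h, now, dlal_params()), 150 * 0.05)
  # optional g-force rate clamp bounds the per-call rotation
  p_cl <- dlal_params(gain_units = "per_call", rate_clamp = TRUE)
  lim <- (4 * 9.81 / 3) * 180 / pi * 0.05
  expect_equal(dlal_body_update(h, now, p_cl, speed = 3), lim)
  # constant zero head: no body rotation
  h0 <- head_history(time = c(0.90, 0.95), phi = c(0, 0))
  expect_equal(dlal_body_update(h0, now, p_rate), 0)
  # empty or too-short history reads phi_tau = 0
  expect_equal(dlal_body_update(head_history(), now, p_rate), 0)
  expect_equal(dlal_body_update(head_history(0.99, 40), now, p_rate), 0)
})

test_that("fixed-head commands follow the distance laws with zero gaze", {
  cmd <- fixed_head_step(fake_reading(0.1, 2, 1), laws)
  expect_equal(cmd$delta_theta, -50)
  expect_equal(cmd$speed, 1)
  expect_equal(cmd$delta_phi, 0)
  cmd2 <- fixed_head_step(fake_reading(2.5, 1, 2), laws)
  expect_equal(cmd2$delta_theta, 25)
  expect_equal(cmd2$speed, 3)
  expect_equal(cmd2$delta_phi, 0)
})

test_that("random-walk steps match the stated uniform law", {
  rng <- echosteer:::rng_stream(5, "walk")
  n <- 20000
  dt <- vapply(seq_len(n), function(i) {
    random_walk_step(rng)$delta_theta
  }, numeric(1))
  mags <- abs(dt)
  expect_true(all(mags >= 25 & mags <= 50))
  # mean magnitude 37.5 within Monte-Carlo error (se ~ 0.05)
  expect_equal(mean(mags), 37.5, tolerance = 0.01)
  expect_equal(mean(sign(dt)), 0, tolerance = 0.05)
  # fixed speed, no head motion
  one <- random_walk_step(echosteer:::rng_stream(1, "walk"))
  expect_equal(one$speed, 2)
  expect_equal(one$delta_phi, 0)
  # same stream seed, same sequence
  r1 <- echosteer:::rng_stream(9, "walk")
  r2 <- echosteer:::rng_stream(9, "walk")
  s1 <- replicate(10, random_walk_step(r1)$delta_theta)
  expect_identical(s1, replicate(10, random_walk_step(r2)$delta_theta))
})

test_that("the g-force turn-rate bound and feasibility check", {
  expect_equal(max_body_rotation_rate(2, 4), 19.62)
  expect_equal(max_body_rotation_rate(1, 4), 39.24)
  expect_equal(max_body_rotation_rate(2, 0), 0)
  expect_error(max_body_rotation_rate(0), "v must be > 0")

  fc <- feasibility_check(laws, G = 4)
  expect_true(fc$pass)
  expect_true(all(fc$margin >= 0))
  # spot values: 1000 <= 2248 deg/s at d_near, 500 <= 749 deg/s at d_far
  expect_equal(fc$commanded[1], 1000)
  expect_equal(fc$limit[1], 39.24 * 180 / pi, tolerance = 1e-6)
  expect_equal(fc$commanded[length(fc$commanded)], 500)
  expect_equal(fc$limit[length(fc$limit)], 13.08 * 180 / pi, tolerance = 1e-6)
  # a collapsed load-factor bound must fail
  expect_false(feasibility_check(laws, G = 0.1)$pass)
})
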