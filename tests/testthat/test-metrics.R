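# Constructed trial results for rate arithmetic.
fake_trial <- function(n_collisions, duration, path, termination = "completed",
                       speeds = 2, dthetas = 10) {
  n <- max(length(speeds), 5)
  structure(list(
    trajectory = data.frame(
      call = 1:n, t = (1:n - 1) * 0.05, x = seq(0, 1, length.out = n), y = 0,
      theta = 0, phi = 0, speed = rep_len(speeds, n),
      delta_theta = rep_len(dthetas, n), delta_phi = 0,
      d_hat = 1, energy_left = 1, energy_right = 1, detected = TRUE,
      d_true = 0.8, collision = FALSE
    ),
    collisions = data.frame(call = seq_len(n_collisions),
                            x = rep(0, n_collisions),
                            y = rep(0, n_collisions),
                            type = rep("obstacle", n_collisions),
                            index = rep(1L, n_collisions)),
    termination = termination, path_length = path, duration = duration,
    n_calls_executed = n, strategy = "fixed_head", seed = 1L
  ), class = "trial_result")
}

test_that("pooled collision rates use totals, not means of rates", {
  r <- collision_rates(list(fake_trial(3, 30, 60)))
  expect_equal(r$per_second, 0.1)
  expect_equal(r$per_meter, 0.05)
  r0 <- collision_rates(list(fake_trial(0, 30, 60)))
  expect_equal(r0$per_second, 0)
  expect_equal(r0$per_meter, 0)
  # pooling two unequal trials equals the rate on concatenated totals
  t1 <- fake_trial(2, 10, 15)
  t2 <- fake_trial(4, 50, 105)
  pooled <- collision_rates(list(t1, t2))
  expect_equal(pooled$per_meter, 6 / 120)
  expect_false(isTRUE(all.equal(pooled$per_meter,
                                mean(c(2 / 15, 4 / 105)))))
  expect_error(collision_rates(list(fake_trial(1, 0, 0))), "zero total")
})

test_that("percent reduction arithmetic and its antisymmetry", {
  expect_equal(reduction_pct(1.0, 0.2), 80)
  expect_equal(reduction_pct(1.0, 0), 100)
  expect_equal(reduction_pct(0.5, 0.5), 0)
  expect_error(reduction_pct(0, 1), "baseline")
  # swapping a reduction r < b turns a positive reduction negative
  b <- 0.8; r <- 0.3
  expect_gt(reduction_pct(b, r), 0)
  expect_equal(reduction_pct(r, b), 100 * (1 - b / r))
  expect_lt(reduction_pct(r, b), 0)
})

test_that("corridor outcomes report proportions with a Wilson interval", {
  all_ok <- replicate(20, fake_trial(0, 2, 4), simplify = FALSE)
  oc <- corridor_outcomes(all_ok)
  expect_equal(oc$proportion, 1.0)
  mixed <- c(replicate(6, fake_trial(0, 2, 4), simplify = FALSE),
             replicate(14, fake_trial(1, 1, 2, termination = "collision"),
                       simplify = FALSE))
  oc2 <- corridor_outcomes(mixed)
  expect_equal(oc2$proportion, 0.30)
  expect_equal(oc2$n, 20)
  # Wilson 95% interval for 6/20 (score interval, no continuity correction)
  expect_equal(oc2$ci, c(0.1455, 0.5190), tolerance = 1e-3)
  expect_true(oc2$ci[1] < 0.3 && 0.3 < oc2$ci[2])
  expect_error(corridor_outcomes(list()), "no trials")
})

test_that("Yates-corrected chi-square matches closed form and chisq.test", {
  # worked corridor table: 20/20 vs 6/20 completions
  x <- chi2_proportions_yates(matrix(c(20, 0, 6, 14), 2, 2, byrow = TRUE))
  expect_equal(floor(x), 18)
  expect_equal(x, 18.5714, tolerance = 1e-4)
  # no association
  expect_equal(chi2_proportions_yates(matrix(c(10, 10, 10, 10), 2, 2)), 0)
  # direct evaluation of the corrected formula
  expect_equal(chi2_proportions_yates(matrix(c(5, 5, 0, 10), 2, 2,
                                             byrow = TRUE)),
               4.2667, tolerance = 1e-4)
  # independent oracle: base R's corrected test statistic
  for (m in list(matrix(c(20, 0, 6, 14), 2, 2, byrow = TRUE),
                 matrix(c(5, 5, 3, 10), 2, 2, byrow = TRUE))) {
    expect_equal(chi2_proportions_yates(m),
                 unname(suppressWarnings(chisq.test(m,
                                                    correct = TRUE))$statistic))
  }
  # invariant under simultaneous row and column swaps
  m <- matrix(c(12, 3, 5, 9), 2, 2)
  expect_equal(chi2_proportions_yates(m), chi2_proportions_yates(m[2:1, 2:1]))
  expect_error(chi2_proportions_yates(matrix(c(0, 0, 3, 4), 2, 2,
                                             byrow = TRUE)), "marginal")
})

test_that("trajectory summaries pool per-call values and match a sort-based
           median", {
  e1 <- structure(list(fake_trial(0, 1, 2, speeds = c(1, 2, 2, 3, 2)),
                       fake_trial(0, 1, 2, speeds = c(2, 2, 2, 2, 2))),
                  class = "experiment_result")
  e2 <- structure(list(fake_trial(0, 1, 2, speeds = c(3, 3, 3, 3, 1))),
                  class = "experiment_result")
  ts <- trajectory_summaries(list(a = e1, b = e2), ipi = 0.05)
  sa <- ts$summary[ts$summary$strategy == "a" & ts$summary$measure == "speed", ]
  pooled <- c(1, 2, 2, 3, 2, 2, 2, 2, 2, 2)
  expect_equal(sa$median, sort(pooled)[c(5, 6)][1])  # brute-force median
  expect_equal(sa$n, 10)
  # constant speed: zero IQR
  sb <- ts$summary[ts$summary$strategy == "a" &
                     ts$summary$measure == "rotation_rate", ]
  expect_equal(sb$iqr, 0)
  # comparison statistics present for two groups
  expect_true(all(c("kruskal_H", "levene_W") %in% names(ts$tests)))
  # invariant to trial ordering
  e1r <- structure(rev(unclass(e1)), class = "experiment_result")
  ts2 <- trajectory_summaries(list(a = e1r, b = e2), ipi = 0.05)
  expect_equal(ts$summary$median, ts2$summary$median)
})

test_that("bootstrap rate intervals cover the point estimate", {
  trials <- list(fake_trial(1, 30, 60), fake_trial(3, 30, 55),
                 fake_trial(0, 30, 62), fake_trial(2, 30, 58))
  ci <- collision_rate_ci(trials, n_boot = 200, seed = 4)
  r <- collision_rates(trials)
  expect_true(ci$per_meter[1] <= r$per_meter && r$per_meter <= ci$per_meter[2])
  expect_identical(ci, collision_rate_ci(trials, n_boot = 200, seed = 4))
})
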