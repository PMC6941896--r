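test_that("default arena matches the physical layout", {
  env <- make_arena(seed = 1, n_obstacles = 11)
  expect_s3_class(env, "sonar_env")
  expect_equal(nrow(env$obstacles), 11)
  expect_equal(env$bounds, c(0, 4, 0, 3))
  # density about one pole per square meter of the 12 m^2 arena
  expect_equal(nrow(env$obstacles) / 12, 11 / 12)
  # every pole fully inside the bounds
  expect_true(all(env$obstacles$x - env$obstacles$collision_radius > 0))
  expect_true(all(env$obstacles$x + env$obstacles$collision_radius < 4))
  expect_true(all(env$obstacles$y - env$obstacles$collision_radius > 0))
  expect_true(all(env$obstacles$y + env$obstacles$collision_radius < 3))
})

test_that("arena pole spacing honours both spacing constraints", {
  for (seed in c(1, 2, 7)) {
    env <- make_arena(seed)
    dm <- as.matrix(dist(cbind(env$obstacles$x, env$obstacles$y)))
    diag(dm) <- Inf
    expect_gte(min(dm), 0.4)
    expect_lt(max(apply(dm, 1, min)), 1.0)
  }
})

test_that("arena generation is deterministic and seed-sensitive", {
  a <- make_arena(seed = 5)
  b <- make_arena(seed = 5)
  c <- make_arena(seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$scatterers, c$scatterers))
})

test_that("an obstacle-free arena carries wall scatterers only", {
  env <- make_arena(seed = 1, n_obstacles = 0)
  expect_equal(nrow(env$obstacles), 0)
  expect_true(all(env$scatterers$parent_type == "wall"))
  expect_gt(nrow(env$scatterers), 100)
})

test_that("every scatterer sits near its parent primitive", {
  env <- make_arena(seed = 3)
  sc <- env$scatterers
  ob <- sc[sc$parent_type == "obstacle", ]
  d <- sqrt((ob$x - env$obstacles$x[ob$parent_index])^2 +
            (ob$y - env$obstacles$y[ob$parent_index])^2)
  expect_true(all(d <= env$obstacles$scatter_radius[ob$parent_index] + 1e-12))
  wl <- sc[sc$parent_type == "wall", ]
  wd <- vapply(seq_len(nrow(wl)), function(i) {
    w <- env$walls[wl$parent_index[i], ]
    echosteer:::dist_point_segment(wl$x[i], wl$y[i],
                                   w$x1, w$y1, w$x2, w$y2)$distance
  }, numeric(1))
  expect_true(all(wd <= 2 * env$params$wall_jitter + 1e-12))
  expect_true(all(sc$strength > 0))
})

test_that("corridor geometry, determinism and the narrow-width error", {
  env <- make_corridor(seed = 2)
  expect_equal(env$kind, "corridor")
  expect_equal(nrow(env$walls), 2)
  expect_equal(env$goal_line, 3.0)
  expect_equal(env$corridor_axis, c(1, 0))
  expect_identical(env, make_corridor(seed = 2))
  expect_error(make_corridor(seed = 1, width = 0.2, robot_radius = 0.165),
               "invalid geometry")
})

test_that("nearest distance: closed-form cases", {
  empty <- make_arena(seed = 1, n_obstacles = 0)
  expect_equal(nearest_obstacle_distance(c(2, 1.5), empty), 1.5)
  one <- scene_with_scatterers(numeric(0), numeric(0), numeric(0))
  one$obstacles <- data.frame(x = 0, y = 0, collision_radius = 0.02,
                              scatter_radius = 0.1)
  expect_equal(nearest_obstacle_distance(c(0.5, 0), one), 0.48)
})

test_that("nearest distance equals the brute-force per-primitive minimum", {
  env <- make_arena(seed = 4)
  set.seed(99)
  for (i in 1:50) {
    p <- c(runif(1, 0, 4), runif(1, 0, 3))
    # independent brute force: explicit loops over discs and walls
    dd <- Inf
    for (j in seq_len(nrow(env$obstacles))) {
      dd <- min(dd, max(sqrt((p[1] - env$obstacles$x[j])^2 +
                             (p[2] - env$obstacles$y[j])^2) -
                          env$obstacles$collision_radius[j], 0))
    }
    for (j in seq_len(nrow(env$walls))) {
      w <- env$walls[j, ]
      vx <- w$x2 - w$x1; vy <- w$y2 - w$y1
      t <- ((p[1] - w$x1) * vx + (p[2] - w$y1) * vy) / (vx^2 + vy^2)
      t <- min(max(t, 0), 1)
      dd <- min(dd, sqrt((p[1] - w$x1 - t * vx)^2 + (p[2] - w$y1 - t * vy)^2))
    }
    expect_equal(nearest_obstacle_distance(p, env), dd)
  }
})

test_that("collision report is equivalent to a distance comparison", {
  env <- make_arena(seed = 8)
  set.seed(42)
  hits <- 0
  for (i in 1:80) {
    p <- c(runif(1, 0, 4), runif(1, 0, 3))
    cc <- check_collision(p, 0.165, env)
    expect_identical(cc$hit, nearest_obstacle_distance(p, env) < 0.165)
    if (cc$hit) {
      hits <- hits + 1
      expect_true(cc$type %in% c("obstacle", "wall"))
      expect_equal(sqrt(sum(cc$normal^2)), 1)
    }
  }
  expect_gt(hits, 0)  # the sampling must actually exercise both branches
})

test_that("wall contact reports the outward wall normal", {
  env <- make_arena(seed = 1, n_obstacles = 0)
  cc <- check_collision(c(2, 0.1), 0.165, env)  # near the y = 0 wall
  expect_true(cc$hit)
  expect_equal(cc$type, "wall")
  expect_equal(cc$normal, c(0, 1))
  expect_false(check_collision(c(2, 1.5), 0.165, env)$hit)
})

test_that("environments survive a JSON round trip", {
  env <- make_arena(seed = 11)
  path <- withr::local_tempfile(fileext = ".json")
  env_to_json(env, path)
  back <- env_from_json(path)
  expect_equal(back$kind, env$kind)
  expect_equal(back$bounds, env$bounds)
  expect_equal(back$obstacles, env$obstacles, tolerance = 1e-12)
  expect_equal(back$scatterers$strength, env$scatterers$strength,
               tolerance = 1e-12)
  expect_equal(nearest_obstacle_distance(c(1, 1), back),
               nearest_obstacle_distance(c(1, 1), env), tolerance = 1e-9)
})
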