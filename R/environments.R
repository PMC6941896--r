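# Scene generators and geometric queries. An environment couples collision
# geometry (wall segments, obstacle discs) with the acoustic point-scatterer
# ensemble used for echo synthesis: poles are wrapped in "ivy" (a cloud of
# scatterers inside the scatter radius), walls carry a dense jittered strip
# of scatterers emulating corrugated cardboard / egg-carton relief.

new_environment <- function(kind, walls, obstacles, scatterers, bounds,
                            corridor_axis = NULL, goal_line = NULL,
                            seed = NA_integer_, params = list()) {
  env <- list(
    kind = kind,
    walls = walls,            # data.frame: x1, y1, x2, y2
    obstacles = obstacles,    # data.frame: x, y, collision_radius, scatter_radius
    scatterers = scatterers,  # data.frame: x, y, strength, parent_type, parent_index
    bounds = bounds,          # c(xmin, xmax, ymin, ymax)
    corridor_axis = corridor_axis,
    goal_line = goal_line,
    seed = seed,
    params = params
  )
  class(env) <- "sonar_env"
  env
}

empty_scatterers <- function() {
  data.frame(x = numeric(0), y = numeric(0), strength = numeric(0),
             parent_type = character(0), parent_index = integer(0),
             stringsAsFactors = FALSE)
}

wall_df <- function(x1, y1, x2, y2) {
  stopifnot((x1 - x2)^2 + (y1 - y2)^2 > 0)
  data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

# Scatterer strip for one wall segment: one scatterer every `spacing` meters
# along the wall, displaced into the room by jitter_center +/- jitter about
# the wall line (relief depth), log-normal strengths.
wall_scatterers <- function(wall, inward, spacing, jitter, base_strength,
                            sdlog, rng, index) {
  len <- sqrt((wall$x2 - wall$x1)^2 + (wall$y2 - wall$y1)^2)
  n <- max(1L, floor(len / spacing))
  s <- (seq_len(n) - 0.5) * (len / n)
  ux <- (wall$x2 - wall$x1) / len
  uy <- (wall$y2 - wall$y1) / len
  off <- stream_draw(rng, function() stats::runif(n, 0, 2 * jitter))
  str <- stream_draw(rng, function() stats::rlnorm(n, log(base_strength), sdlog))
  data.frame(
    x = wall$x1 + s * ux + inward[1] * off,
    y = wall$y1 + s * uy + inward[2] * off,
    strength = str,
    parent_type = "wall",
    parent_index = index,
    stringsAsFactors = FALSE
  )
}

# "Ivy" cloud for one pole: n scatterers uniform in the scatter disc,
# log-normal amplitudes around the per-pole base strength.
obstacle_scatterers <- function(cx, cy, scatter_radius, n, base_strength,
                                sdlog, rng, index) {
  u <- stream_draw(rng, function() stats::runif(n))
  a <- stream_draw(rng, function() stats::runif(n, 0, 2 * pi))
  r <- scatter_radius * sqrt(u)
  str <- stream_draw(rng, function() stats::rlnorm(n, log(base_strength), sdlog))
  data.frame(
    x = cx + r * cos(a), y = cy + r * sin(a), strength = str,
    parent_type = "obstacle", parent_index = index,
    stringsAsFactors = FALSE
  )
}

#' Generate the cluttered rectangular arena
#'
#' Builds a walled 3 x 4 m arena populated with `n_obstacles` thin vertical
#' poles (collision radius 2 cm) wrapped in simulated ivy: each pole carries a
#' cloud of point scatterers within its 10 cm scatter radius, so a single pole
#' returns a cascade of overlapping echoes. The cardboard boundary walls carry
#' a dense strip of jittered scatterers. Pole centers are placed by rejection
#' sampling with a minimum center spacing (poles must not overlap physically)
#' and a maximum nearest-neighbour spacing below 1 m, giving a density of
#' about one obstacle per square meter.
#'
#' @param seed integer seed; the same seed reproduces the environment exactly.
#' @param n_obstacles number of poles (default 11).
#' @param width,length arena sides in meters (default 3 x 4; x runs along the
#'   long side).
#' @param collision_radius,scatter_radius pole collision / ivy radii (m).
#' @param min_spacing minimum pole center-to-center distance (m).
#' @param max_nn_spacing every pole's nearest neighbour must be closer than
#'   this (m); mirrors the "spaced less than a meter apart" layout.
#' @param wall_margin minimum pole distance from the walls (m).
#' @param scatterers_per_obstacle ivy scatterers per pole.
#' @param obstacle_strength,wall_strength base reflection amplitudes.
#' @param strength_sdlog log-normal amplitude spread (sdlog).
#' @param wall_spacing,wall_jitter wall scatterer spacing and relief jitter (m).
#' @param max_attempts rejection-sampling retry budget for the whole layout.
#' @return an object of class `sonar_env`.
#' @seealso [make_corridor()], [nearest_obstacle_distance()], [check_collision()]
#' @export
make_arena <- function(seed, n_obstacles = 11, width = 3, length = 4,
                       collision_radius = 0.02, scatter_radius = 0.10,
                       min_spacing = 0.4, max_nn_spacing = 1.0,
                       wall_margin = 0.4, scatterers_per_obstacle = 20,
                       obstacle_strength = 0.25, wall_strength = 0.15,
                       strength_sdlog = 0.5, wall_spacing = 0.03,
                       wall_jitter = 0.02, max_attempts = 500) {
  stopifnot(n_obstacles >= 0, width > 0, length > 0,
            collision_radius > 0, collision_radius <= scatter_radius)
  rng <- rng_stream(seed, "env")
  bounds <- c(0, length, 0, width)
  walls <- rbind(
    wall_df(0, 0, length, 0),
    wall_df(length, 0, length, width),
    wall_df(length, width, 0, width),
    wall_df(0, width, 0, 0)
  )
  inward <- list(c(0, 1), c(-1, 0), c(0, -1), c(1, 0))

  centers <- matrix(numeric(0), ncol = 2)
  if (n_obstacles > 0) {
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      pts <- matrix(NA_real_, nrow = n_obstacles, ncol = 2)
      placed <- 0L
      tries <- 0L
      while (placed < n_obstacles && tries < 200L * n_obstacles) {
        tries <- tries + 1L
        p <- stream_draw(rng, function() c(
          stats::runif(1, wall_margin, length - wall_margin),
          stats::runif(1, wall_margin, width - wall_margin)
        ))
        if (placed == 0L ||
            min(sqrt((pts[seq_len(placed), 1] - p[1])^2 +
                     (pts[seq_len(placed), 2] - p[2])^2)) >= min_spacing) {
          placed <- placed + 1L
          pts[placed, ] <- p
        }
      }
      if (placed < n_obstacles) next
      if (n_obstacles >= 2) {
        dm <- as.matrix(stats::dist(pts))
        diag(dm) <- Inf
        if (max(apply(dm, 1, min)) >= max_nn_spacing) next
      }
      centers <- pts
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("make_arena: could not satisfy obstacle placement constraints after ",
           max_attempts, " attempts")
    }
  }

  obstacles <- data.frame(
    x = centers[, 1][seq_len(n_obstacles)],
    y = centers[, 2][seq_len(n_obstacles)],
    collision_radius = rep(collision_radius, n_obstacles),
    scatter_radius = rep(scatter_radius, n_obstacles)
  )

  sc <- empty_scatterers()
  for (i in seq_len(nrow(walls))) {
    sc <- rbind(sc, wall_scatterers(walls[i, ], inward[[i]], wall_spacing,
                                    wall_jitter, wall_strength,
                                    strength_sdlog, rng, i))
  }
  for (i in seq_len(n_obstacles)) {
    sc <- rbind(sc, obstacle_scatterers(obstacles$x[i], obstacles$y[i],
                                        scatter_radius,
                                        scatterers_per_obstacle,
                                        obstacle_strength, strength_sdlog,
                                        rng, i))
  }
  rownames(sc) <- NULL

  new_environment(
    kind = "arena", walls = walls, obstacles = obstacles, scatterers = sc,
    bounds = bounds, seed = as.integer(seed),
    params = list(n_obstacles = n_obstacles, width = width, length = length,
                  collision_radius = collision_radius,
                  scatter_radius = scatter_radius, min_spacing = min_spacing,
                  max_nn_spacing = max_nn_spacing, wall_margin = wall_margin,
                  scatterers_per_obstacle = scatterers_per_obstacle,
                  obstacle_strength = obstacle_strength,
                  wall_strength = wall_strength,
                  strength_sdlog = strength_sdlog,
                  wall_spacing = wall_spacing, wall_jitter = wall_jitter)
  )
}

#' Generate the egg-carton-lined corridor
#'
#' Two parallel walls at +/- width/2 around the corridor axis (the x axis),
#' each lined with a dense, position- and strength-jittered scatterer strip
#' that emulates egg-carton relief: every wall return is a cascade of
#' overlapping echoes rather than a clean specular reflection. The goal line
#' sits at `length` along the axis; the corridor ends are open.
#'
#' @param seed integer seed (reproducible layout).
#' @param width,length corridor width and length in meters (defaults 0.9 x 3).
#' @param robot_radius used only to validate that the corridor is passable.
#' @param wall_strength,strength_sdlog,wall_spacing,wall_jitter scatterer
#'   ensemble parameters as in [make_arena()].
#' @return an object of class `sonar_env` with `corridor_axis` and `goal_line`.
#' @export
make_corridor <- function(seed, width = 0.9, length = 3.0,
                          robot_radius = 0.165, wall_strength = 0.15,
                          strength_sdlog = 0.5, wall_spacing = 0.03,
                          wall_jitter = 0.02) {
  if (width <= 2 * robot_radius) {
    stop("make_corridor: invalid geometry, width (", width,
         " m) must exceed the robot diameter (", 2 * robot_radius, " m)")
  }
  stopifnot(length > 0)
  rng <- rng_stream(seed, "env")
  walls <- rbind(
    wall_df(0, -width / 2, length, -width / 2),
    wall_df(0, width / 2, length, width / 2)
  )
  inward <- list(c(0, 1), c(0, -1))
  sc <- empty_scatterers()
  for (i in 1:2) {
    sc <- rbind(sc, wall_scatterers(walls[i, ], inward[[i]], wall_spacing,
                                    wall_jitter, wall_strength,
                                    strength_sdlog, rng, i))
  }
  rownames(sc) <- NULL
  new_environment(
    kind = "corridor", walls = walls,
    obstacles = data.frame(x = numeric(0), y = numeric(0),
                           collision_radius = numeric(0),
                           scatter_radius = numeric(0)),
    scatterers = sc,
    bounds = c(-0.5, length + 0.5, -width / 2, width / 2),
    corridor_axis = c(1, 0), goal_line = length, seed = as.integer(seed),
    params = list(width = width, length = length,
                  wall_strength = wall_strength,
                  strength_sdlog = strength_sdlog,
                  wall_spacing = wall_spacing, wall_jitter = wall_jitter)
  )
}

# Closest primitive to a point: distance to each disc surface and each wall
# segment, plus contact point and outward normal of the winner.
nearest_primitive <- function(point, env) {
  best <- list(distance = Inf, type = NA_character_, index = NA_integer_,
               point = c(NA_real_, NA_real_), normal = c(NA_real_, NA_real_))
  ob <- env$obstacles
  if (nrow(ob) > 0) {
    dx <- point[1] - ob$x
    dy <- point[2] - ob$y
    dc <- sqrt(dx * dx + dy * dy)
    ds <- pmax(dc - ob$collision_radius, 0)
    i <- which.min(ds)
    if (ds[i] < best$distance) {
      u <- if (dc[i] > 1e-12) c(dx[i], dy[i]) / dc[i] else c(1, 0)
      best <- list(distance = ds[i], type = "obstacle", index = i,
                   point = c(ob$x[i], ob$y[i]) + u * ob$collision_radius[i],
                   normal = u)
    }
  }
  for (i in seq_len(nrow(env$walls))) {
    w <- env$walls[i, ]
    d <- dist_point_segment(point[1], point[2], w$x1, w$y1, w$x2, w$y2)
    if (d$distance < best$distance) {
      best <- list(distance = d$distance, type = "wall", index = i,
                   point = d$point, normal = d$normal)
    }
  }
  best
}

#' Ground-truth distance to the nearest obstacle or wall
#'
#' The geometric analogue of an external tracking system: the minimum over
#' the distance to every obstacle disc surface and every wall segment.
#'
#' @param point numeric length-2 position (m).
#' @param env a `sonar_env`.
#' @return non-negative distance in meters.
#' @export
nearest_obstacle_distance <- function(point, env) {
  stopifnot(inherits(env, "sonar_env"), length(point) == 2)
  nearest_primitive(point, env)$distance
}

#' Test whether a robot disc of given radius is in contact with the scene
#'
#' Contact is declared when the nearest primitive is closer than the robot
#' radius. The report carries the contacted primitive, the contact point on
#' its surface, and the outward normal (from the primitive toward the robot
#' center), which the simulator uses to turn the robot away after a hit.
#'
#' @param position numeric length-2 robot center (m).
#' @param robot_radius robot body radius (m), > 0.
#' @param env a `sonar_env`.
#' @return list with `hit` (logical), `distance`, and (when hit) `type`
#'   ("obstacle" or "wall"), `index`, `contact_point`, `normal`.
#' @export
check_collision <- function(position, robot_radius, env) {
  stopifnot(robot_radius > 0)
  np <- nearest_primitive(position, env)
  if (np$distance < robot_radius) {
    list(hit = TRUE, distance = np$distance, type = np$type, index = np$index,
         contact_point = np$point, normal = np$normal)
  } else {
    list(hit = FALSE, distance = np$distance, type = NA_character_,
         index = NA_integer_, contact_point = NULL, normal = NULL)
  }
}

#' Serialize an environment to JSON
#'
#' @param env a `sonar_env`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return invisibly, the JSON string.
#' @export
env_to_json <- function(env, path = NULL) {
  stopifnot(inherits(env, "sonar_env"))
  payload <- unclass(env)
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                           dataframe = "columns", null = "null")
  if (!is.null(path)) writeLines(json, path)
  invisible(json)
}

#' Restore an environment from JSON
#'
#' @param source a JSON string or a file path produced by [env_to_json()].
#' @return a `sonar_env`.
#' @export
env_from_json <- function(source) {
  x <- jsonlite::fromJSON(source, simplifyDataFrame = TRUE)
  new_environment(
    kind = x$kind,
    walls = as.data.frame(x$walls),
    obstacles = as.data.frame(x$obstacles),
    scatterers = as.data.frame(x$scatterers),
    bounds = as.numeric(x$bounds),
    corridor_axis = if (is.null(x$corridor_axis)) NULL else as.numeric(x$corridor_axis),
    goal_line = x$goal_line,
    seed = x$seed,
    params = x$params
  )
}

#' @export
print.sonar_env <- function(x, ...) {
  cat("<sonar_env> ", x$kind, ": ",
      diff(x$bounds[1:2]), " x ", diff(x$bounds[3:4]), " m, ",
      nrow(x$obstacles), " obstacles, ", nrow(x$scatterers),
      " scatterers (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
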