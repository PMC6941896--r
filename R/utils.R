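# Internal helpers shared across modules. Angles are degrees, CCW-positive;
# distances are meters; the world frame has x along the arena long side /
# corridor axis.

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle into (-180, 180] degrees
#' @param x angle(s) in degrees
#' @return wrapped angle(s)
#' @keywords internal
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Shortest distance from point p = c(x, y) to segment a-b, plus the closest
# point and the outward unit normal (pointing from the segment toward p).
dist_point_segment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax
  vy <- by - ay
  len2 <- vx * vx + vy * vy
  t <- if (len2 <= 0) 0 else clamp(((px - ax) * vx + (py - ay) * vy) / len2, 0, 1)
  qx <- ax + t * vx
  qy <- ay + t * vy
  dx <- px - qx
  dy <- py - qy
  d <- sqrt(dx * dx + dy * dy)
  if (d > 1e-12) {
    n <- c(dx, dy) / d
  } else {
    # point on the segment: fall back to a perpendicular of the segment
    nl <- sqrt(len2)
    n <- if (nl > 0) c(-vy, vx) / nl else c(1, 0)
  }
  list(distance = d, point = c(qx, qy), normal = n)
}

# ---- Seeded, named RNG streams -------------------------------------------
#
# Each trial owns independent streams ("noise", "tiebreak", "walk", "init")
# derived from one seed, so adding draws to one consumer never perturbs the
# others (replay stability). Streams snapshot and restore .Random.seed so
# package code never disturbs the caller's RNG state.

stream_subseed <- function(seed, name) {
  chars <- utf8ToInt(name)
  h <- sum(chars * seq_along(chars)) %% 100000
  as.integer((abs(as.numeric(seed)) * 48271 + h * 921 + 7) %% 2147483629)
}

#' Create a named, seeded random stream
#'
#' @param seed integer master seed
#' @param name stream label; different labels give independent streams
#' @return an object of class `rng_stream`
#' @keywords internal
rng_stream <- function(seed, name = "default") {
  e <- new.env(parent = emptyenv())
  e$name <- name
  e$seed <- stream_subseed(seed, name)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(e$seed)
  e$state <- get(".Random.seed", envir = globalenv())
  if (had) {
    assign(".Random.seed", old, envir = globalenv())
  } else {
    rm(".Random.seed", envir = globalenv())
  }
  class(e) <- "rng_stream"
  e
}

# Evaluate a drawing function under the stream's RNG state, then save the
# advanced state back into the stream.
stream_draw <- function(stream, fun) {
  stopifnot(inherits(stream, "rng_stream"))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  val <- fun()
  stream$state <- get(".Random.seed", envir = globalenv())
  val
}

# ---- FFT convolution with cached kernels ---------------------------------

.echo_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (!exists(key, envir = .echo_cache, inherits = FALSE)) {
    assign(key, compute(), envir = .echo_cache)
  }
  get(key, envir = .echo_cache, inherits = FALSE)
}

# Linear convolution of x with a kernel whose padded FFT is cached under
# `key`; returns the first n_out samples (kernel is causal).
fft_conv <- function(x, kernel, key, n_out) {
  nfft <- stats::nextn(n_out + length(kernel) - 1L, 2)
  kf <- cache_get(paste0(key, "#", nfft), function() {
    stats::fft(c(kernel, numeric(nfft - length(kernel))))
  })
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  y <- Re(stats::fft(X * kf, inverse = TRUE)) / nfft
  y[seq_len(n_out)]
}
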