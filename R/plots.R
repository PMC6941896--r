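# Base-graphics scene and trajectory plots; `file` writes a PNG.

#' Plot an environment
#'
#' Walls in black, obstacle collision discs filled, scatterers as grey dots.
#'
#' @param env a `sonar_env`.
#' @param file optional PNG path.
#' @param ... passed to `plot`.
#' @return invisibly, `env`.
#' @export
plot_environment <- function(env, file = NULL, ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  b <- env$bounds
  plot(NA, xlim = b[1:2], ylim = b[3:4], asp = 1, xlab = "x (m)",
       ylab = "y (m)", main = paste("environment:", env$kind), ...)
  graphics::points(env$scatterers$x, env$scatterers$y, pch = 16, cex = 0.3,
                   col = "grey60")
  graphics::segments(env$walls$x1, env$walls$y1, env$walls$x2, env$walls$y2,
                     lwd = 2)
  if (nrow(env$obstacles) > 0) {
    th <- seq(0, 2 * pi, length.out = 40)
    for (i in seq_len(nrow(env$obstacles))) {
      graphics::polygon(env$obstacles$x[i] +
                          env$obstacles$collision_radius[i] * cos(th),
                        env$obstacles$y[i] +
                          env$obstacles$collision_radius[i] * sin(th),
                        col = "black")
    }
  }
  invisible(env)
}

#' Overlay a trial trajectory on its environment
#'
#' The path is drawn in blue, head orientations as short red ticks, and
#' collisions as green stars.
#'
#' @param result a `trial_result`.
#' @param env the `sonar_env` the trial ran in.
#' @param file optional PNG path.
#' @param head_every draw a head tick every this many calls.
#' @param ... passed to [plot_environment()].
#' @return invisibly, `result`.
#' @export
plot_trajectory <- function(result, env, file = NULL, head_every = 5, ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  plot_environment(env, file = NULL, ...)
  tr <- result$trajectory
  graphics::lines(tr$x, tr$y, col = "blue")
  idx <- seq(1, nrow(tr), by = head_every)
  g <- deg2rad(tr$theta[idx] + tr$phi[idx])
  graphics::segments(tr$x[idx], tr$y[idx], tr$x[idx] + 0.08 * cos(g),
                     tr$y[idx] + 0.08 * sin(g), col = "red")
  if (nrow(result$collisions) > 0) {
    graphics::points(result$collisions$x, result$collisions$y, pch = 8,
                     col = "green3", cex = 1.5, lwd = 2)
  }
  invisible(result)
}
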