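# Performance measures: pooled collision rates (totals over trials, not
# means of per-trial rates), percent reductions between strategies,
# corridor outcome proportions with Wilson intervals, the continuity-
# corrected chi-square worked statistic, and pooled trajectory summaries.

#' Pooled collision rates over a set of trials
#'
#' Total collisions divided by total simulated duration and by total path
#' length (a rate interpretation: pooling totals, not averaging per-trial
#' rates).
#'
#' @param results an `experiment_result` or list of `trial_result`s.
#' @return list with `per_second`, `per_meter`, `n_collisions`,
#'   `total_duration`, `total_path`.
#' @export
collision_rates <- function(results) {
  stopifnot(length(results) > 0)
  ncol_ <- sum(vapply(results, function(r) nrow(r$collisions), integer(1)))
  dur <- sum(vapply(results, function(r) r$duration, numeric(1)))
  path <- sum(vapply(results, function(r) r$path_length, numeric(1)))
  if (dur <= 0 || path <= 0) {
    stop("collision_rates: zero total duration or path length")
  }
  list(per_second = ncol_ / dur, per_meter = ncol_ / path,
       n_collisions = ncol_, total_duration = dur, total_path = path)
}

#' Bootstrap 95% CI on pooled collision rates
#'
#' Resamples trials with replacement and recomputes the pooled rates.
#'
#' @param results an `experiment_result`.
#' @param n_boot number of resamples.
#' @param seed bootstrap seed.
#' @return list with `per_second` and `per_meter` 2.5/97.5% quantiles.
#' @export
collision_rate_ci <- function(results, n_boot = 1000, seed = 1) {
  rng <- rng_stream(seed, "bootstrap")
  n <- length(results)
  ps <- pm <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- stream_draw(rng, function() sample.int(n, n, replace = TRUE))
    r <- collision_rates(results[idx])
    ps[b] <- r$per_second
    pm[b] <- r$per_meter
  }
  list(per_second = stats::quantile(ps, c(0.025, 0.975), names = FALSE),
       per_meter = stats::quantile(pm, c(0.025, 0.975), names = FALSE))
}

#' Percent reduction of a rate relative to a baseline
#'
#' @param baseline_rate reference rate (> 0).
#' @param rate rate to compare.
#' @return `100 * (1 - rate / baseline_rate)`.
#' @export
reduction_pct <- function(baseline_rate, rate) {
  if (baseline_rate <= 0) stop("reduction_pct: baseline rate must be > 0")
  100 * (1 - rate / baseline_rate)
}

#' Corridor outcome proportion with Wilson 95% interval
#'
#' @param results corridor `trial_result`s.
#' @return list with `proportion` of trials terminating `"completed"`,
#'   `n_success`, `n`, and the Wilson score 95% `ci`.
#' @export
corridor_outcomes <- function(results) {
  n <- length(results)
  if (n == 0) stop("corridor_outcomes: no trials")
  term <- vapply(results, function(r) r$termination, character(1))
  x <- sum(term == "completed")
  ci <- suppressWarnings(
    stats::prop.test(x, n, correct = FALSE)$conf.int
  )
  list(proportion = x / n, n_success = x, n = n, ci = as.numeric(ci),
       terminations = table(term))
}

#' Continuity-corrected chi-square statistic for a 2x2 proportion table
#'
#' Yates-corrected statistic
#' `N (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))` computed directly from
#' the closed form.
#'
#' @param table 2x2 matrix of counts (rows: groups, columns: outcomes).
#' @return the chi-square statistic (1 df).
#' @export
chi2_proportions_yates <- function(table) {
  m <- as.matrix(table)
  stopifnot(all(dim(m) == c(2, 2)), all(m >= 0))
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  N <- a + b + c_ + d
  marg <- c(a + b, c_ + d, a + c_, b + d)
  if (any(marg == 0)) stop("chi2_proportions_yates: zero marginal")
  N * max(abs(a * d - b * c_) - N / 2, 0)^2 / prod(marg)
}

pooled_column <- function(results, col) {
  unlist(lapply(results, function(r) r$trajectory[[col]]), use.names = FALSE)
}

# Per-call summary vectors pooled over the trials of one strategy.
pooled_measures <- function(results, env = NULL, ipi = NULL) {
  ipi <- ipi %||% (results[[1]]$duration / results[[1]]$n_calls_executed)
  out <- list(
    speed = pooled_column(results, "speed"),
    rotation_rate = abs(pooled_column(results, "delta_theta")) / ipi,
    d_hat = stats::na.omit(pooled_column(results, "d_hat")),
    d_true = pooled_column(results, "d_true")
  )
  if (!is.null(env) && env$kind == "corridor") {
    axis_deg <- rad2deg(atan2(env$corridor_axis[2], env$corridor_axis[1]))
    out$axis_angle <- abs(wrap180(pooled_column(results, "theta") - axis_deg))
  }
  out
}

#' Pooled trajectory summaries per strategy, with group comparisons
#'
#' Medians, interquartile ranges and variances of the per-call speed,
#' absolute body rotation rate, detected nearest distance, true nearest
#' distance and (corridor) body-axis angle, pooled over trials within each
#' strategy. Across strategies, a Kruskal-Wallis rank test and a
#' Brown-Forsythe variance-homogeneity test (one-way ANOVA on absolute
#' deviations from group medians) are reported per measure.
#'
#' @param experiments named list of `experiment_result`s (one per strategy).
#' @param env optional `sonar_env` (enables the corridor axis angle).
#' @param ipi control cycle, s (recovered from the trials when `NULL`).
#' @return list with `summary` (data.frame of median/IQR/variance per
#'   strategy and measure) and `tests` (data.frame of Kruskal-Wallis H and
#'   Brown-Forsythe W per measure).
#' @export
trajectory_summaries <- function(experiments, env = NULL, ipi = NULL) {
  stopifnot(length(experiments) > 0, !is.null(names(experiments)))
  measured <- lapply(experiments, pooled_measures, env = env, ipi = ipi)
  measures <- names(measured[[1]])

  rows <- list()
  for (strat in names(measured)) {
    for (m in measures) {
      v <- measured[[strat]][[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = strat, measure = m, n = length(v),
        median = stats::median(v), iqr = stats::IQR(v),
        variance = stats::var(v)
      )
    }
  }
  summary <- do.call(rbind, rows)

  tests <- NULL
  if (length(measured) >= 2) {
    trows <- list()
    for (m in measures) {
      vals <- lapply(measured, `[[`, m)
      g <- factor(rep(names(vals), lengths(vals)))
      v <- unlist(vals, use.names = FALSE)
      kw <- stats::kruskal.test(v, g)
      dev <- abs(v - stats::ave(v, g, FUN = stats::median))
      bf <- stats::anova(stats::aov(dev ~ g))
      trows[[length(trows) + 1L]] <- data.frame(
        measure = m,
        kruskal_H = as.numeric(kw$statistic), kruskal_p = kw$p.value,
        levene_W = bf$`F value`[1], levene_p = bf$`Pr(>F)`[1]
      )
    }
    tests <- do.call(rbind, trows)
  }
  list(summary = summary, tests = tests)
}
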