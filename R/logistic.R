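#' The logistic map: one step
#'
#' Applies \eqn{f_\mu(x) = \mu x (1 - x)}, the elementary model of a single
#' crab's claw displacement: `x` is the displacement at one time step and the
#' return value the displacement at the next. For `1 < mu <= 4` and
#' `x` in `[0, 1]` the image stays in `[0, mu/4] \subseteq [0, 1]`.
#'
#' @param x Numeric vector of displacements in `[0, 1]`.
#' @param mu Logistic map constant, in `(0, 4]`. Controls waving complexity:
#'   `mu < 3` gives a stable fixed point `1 - 1/mu`, `3 <= mu < 3.45` a
#'   period-two wave, then a period-doubling cascade into chaos near 3.57.
#' @return Numeric vector, `mu * x * (1 - x)`.
#' @examples
#' logistic_step(0.1, 4)    # 0.36
#' logistic_step(0.6, 2.5)  # 0.6, the fixed point 1 - 1/mu
#' @export
logistic_step <- function(x, mu) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu <= 0 || mu > 4) {
    stop("'mu' must be a single number in (0, 4], got: ", format(mu))
  }
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop("'x' must be numeric in [0, 1], got: ",
         paste(utils::head(format(x), 3L), collapse = ", "))
  }
  mu * x * (1 - x)
}

#' Parameters of a single logistic map
#'
#' @param mu Map constant in `(1, 4]`.
#' @param x0 Initial displacement in `(0, 1)`.
#' @return A list of class `"map_params"`.
#' @export
map_params <- function(mu, x0 = 0.1) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu <= 1 || mu > 4) {
    stop("'mu' must be a single number in (1, 4], got: ", format(mu))
  }
  if (!is.numeric(x0) || length(x0) != 1L || is.na(x0) || x0 <= 0 || x0 >= 1) {
    stop("'x0' must be a single number in (0, 1), got: ", format(x0))
  }
  structure(list(mu = mu, x0 = x0), class = "map_params")
}

#' Iterate the logistic map
#'
#' @param params A [map_params()] object (or a bare `mu`, in which case `x0`
#'   is taken from the `x0` argument).
#' @param n_steps Number of iterations, `>= 1`.
#' @param x0 Initial displacement, used only when `params` is numeric.
#' @return Numeric vector of length `n_steps + 1`: the trajectory
#'   `x_0, x_1, ..., x_{n_steps}`.
#' @examples
#' x <- iterate_map(map_params(2.5, 0.1), 1000)
#' tail(x, 1)  # converges to 1 - 1/2.5 = 0.6
#' @export
iterate_map <- function(params, n_steps, x0 = 0.1) {
  if (is.numeric(params)) params <- map_params(params, x0)
  stopifnot(inherits(params, "map_params"))
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1) {
    stop("'n_steps' must be a positive count")
  }
  n_steps <- as.integer(n_steps)
  out <- numeric(n_steps + 1L)
  out[1L] <- params$x0
  mu <- params$mu
  x <- params$x0
  for (n in seq_len(n_steps)) {
    x <- mu * x * (1 - x)
    out[n + 1L] <- x
  }
  out
}

#' Detect the period of an asymptotic trajectory tail
#'
#' Reports the smallest period `p <= p_max` such that the tail is
#' `p`-periodic within `tol` (i.e. `|x[n + p] - x[n]| < tol` for every `n`
#' the tail allows). A tail that matches no period up to `p_max` is flagged
#' aperiodic, the operational reading of the period-doubling cascade's
#' "period approaching infinity" at the onset of chaos.
#'
#' @param tail Numeric vector: trajectory values after the transient has been
#'   discarded. Must have length `>= 2 * p_max`.
#' @param tol Equality tolerance for orbit recurrence.
#' @param p_max Largest period considered.
#' @return A list of class `"period_report"` with elements `period` (integer,
#'   or `NA_integer_` when aperiodic), `aperiodic` (logical), `orbit_values`
#'   (the last `period` values, `NULL` when aperiodic) and `tolerance`.
#' @examples
#' x <- iterate_map(map_params(3.2, 0.1), 3000)
#' detect_period(tail(x, 200))$period  # 2
#' @export
detect_period <- function(tail, tol = 1e-8, p_max = 64L) {
  if (!is.numeric(tail) || length(tail) < 2L * p_max) {
    stop("'tail' must be numeric with length >= 2 * p_max = ", 2L * p_max)
  }
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be > 0")
  m <- length(tail)
  for (p in seq_len(p_max)) {
    if (max(abs(tail[seq_len(m - p) + p] - tail[seq_len(m - p)])) < tol) {
      return(structure(
        list(period = as.integer(p), aperiodic = FALSE,
             orbit_values = tail[seq.int(m - p + 1L, m)], tolerance = tol),
        class = "period_report"))
    }
  }
  structure(
    list(period = NA_integer_, aperiodic = TRUE,
         orbit_values = NULL, tolerance = tol),
    class = "period_report")
}

#' @export
print.period_report <- function(x, ...) {
  if (x$aperiodic) {
    cat("period report: aperiodic (no period <= p_max at tol ",
        format(x$tolerance), ")\n", sep = "")
  } else {
    cat("period report: period ", x$period, " (tol ", format(x$tolerance),
        ")\n  orbit: ", paste(signif(x$orbit_values, 6), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Scan the bifurcation structure of the logistic map
#'
#' For each `mu` on a grid, iterates the map past a transient, samples the
#' asymptotic displacement values, and classifies the attractor's period.
#' The scan reproduces the textbook landmarks: the period-two bifurcation at
#' `mu = 3`, period four at `mu = 3.45`, the accumulation of period
#' doublings near `mu = 3.57` (reported aperiodic once the period exceeds
#' `p_max`), and the period-three window around `mu = 3.83`.
#'
#' A transient long enough to pass the critical slowing-down next to each
#' bifurcation point is essential: the default of 20000 steps keeps the
#' residual decay below `tol` one grid step (0.005) away from `mu = 3`.
#'
#' @param mu_grid Increasing numeric vector of map constants in `(1, 4]`.
#' @param transient Iterations discarded before sampling.
#' @param samples Number of asymptotic values kept per `mu` (also the tail
#'   length used for period detection; must be `>= 2 * p_max`).
#' @param tol,p_max Passed to [detect_period()].
#' @param x0 Initial displacement.
#' @return A data frame with one row per grid point: `mu`, `period`
#'   (`NA` when aperiodic), `aperiodic`, and a list-column `values` holding
#'   the sampled asymptotic displacements.
#' @examples
#' scan <- scan_bifurcation(seq(2.8, 3.2, by = 0.05), transient = 20000)
#' scan[scan$period > 1, "mu"][1]  # first period-2 grid point, 3.0
#' @export
scan_bifurcation <- function(mu_grid, transient = 20000L, samples = 256L,
                             tol = 1e-8, p_max = 64L, x0 = 0.1) {
  if (length(mu_grid) == 0L) stop("'mu_grid' must be non-empty")
  if (any(mu_grid <= 1) || any(mu_grid > 4)) {
    stop("'mu_grid' values must lie in (1, 4]")
  }
  if (transient < 1) stop("'transient' must be >= 1")
  if (samples < 2L * p_max) stop("'samples' must be >= 2 * p_max")
  # all grid points iterated together; the transient dominates the cost
  x <- rep(x0, length(mu_grid))
  for (n in seq_len(transient)) x <- mu_grid * x * (1 - x)
  vals <- matrix(0, nrow = as.integer(samples), ncol = length(mu_grid))
  for (n in seq_len(samples)) {
    x <- mu_grid * x * (1 - x)
    vals[n, ] <- x
  }
  reports <- apply(vals, 2L, detect_period, tol = tol, p_max = p_max,
                   simplify = FALSE)
  out <- data.frame(
    mu = mu_grid,
    period = vapply(reports, `[[`, integer(1), "period"),
    aperiodic = vapply(reports, `[[`, logical(1), "aperiodic"))
  out$values <- lapply(seq_along(mu_grid), function(k) vals[, k])
  out
}

#' Onset of chaos on a bifurcation scan
#'
#' The period-doubling cascade accumulates near `mu = 3.57`, where the
#' attractor's period exceeds any finite bound; on a scan this shows up as
#' period detection failing (`aperiodic`). A grid point that lands exactly on
#' a bifurcation (e.g. `mu = 3`) is neutrally stable and also fails detection
#' after any finite transient, so the onset is taken as the first grid point
#' opening a run of at least `min_run` consecutive aperiodic points, which
#' discards such isolated marginal flags.
#'
#' @param scan A data frame from [scan_bifurcation()].
#' @param min_run Minimum number of consecutive aperiodic grid points.
#' @return The onset `mu`, or `NA` if no such run exists.
#' @export
chaos_onset <- function(scan, min_run = 2L) {
  stopifnot(is.data.frame(scan), "aperiodic" %in% names(scan))
  ap <- scan$aperiodic
  r <- rle(ap)
  ends <- cumsum(r$lengths)
  k <- which(r$values & r$lengths >= min_run)[1L]
  if (is.na(k)) return(NA_real_)
  scan$mu[ends[k] - r$lengths[k] + 1L]
}
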