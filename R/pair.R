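# Closed-form theory for two coupled individuals.
#
# Bidirectional (each watches the other):
#   x'_i = (1 - D) f(x_i) + D f(x_j),  x'_j = (1 - D) f(x_j) + D f(x_i)
# Leader-follower (i watches j, j watches no one):
#   x'_i = (1 - D) f(x_i) + D f(x_j),  x'_j = f(x_j)
# The amplitude difference Delta = x_i - x_j contracts by the factor
#   (1 - 2D) mu (1 - x_i - x_j)   (bidirectional)
#   (1 - D)  mu (1 - x_i - x_j)   (leader-follower)
# and since |1 - x_i - x_j| <= 1 on [0, 1]^2, nu = |1 - 2D| mu (resp.
# (1 - D) mu) < 1 is a sufficient — not necessary — synchrony condition.

#' State of a two-individual system
#'
#' @param x_i,x_j Displacements in `[0, 1]`.
#' @return A list of class `"pair_state"` with `x_i`, `x_j` and the
#'   amplitude difference `delta = x_i - x_j`.
#' @export
pair_state <- function(x_i, x_j) {
  if (any(c(x_i, x_j) < 0) || any(c(x_i, x_j) > 1)) {
    stop("displacements must lie in [0, 1]")
  }
  structure(list(x_i = x_i, x_j = x_j, delta = x_i - x_j),
            class = "pair_state")
}

#' One step of the two-individual dynamics
#'
#' @param state A [pair_state()].
#' @param mu Map constant, `(0, 4]`.
#' @param D Coupling constant, `[0, 1]`.
#' @param mode `"bidirectional"` (mutual attention) or `"leader-follower"`
#'   (`i` follows `j`; `j` is the leader, running a pure logistic map).
#' @return The next [pair_state()].
#' @examples
#' s <- pair_step(pair_state(0.2, 0.9), mu = 3.2, D = 0.5)
#' s$delta  # 0: a mutually coupled pair equalizes in one step at D = 0.5
#' @export
pair_step <- function(state, mu, D,
                      mode = c("bidirectional", "leader-follower")) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "pair_state"))
  fi <- mu * state$x_i * (1 - state$x_i)
  fj <- mu * state$x_j * (1 - state$x_j)
  if (mode == "bidirectional") {
    pair_state((1 - D) * fi + D * fj, (1 - D) * fj + D * fi)
  } else {
    pair_state((1 - D) * fi + D * fj, fj)
  }
}

#' One-step multiplier of the amplitude difference
#'
#' Returns the factor by which `delta = x_i - x_j` is multiplied in one
#' step: `(1 - 2 D) mu (1 - x_i - x_j)` for a bidirectional pair,
#' `(1 - D) mu (1 - x_i - x_j)` for a leader-follower pair. Exact:
#' `pair_step(state)$delta == factor * state$delta` up to round-off.
#'
#' @inheritParams pair_step
#' @return A single numeric factor.
#' @export
delta_update_factor <- function(state, mu, D,
                                mode = c("bidirectional", "leader-follower")) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "pair_state"))
  base <- if (mode == "bidirectional") 1 - 2 * D else 1 - D
  base * mu * (1 - state$x_i - state$x_j)
}

#' Sufficient condition for pair synchronization
#'
#' The worst-case contraction factor of the amplitude difference is
#' `nu = |1 - 2D| mu` (bidirectional) or `nu = (1 - D) mu`
#' (leader-follower); `nu < 1` guarantees `|Delta_n| <= nu^n |Delta_0|`,
#' hence synchronization. The condition is sufficient but not necessary:
#' `|1 - x_i - x_j|` is usually below 1, so pairs with `nu >= 1` can (and
#' for `mu = 3.2` above `D = 0.058` do) still synchronize.
#'
#' @param mu Map constant in `(1, 4]`.
#' @param D Coupling constant in `[0, 1]`.
#' @param mode `"bidirectional"` or `"leader-follower"`.
#' @return A list of class `"pair_condition"`: `nu`, `sufficient`
#'   (`nu < 1`), `mode`.
#' @examples
#' sync_condition(3.2, 0.5)$nu  # 0: one-step synchronization
#' @export
sync_condition <- function(mu, D,
                           mode = c("bidirectional", "leader-follower")) {
  mode <- match.arg(mode)
  if (mu <= 1 || mu > 4) stop("'mu' must be in (1, 4]")
  if (D < 0 || D > 1) stop("'D' must be in [0, 1]")
  nu <- if (mode == "bidirectional") abs(1 - 2 * D) * mu else (1 - D) * mu
  structure(list(nu = nu, sufficient = nu < 1, mode = mode),
            class = "pair_condition")
}

#' @export
print.pair_condition <- function(x, ...) {
  cat("pair condition (", x$mode, "): nu = ", signif(x$nu, 6),
      if (x$sufficient) " < 1: synchronization guaranteed\n"
      else " >= 1: no guarantee (synchronization may still occur)\n",
      sep = "")
  invisible(x)
}

#' Grid of contraction factors for the pair conditions
#'
#' Evaluates `nu` over a `(mu, D)` grid for both coupling modes — the data
#' behind the analytic synchronization phase diagram.
#'
#' @param mu_grid,D_grid Numeric grids.
#' @return A data frame with columns `mu`, `D`, `mode`, `nu`, `sufficient`.
#' @export
pair_condition_grid <- function(mu_grid = seq(1.05, 4, by = 0.05),
                                D_grid = seq(0, 1, by = 0.05)) {
  g <- expand.grid(mu = mu_grid, D = D_grid,
                   mode = c("bidirectional", "leader-follower"),
                   stringsAsFactors = FALSE)
  g$nu <- ifelse(g$mode == "bidirectional",
                 abs(1 - 2 * g$D) * g$mu, (1 - g$D) * g$mu)
  g$sufficient <- g$nu < 1
  g
}

#' Numerical estimate of the pair synchronization threshold
#'
#' For each coupling value on `D_grid`, iterates the pair dynamics from
#' `trials` independent uniform initial pairs and records whether
#' `|Delta| < tol` is reached within `max_iter` steps. The estimated
#' threshold is the smallest grid `D` from which *every* larger grid value
#' also synchronizes in all trials (guarding against reentrant
#' desynchronization windows). For `mu = 3.2`, bidirectional coupling
#' synchronizes for all `D` above about 0.058, well below the sufficient
#' condition's `D = (1 - 1/mu)/2`.
#'
#' @param mu Map constant.
#' @param mode `"bidirectional"` or `"leader-follower"`.
#' @param D_grid Increasing grid of coupling values.
#' @param trials Independent random initial pairs per grid value.
#' @param max_iter Iteration budget per trial.
#' @param tol Synchronization tolerance on `|Delta|`.
#' @param seed Optional integer seed.
#' @return A list of class `"sync_threshold"`: `threshold` (numeric, `NA`
#'   if no grid value synchronizes in all trials), `table` (data frame `D`,
#'   `fraction_synchronized`, `median_sync_time`), and the call parameters.
#' @export
estimate_sync_threshold <- function(mu, mode = c("bidirectional", "leader-follower"),
                                    D_grid = seq(0, 0.5, by = 0.002),
                                    trials = 200L, max_iter = 1e5L,
                                    tol = 1e-9, seed = NULL) {
  mode <- match.arg(mode)
  if (trials < 1) stop("'trials' must be >= 1")
  if (tol <= 0) stop("'tol' must be > 0")
  if (is.unsorted(D_grid)) stop("'D_grid' must be increasing")
  if (!is.null(seed)) set.seed(seed)
  bidir <- mode == "bidirectional"
  rows <- lapply(D_grid, function(D) {
    xi <- stats::runif(trials)
    xj <- stats::runif(trials)
    sync_time <- rep(NA_real_, trials)
    alive <- which(abs(xi - xj) >= tol)
    sync_time[setdiff(seq_len(trials), alive)] <- 0
    for (it in seq_len(max_iter)) {
      if (length(alive) == 0L) break
      fi <- mu * xi[alive] * (1 - xi[alive])
      fj <- mu * xj[alive] * (1 - xj[alive])
      xi[alive] <- (1 - D) * fi + D * fj
      xj[alive] <- if (bidir) (1 - D) * fj + D * fi else fj
      done <- abs(xi[alive] - xj[alive]) < tol
      sync_time[alive[done]] <- it
      alive <- alive[!done]
    }
    data.frame(D = D,
               fraction_synchronized = mean(!is.na(sync_time)),
               median_sync_time = stats::median(sync_time, na.rm = TRUE))
  })
  tab <- do.call(rbind, rows)
  all_sync <- tab$fraction_synchronized == 1
  # smallest D whose entire upper tail synchronizes in all trials
  tail_ok <- rev(cumprod(rev(all_sync))) == 1
  threshold <- if (any(tail_ok)) tab$D[which(tail_ok)[1L]] else NA_real_
  structure(list(threshold = threshold, table = tab, mu = mu, mode = mode,
                 trials = trials, max_iter = max_iter, tol = tol),
            class = "sync_threshold")
}

#' @export
print.sync_threshold <- function(x, ...) {
  cat("pair synchronization threshold (", x$mode, ", mu = ", x$mu, "): ",
      if (is.na(x$threshold)) "not found on grid" else signif(x$threshold, 4),
      "\n  (", x$trials, " trials, max ", format(x$max_iter, scientific = FALSE),
      " iterations, tol ", format(x$tol), ")\n", sep = "")
  invisible(x)
}
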