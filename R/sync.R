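# Synchrony statistics: per-individual neighbor correlation r_i, the global
# average <r> over central-subgrid followers and replicates, and the two
# headline parameter sweeps (bifurcation diagram, (D, rho) phase diagram).

# below this standard deviation a window is treated as constant
.degenerate_sd <- 1e-8

#' Pearson correlation of two displacement windows
#'
#' Plain Pearson correlation over the measurement window, with an explicit
#' convention for degenerate (constant) windows so that the fixed-point
#' regime reports full synchrony instead of an undefined value: if both
#' series are near-constant (sd below `1e-8`), the correlation is 1 when
#' their means agree to the same tolerance and 0 otherwise; if exactly one
#' is near-constant, the correlation is 0.
#'
#' @param a,b Numeric vectors of equal length `>= 2`.
#' @return A single value in `[-1, 1]`.
#' @examples
#' pair_correlation(c(0.5, 0.8, 0.5, 0.8), c(0.8, 0.5, 0.8, 0.5))  # -1
#' pair_correlation(rep(0.6, 10), rep(0.6, 10))                    # 1
#' @export
pair_correlation <- function(a, b) {
  if (length(a) != length(b)) {
    stop("'a' and 'b' must have equal length (got ", length(a), " and ",
         length(b), ")")
  }
  if (length(a) < 2L) stop("windows must have length >= 2")
  sa <- stats::sd(a)
  sb <- stats::sd(b)
  if (sa < .degenerate_sd && sb < .degenerate_sd) {
    return(if (abs(mean(a) - mean(b)) < .degenerate_sd) 1 else 0)
  }
  if (sa < .degenerate_sd || sb < .degenerate_sd) return(0)
  stats::cor(a, b)
}

# all-pairs correlation matrix under the same degenerate convention;
# X has one column per series
cor_matrix_degenerate <- function(X) {
  s <- apply(X, 2L, stats::sd)
  m <- colMeans(X)
  C <- suppressWarnings(stats::cor(X))
  deg <- s < .degenerate_sd
  if (any(deg)) {
    both <- outer(deg, deg, "&")
    C[both] <- (abs(outer(m, m, "-")) < .degenerate_sd)[both] * 1
    one <- xor(outer(deg, deg, "|"), both)
    C[one] <- 0
  }
  C
}

#' Mean neighbor correlation of one individual
#'
#' `r_i`: the arithmetic mean of the pairwise window correlations between
#' individual `i` and each individual inside its field of attention. A
#' leader (empty field of attention) has no defined `r_i`; `NA` is returned.
#'
#' @param i Individual index.
#' @param trajs A `"trajectory_set"` from [run_simulation()].
#' @return A single value in `[-1, 1]`, or `NA` for a leader.
#' @export
individual_correlation <- function(i, trajs) {
  stopifnot(inherits(trajs, "trajectory_set"))
  nb <- trajs$network$adjacency[[i]]
  if (length(nb) == 0L) return(NA_real_)
  win <- trajs$traj[-1L, , drop = FALSE]  # the n_l measured steps
  mean(vapply(nb, function(j) pair_correlation(win[, i], win[, j]),
              numeric(1)))
}

#' Global synchrony <r> under a configuration
#'
#' Runs `s_t` independently seeded replicates of the lattice simulation and
#' averages `r_i` over the individuals that lie inside the centered
#' `L_c x L_c` subgrid *and* have at least one neighbor (leaders have an
#' empty correlation sum and are excluded; the restriction to the central
#' subgrid removes lattice-boundary effects). The global value is the mean
#' of the per-replicate means.
#'
#' @param config A [simulation_config()]; `s_t`, `n_l`, `n_transient` and
#'   the seed are taken from it unless overridden.
#' @param seed Optional master seed overriding `config$seed`.
#' @param s_t Optional replicate count overriding `config$s_t`.
#' @return A list of class `"correlation_summary"`: `r_global`,
#'   `per_replicate` (data frame with the replicate means, contributing
#'   counts and exclusion counts), `n_contributing` (total), `window`
#'   (`n_l`), `defined` (`FALSE` when no individual contributed anywhere).
#' @export
global_correlation <- function(config, seed = config$seed, s_t = config$s_t) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- spawn_seeds(s_t, seed)
  rows <- lapply(seq_len(s_t), function(k) {
    sim <- run_simulation(config, seed = seeds[k])
    net <- sim$network
    keep <- which(central_index(sim$population) & net$out_degree > 0L)
    excluded <- sum(central_index(sim$population)) - length(keep)
    if (length(keep) == 0L) {
      return(data.frame(replicate = k, mean_r = NA_real_, n_contributing = 0L,
                        n_excluded_leaders = excluded))
    }
    win <- sim$traj[-1L, , drop = FALSE]
    cols <- sort(unique(c(keep, unlist(net$adjacency[keep]))))
    C <- cor_matrix_degenerate(win[, cols, drop = FALSE])
    pos <- match(seq_len(net$n), cols)
    r_i <- vapply(keep, function(i) {
      mean(C[pos[i], pos[net$adjacency[[i]]]])
    }, numeric(1))
    data.frame(replicate = k, mean_r = mean(r_i),
               n_contributing = length(keep),
               n_excluded_leaders = excluded)
  })
  per_rep <- do.call(rbind, rows)
  ok <- !is.na(per_rep$mean_r)
  structure(list(
    r_global = if (any(ok)) mean(per_rep$mean_r[ok]) else NA_real_,
    per_replicate = per_rep,
    n_contributing = sum(per_rep$n_contributing),
    window = config$n_l,
    defined = any(ok)
  ), class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat("global correlation <r> = ",
      if (x$defined) signif(x$r_global, 4) else "undefined (no followers)",
      " over ", nrow(x$per_replicate), " replicates (",
      x$n_contributing, " contributing individuals, window ", x$window,
      ")\n", sep = "")
  invisible(x)
}

# per-individual period classification of a trajectory window
window_periods <- function(win, tol = 1e-6, p_max = 64L) {
  apply(win, 2L, function(v) {
    detect_period(v, tol = tol, p_max = p_max)$period
  })
}

#' Bifurcation sweep of the lattice model
#'
#' For each `mu` on a grid: runs the full lattice model, records the global
#' correlation `<r>` over `s_t` replicates, the asymptotic displacement
#' values of all individuals, one tracked individual's orbit, and the
#' distribution of detected per-individual periods. This is the coupled
#' analogue of [scan_bifurcation()], colored by synchrony.
#'
#' @param config A [simulation_config()]; its `mu` is replaced by each grid
#'   value in turn.
#' @param mu_grid Numeric grid in `(1, 4]`.
#' @param seed Master seed (overrides `config$seed`).
#' @param sample_steps How many trailing window steps to keep as asymptotic
#'   displacement samples.
#' @param period_tol Tolerance for per-individual period detection (looser
#'   than the single-map default: the window starts only `n_transient` steps
#'   after random initial conditions).
#' @return A data frame, one row per `mu`: `mu`, `r_global`,
#'   `n_contributing`, `period_mode` (most common finite period, `NA` if all
#'   aperiodic), `n_aperiodic`, plus list-columns `periods`, `samples`
#'   (pooled asymptotic values) and `tracked_orbit`.
#' @export
sweep_mu <- function(config, mu_grid, seed = config$seed,
                     sample_steps = 64L, period_tol = 1e-6) {
  stopifnot(inherits(config, "simulation_config"))
  if (any(mu_grid <= 1) || any(mu_grid > 4)) stop("'mu_grid' must lie in (1, 4]")
  seeds <- spawn_seeds(length(mu_grid), seed)
  rows <- lapply(seq_along(mu_grid), function(k) {
    cfg <- config
    cfg$mu <- mu_grid[k]
    gc <- global_correlation(cfg, seed = seeds[k])
    sim <- run_simulation(cfg, seed = spawn_seeds(1L, seeds[k]))
    win <- sim$traj[-1L, , drop = FALSE]
    periods <- window_periods(win, tol = period_tol)
    finite <- periods[!is.na(periods)]
    list(mu = mu_grid[k], r_global = gc$r_global,
         n_contributing = gc$n_contributing,
         period_mode = if (length(finite)) {
           as.integer(names(sort(table(finite), decreasing = TRUE))[1L])
         } else NA_integer_,
         n_aperiodic = sum(is.na(periods)),
         periods = periods,
         samples = as.numeric(utils::tail(win, sample_steps)),
         tracked_orbit = win[, 1L])
  })
  out <- data.frame(
    mu = vapply(rows, `[[`, numeric(1), "mu"),
    r_global = vapply(rows, `[[`, numeric(1), "r_global"),
    n_contributing = vapply(rows, `[[`, numeric(1), "n_contributing"),
    period_mode = vapply(rows, `[[`, integer(1), "period_mode"),
    n_aperiodic = vapply(rows, function(r) as.integer(r$n_aperiodic), integer(1)))
  out$periods <- lapply(rows, `[[`, "periods")
  out$samples <- lapply(rows, `[[`, "samples")
  out$tracked_orbit <- lapply(rows, `[[`, "tracked_orbit")
  out
}

#' Phase-diagram sweep over coupling and density
#'
#' Computes the global correlation `<r>` on a `(D, rho)` grid for a fixed
#' `mu`, `theta` and orientation model — the data behind the synchrony
#' phase diagrams (high synchrony at low density for any `mu`; an
#' asynchrony band at intermediate densities under M1; a shallow valley
#' around `rho = 0.6` under M2 in the periodic regime).
#'
#' @param config A [simulation_config()]; `D` and `rho` are replaced by the
#'   grid values.
#' @param D_grid,rho_grid Numeric grids in `[0, 1]` (`rho > 0`).
#' @param seed Master seed (overrides `config$seed`).
#' @return A data frame with one row per `(D, rho)` cell: `D`, `rho`,
#'   `r_global`, `n_contributing`.
#' @export
sweep_phase <- function(config, D_grid, rho_grid, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (any(D_grid < 0) || any(D_grid > 1)) stop("'D_grid' must lie in [0, 1]")
  if (any(rho_grid <= 0) || any(rho_grid > 1)) stop("'rho_grid' must lie in (0, 1]")
  cells <- expand.grid(D = D_grid, rho = rho_grid)
  seeds <- spawn_seeds(nrow(cells), seed)
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    cfg <- config
    cfg$D <- cells$D[k]
    cfg$grid <- grid_config(config$grid$L, config$grid$L_c, cells$rho[k])
    gc <- global_correlation(cfg, seed = seeds[k])
    data.frame(D = cells$D[k], rho = cells$rho[k], r_global = gc$r_global,
               n_contributing = gc$n_contributing)
  })
  do.call(rbind, rows)
}
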