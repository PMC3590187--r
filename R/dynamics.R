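# Coupled logistic dynamics over the interaction network.
#
# Update rule (synchronous, all individuals at once):
#   x'_i = (1 - D) * f_mu(x_i) + D * f_mu(Xbar_i),   f_mu(x) = mu x (1 - x)
# where Xbar_i is the (plain or 1/d-weighted) mean displacement over the
# N_i individuals in i's field of attention. Leaders (N_i = 0) follow the
# pure logistic map. Both terms lie in [0, mu/4], so states stay in [0, 1]
# for any network and any D in [0, 1].

#' Full simulation configuration
#'
#' Bundles every model and run parameter. Defaults follow the reference
#' setting of the lattice study: reach `R = 3`, lattice width `L = 30`,
#' correlation subgrid `L_c = 10`, attention angle `theta = 60` degrees, a
#' 500-step transient and a 500-step measurement window.
#'
#' @param mu Logistic constant, `(1, 4]`.
#' @param D Coupling constant in `[0, 1]`; 0 decouples the population into
#'   independent logistic maps.
#' @param grid A [grid_config()].
#' @param theta,R Field-of-attention angle (degrees) and reach (sites).
#' @param model Orientation rule, `"M1"` (random) or `"M2"`
#'   (neighbor-maximizing).
#' @param n_transient Steps discarded before measurement.
#' @param n_l Measurement window length (the time lag of the correlation
#'   statistic), `>= 2`.
#' @param s_t Number of replicate simulations entering global averages.
#' @param seed Master seed (integer) for full reproducibility.
#' @param coupling_variant `"plain"` (arithmetic neighbor mean) or
#'   `"distance-weighted"` (weights proportional to `1/d^weight_exponent`).
#' @param weight_exponent Exponent of the inverse-distance weights.
#' @param coupling_form `"map-of-mean"` applies the map to the neighborhood
#'   mean, `D * f_mu(Xbar_i)`; `"mean-of-map"` averages the mapped
#'   neighbors, `D * mean(f_mu(x_j))`. The first is the default: it is the
#'   form consistent with the pair theory's amplitude-difference factor
#'   `(1 - 2D) mu (1 - x_i - x_j)`. The alternative is kept for sensitivity
#'   checks.
#' @param tie_rule Tie-break for M2 orientation, see [orient_preferential()].
#' @param boundary `"clip"` (default: sectors overhanging the lattice edge
#'   simply contain nobody) or `"literal"` (an individual whose sector
#'   extends beyond the lattice receives no coupling at all), see
#'   [build_network()].
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(mu = 3.2, D = 0.5, grid = grid_config(),
                              theta = 60, R = 3,
                              model = c("M1", "M2"),
                              n_transient = 500L, n_l = 500L, s_t = 500L,
                              seed = NULL,
                              coupling_variant = c("plain", "distance-weighted"),
                              weight_exponent = 1,
                              coupling_form = c("map-of-mean", "mean-of-map"),
                              tie_rule = c("count-random", "similarity"),
                              boundary = c("clip", "literal")) {
  model <- model[1L]
  if (!is.character(model) || !model %in% c("M1", "M2")) {
    stop("'model' must be \"M1\" or \"M2\", got: ", format(model))
  }
  coupling_variant <- match.arg(coupling_variant)
  coupling_form <- match.arg(coupling_form)
  tie_rule <- match.arg(tie_rule)
  boundary <- match.arg(boundary)
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 1 || mu > 4) {
    stop("'mu' must be in (1, 4], got: ", format(mu))
  }
  if (!is.numeric(D) || length(D) != 1L || D < 0 || D > 1) {
    stop("'D' must be in [0, 1], got: ", format(D))
  }
  stopifnot(inherits(grid, "grid_config"))
  check_sector_params(theta, R)
  if (!is.numeric(n_l) || n_l < 2) stop("'n_l' must be >= 2")
  if (!is.numeric(n_transient) || n_transient < 0) {
    stop("'n_transient' must be >= 0")
  }
  if (!is.numeric(s_t) || s_t < 1) stop("'s_t' must be >= 1")
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
      stop("'seed' must be a single integer")
    }
    seed <- as.integer(seed)
  }
  structure(list(
    mu = mu, D = D, grid = grid, theta = theta, R = R, model = model,
    n_transient = as.integer(n_transient), n_l = as.integer(n_l),
    s_t = as.integer(s_t), seed = seed,
    coupling_variant = coupling_variant, weight_exponent = weight_exponent,
    coupling_form = coupling_form, tie_rule = tie_rule, boundary = boundary
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation config: model ", x$model, ", mu = ", x$mu, ", D = ", x$D,
      ", theta = ", x$theta, ", R = ", x$R,
      "\n  grid L = ", x$grid$L, " (L_c = ", x$grid$L_c, "), rho = ",
      x$grid$rho, " (", x$grid$n_ind, " individuals)",
      "\n  steps: ", x$n_transient, " transient + ", x$n_l,
      " measured; s_t = ", x$s_t, " replicates; seed = ",
      if (is.null(x$seed)) "unset" else x$seed, "\n", sep = "")
  invisible(x)
}

# Row-normalized coupling weight matrix (sparse) and the leader mask.
# W[i, j] is the weight of neighbor j in i's average; rows of leaders are 0.
coupling_matrix <- function(net, variant = c("plain", "distance-weighted"),
                            weight_exponent = 1) {
  variant <- match.arg(variant)
  e <- net$edges
  if (nrow(e) == 0L) {
    return(list(W = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                         x = numeric(0), dims = c(net$n, net$n)),
                has_neighbors = rep(FALSE, net$n)))
  }
  w <- if (variant == "plain") rep(1, nrow(e)) else 1 / e$distance^weight_exponent
  tot <- tapply(w, factor(e$from, levels = seq_len(net$n)), sum)
  tot[is.na(tot)] <- 1
  W <- Matrix::sparseMatrix(i = e$from, j = e$to, x = w / as.numeric(tot[e$from]),
                            dims = c(net$n, net$n))
  list(W = W, has_neighbors = net$out_degree > 0L)
}

#' Neighborhood mean displacement
#'
#' The averaged displacement entering individual `i`'s coupling term: the
#' arithmetic mean of the displacements of everyone inside `i`'s field of
#' attention, or an inverse-distance-weighted mean under the
#' `"distance-weighted"` variant. An individual with an empty field of
#' attention has no defined mean; `NA` is returned for it.
#'
#' @param state Numeric vector, one displacement per individual, in `[0, 1]`.
#' @param net An `"interaction_network"`.
#' @param i Individual index (or vector of indices; default all).
#' @param variant `"plain"` or `"distance-weighted"`.
#' @param weight_exponent Exponent of the inverse-distance weights.
#' @return Numeric vector of means, `NA` where `N_i = 0`.
#' @export
neighborhood_mean <- function(state, net, i = seq_len(net$n),
                              variant = c("plain", "distance-weighted"),
                              weight_exponent = 1) {
  variant <- match.arg(variant)
  stopifnot(length(state) == net$n, all(state >= 0 & state <= 1))
  cm <- coupling_matrix(net, variant, weight_exponent)
  xbar <- as.numeric(cm$W %*% state)
  xbar[!cm$has_neighbors] <- NA_real_
  xbar[i]
}

# one synchronous update given a precomputed coupling matrix
step_with_matrix <- function(state, cm, mu, D,
                             coupling_form = "map-of-mean") {
  fx <- mu * state * (1 - state)
  if (D == 0) return(fx)
  if (coupling_form == "map-of-mean") {
    xbar <- as.numeric(cm$W %*% state)
    coup <- mu * xbar * (1 - xbar)
  } else {
    coup <- as.numeric(cm$W %*% fx)
  }
  out <- (1 - D) * fx + D * coup
  out[!cm$has_neighbors] <- fx[!cm$has_neighbors]
  out
}

#' One synchronous step of the coupled dynamics
#'
#' Applies the coupled update to every individual at once:
#' `x'_i = (1 - D) f_mu(x_i) + D f_mu(Xbar_i)` for followers and
#' `x'_i = f_mu(x_i)` for leaders (empty field of attention). With `D = 0`
#' the population decouples into independent logistic maps; with `D = 0.5`
#' a mutually coupled pair equalizes in a single step.
#'
#' @inheritParams neighborhood_mean
#' @param mu,D Map and coupling constants.
#' @param coupling_form See [simulation_config()].
#' @return The next state vector, guaranteed to stay in `[0, 1]`.
#' @export
coupled_step <- function(state, net, mu, D,
                         variant = c("plain", "distance-weighted"),
                         weight_exponent = 1,
                         coupling_form = c("map-of-mean", "mean-of-map")) {
  variant <- match.arg(variant)
  coupling_form <- match.arg(coupling_form)
  stopifnot(length(state) == net$n)
  if (any(state < 0 | state > 1)) stop("'state' must lie in [0, 1]")
  if (mu <= 0 || mu > 4) stop("'mu' must be in (0, 4]")
  if (D < 0 || D > 1) stop("'D' must be in [0, 1]")
  cm <- coupling_matrix(net, variant, weight_exponent)
  step_with_matrix(state, cm, mu, D, coupling_form)
}

#' Run one full lattice simulation
#'
#' Places the population, orients the fields of attention under the chosen
#' model, builds the interaction network, draws independent uniform initial
#' displacements, iterates the coupled dynamics through the transient, and
#' records the measurement window. Everything is a pure function of
#' `(config, seed)`.
#'
#' @param config A [simulation_config()].
#' @param seed Optional integer; overrides `config$seed`.
#' @return A list of class `"trajectory_set"`: `traj` (matrix, `n_l + 1`
#'   rows = the state at the start of the window plus `n_l` updates, one
#'   column per individual), `network`, `population`, `config`.
#' @export
run_simulation <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  pop <- place_individuals(config$grid)
  x <- stats::runif(config$grid$n_ind)  # initial claw displacements
  pop <- if (config$model == "M1") {
    orient_random(pop, config$theta, config$R)
  } else {
    orient_preferential(pop, config$theta, config$R,
                        tie_rule = config$tie_rule, displacement = x)
  }
  net <- build_network(pop, boundary = config$boundary)
  cm <- coupling_matrix(net, config$coupling_variant, config$weight_exponent)
  for (n in seq_len(config$n_transient)) {
    x <- step_with_matrix(x, cm, config$mu, config$D, config$coupling_form)
  }
  traj <- matrix(0, nrow = config$n_l + 1L, ncol = net$n)
  traj[1L, ] <- x
  for (n in seq_len(config$n_l)) {
    x <- step_with_matrix(x, cm, config$mu, config$D, config$coupling_form)
    traj[n + 1L, ] <- x
  }
  structure(list(traj = traj, network = net, population = pop,
                 config = config, seed = seed),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("trajectory set: ", ncol(x$traj), " individuals x ", nrow(x$traj),
      " recorded steps (model ", x$config$model, ", mu = ", x$config$mu,
      ", D = ", x$config$D, ")\n", sep = "")
  invisible(x)
}
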