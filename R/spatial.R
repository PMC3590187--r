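# Lattice population, sector-shaped fields of attention, orientation rules,
# and the directed interaction network they induce.

# absolute angular offset between two directions, in degrees, in [0, 180]
ang_offset <- function(a, b) {
  abs(((a - b + 180) %% 360) - 180)
}

# tolerance for the inclusive sector-boundary comparisons; keeps a neighbor
# lying exactly on a sector edge inside the sector despite rounding
.sector_tol <- 1e-9

#' Lattice configuration
#'
#' Describes the square lattice of burrow sites: width `L`, the width `L_c`
#' of the centered subgrid over which boundary-insensitive statistics are
#' averaged, and the occupancy density `rho`. The population size is
#' `round(rho * L^2)`.
#'
#' @param L Lattice width in sites (`L >= 1`).
#' @param L_c Central-subgrid width (`1 <= L_c <= L`).
#' @param rho Occupancy density in `(0, 1]`.
#' @return A list of class `"grid_config"` with an extra element `n_ind`,
#'   the implied population size.
#' @examples
#' grid_config(L = 30, L_c = 10, rho = 0.4)$n_ind  # 360
#' @export
grid_config <- function(L = 30L, L_c = 10L, rho = 0.4) {
  if (!is.numeric(L) || length(L) != 1L || L < 1 || L != round(L)) {
    stop("'L' must be a positive integer, got: ", format(L))
  }
  if (!is.numeric(L_c) || length(L_c) != 1L || L_c < 1 || L_c > L ||
      L_c != round(L_c)) {
    stop("'L_c' must be an integer in [1, L], got: ", format(L_c))
  }
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) ||
      rho <= 0 || rho > 1) {
    stop("'rho' must be in (0, 1], got: ", format(rho))
  }
  n_ind <- as.integer(round(rho * L^2))
  if (n_ind < 1L) stop("empty population: rho * L^2 rounds to 0")
  structure(list(L = as.integer(L), L_c = as.integer(L_c), rho = rho,
                 n_ind = n_ind),
            class = "grid_config")
}

#' Place individuals on the lattice
#'
#' Draws `round(rho * L^2)` distinct sites uniformly without replacement.
#' Sites are integer coordinates `(x, y)` in `[0, L)^2`, one crab per site
#' (each site is the area around one male's burrow).
#'
#' @param grid A [grid_config()].
#' @param seed Optional integer seed; when given, the placement is a pure
#'   function of `(grid, seed)`.
#' @return A data frame of class `"crab_population"` with columns `id`, `x`,
#'   `y`, and `phi` (orientation, `NA` until an orientation rule is applied);
#'   the grid configuration is kept in attribute `"grid"`.
#' @export
place_individuals <- function(grid, seed = NULL) {
  stopifnot(inherits(grid, "grid_config"))
  if (!is.null(seed)) set.seed(seed)
  sites <- sample.int(grid$L^2, grid$n_ind) - 1L
  pop <- data.frame(
    id = seq_len(grid$n_ind),
    x = sites %% grid$L,
    y = sites %/% grid$L,
    phi = NA_real_
  )
  attr(pop, "grid") <- grid
  class(pop) <- c("crab_population", "data.frame")
  pop
}

#' Sector membership test
#'
#' Is `target` inside the field of attention anchored at `origin`, oriented
#' along `phi`? The field is the circular sector of reach `R` and full
#' opening angle `theta` (degrees); membership requires Euclidean distance
#' `<= R` and absolute angular offset from `phi` `<= theta / 2`, both
#' inclusive. For `theta = 360` the angular test always passes.
#'
#' @param origin Length-2 numeric, the focal site `(x, y)`.
#' @param phi Orientation of the sector axis, degrees.
#' @param target Length-2 numeric or a two-column matrix of sites.
#' @param R Reach, in site units.
#' @param theta Opening angle in degrees, `(0, 360]`.
#' @return Logical, one value per target row.
#' @export
in_sector <- function(origin, phi, target, R, theta) {
  target <- matrix(as.numeric(target), ncol = 2L)
  dx <- target[, 1L] - origin[1L]
  dy <- target[, 2L] - origin[2L]
  d2 <- dx^2 + dy^2
  if (any(d2 == 0)) stop("'target' coincides with 'origin': self is not a neighbor")
  ok <- d2 <= R^2 + .sector_tol
  if (theta < 360) {
    dir <- atan2(dy, dx) * 180 / pi
    ok <- ok & ang_offset(dir, phi) <= theta / 2 + .sector_tol
  }
  ok
}

#' Random orientation of the fields of attention (model M1)
#'
#' Each male's sector axis `phi` is drawn independently and uniformly on
#' `[0, 360)`, blind to where other males are.
#'
#' @param pop A `"crab_population"` from [place_individuals()].
#' @param theta,R Sector opening angle (degrees) and reach (site units).
#' @param seed Optional integer seed.
#' @return The population with `phi` filled in and attributes `theta`, `R`,
#'   `model = "M1"` recorded.
#' @export
orient_random <- function(pop, theta = 60, R = 3, seed = NULL) {
  stopifnot(inherits(pop, "crab_population"))
  check_sector_params(theta, R)
  if (!is.null(seed)) set.seed(seed)
  pop$phi <- stats::runif(nrow(pop), 0, 360)
  attr(pop, "theta") <- theta
  attr(pop, "R") <- R
  attr(pop, "model") <- "M1"
  pop
}

check_sector_params <- function(theta, R) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta > 360) {
    stop("'theta' must be in (0, 360], got: ", format(theta))
  }
  if (!is.numeric(R) || length(R) != 1L || R <= 0) {
    stop("'R' must be > 0, got: ", format(R))
  }
  invisible(TRUE)
}

#' Neighbor-maximizing orientation (model M2)
#'
#' Each male orients his field of attention so that the number of other
#' males inside it is maximal. The maximum of this count over the continuous
#' orientation `phi` is always attained at an orientation whose sector edge
#' touches the direction of some neighbor, so the search is over the finite
#' candidate set \{direction to each neighbor within R\} union \{those
#' directions +/- theta/2\}. When several orientations cover distinct but
#' equally large sets of neighbors, the tie is resolved by `tie_rule`:
#'
#' * `"count-random"`: one of the tied covered sets is chosen uniformly at
#'   random;
#' * `"similarity"`: the set whose mean displacement is closest to the
#'   male's own current displacement is chosen (requires `displacement`).
#'
#' A male with nobody within reach orients uniformly at random; he becomes a
#' leader and, by symmetry of distance, appears in no one's neighbor count
#' statistics any differently than under M1.
#'
#' For `theta = 360` orientation is irrelevant and the rule reduces to
#' [orient_random()].
#'
#' @inheritParams orient_random
#' @param tie_rule `"count-random"` or `"similarity"`.
#' @param displacement Numeric vector of current claw displacements, one per
#'   individual; only used by the `"similarity"` tie rule.
#' @return The population with `phi` filled in and attributes recorded
#'   (`model = "M2"`).
#' @export
orient_preferential <- function(pop, theta = 60, R = 3, seed = NULL,
                                tie_rule = c("count-random", "similarity"),
                                displacement = NULL) {
  stopifnot(inherits(pop, "crab_population"))
  check_sector_params(theta, R)
  tie_rule <- match.arg(tie_rule)
  if (!is.null(seed)) set.seed(seed)
  if (theta >= 360) {
    pop$phi <- stats::runif(nrow(pop), 0, 360)
    attr(pop, "theta") <- theta
    attr(pop, "R") <- R
    attr(pop, "model") <- "M2"
    return(pop)
  }
  if (tie_rule == "similarity" && is.null(displacement)) {
    stop("tie_rule = \"similarity\" needs the 'displacement' vector")
  }
  n <- nrow(pop)
  phi <- numeric(n)
  half <- theta / 2
  for (i in seq_len(n)) {
    dx <- pop$x - pop$x[i]
    dy <- pop$y - pop$y[i]
    d2 <- dx^2 + dy^2
    nb <- which(d2 > 0 & d2 <= R^2 + .sector_tol)
    if (length(nb) == 0L) {
      phi[i] <- stats::runif(1, 0, 360)
      next
    }
    dirs <- atan2(dy[nb], dx[nb]) * 180 / pi
    cand <- c(dirs, dirs + half, dirs - half) %% 360
    # coverage[c, k]: neighbor k visible from candidate orientation c
    coverage <- outer(cand, dirs, function(a, b) {
      ang_offset(b, a) <= half + .sector_tol
    })
    counts <- rowSums(coverage)
    best <- which(counts == max(counts))
    keys <- vapply(best, function(b) {
      paste(which(coverage[b, ]), collapse = ",")
    }, character(1))
    sets <- best[!duplicated(keys)]
    if (length(sets) == 1L) {
      pick <- sets
    } else if (tie_rule == "count-random") {
      pick <- sets[sample.int(length(sets), 1L)]
    } else {
      own <- displacement[i]
      sim <- vapply(sets, function(b) {
        abs(mean(displacement[nb[coverage[b, ]]]) - own)
      }, numeric(1))
      tied <- sets[sim == min(sim)]
      pick <- if (length(tied) == 1L) tied else tied[sample.int(length(tied), 1L)]
    }
    phi[i] <- cand[pick]
  }
  pop$phi <- phi
  attr(pop, "theta") <- theta
  attr(pop, "R") <- R
  attr(pop, "model") <- "M2"
  pop
}

#' Build the directed interaction network
#'
#' Edge `i -> j` means "`j` is inside `i`'s field of attention", i.e. `i`
#' follows (is influenced by) `j`. The out-degree `N_i` is the neighbor
#' count entering `i`'s coupling term. Boundaries are absorbing: the part of
#' a sector hanging over the lattice edge simply contains no one.
#'
#' Boundaries are handled per `boundary`: under `"clip"` (default) a sector
#' overhanging the lattice edge is silently clipped — the missing area just
#' contains nobody; under the `"literal"` alternative an individual whose
#' sector extends beyond the lattice is not influenced by anyone at all (his
#' out-edges are removed and he behaves as a leader).
#'
#' @param pop An oriented `"crab_population"` (from [orient_random()] or
#'   [orient_preferential()]).
#' @param boundary `"clip"` or `"literal"`.
#' @return A list of class `"interaction_network"`: `edges` (data frame
#'   `from`, `to`, `distance`, `reciprocal`), `out_degree` (vector `N_i`),
#'   `adjacency` (list of out-neighbor indices per individual), `n`, and the
#'   `theta`, `R`, `model` attributes echoed.
#' @export
build_network <- function(pop, boundary = c("clip", "literal")) {
  stopifnot(inherits(pop, "crab_population"))
  boundary <- match.arg(boundary)
  if (anyNA(pop$phi)) stop("population has no orientations yet; apply an orientation rule")
  theta <- attr(pop, "theta")
  R <- attr(pop, "R")
  n <- nrow(pop)
  dx <- outer(pop$x, pop$x, "-")   # dx[i, j] = x_j - x_i  (origin in row i)
  dx <- -dx
  dy <- -outer(pop$y, pop$y, "-")
  d2 <- dx^2 + dy^2
  within <- d2 <= R^2 + .sector_tol
  diag(within) <- FALSE
  if (theta < 360) {
    dir <- atan2(dy, dx) * 180 / pi
    within <- within & ang_offset(dir, pop$phi) <= theta / 2 + .sector_tol
  }
  if (boundary == "literal") {
    grid <- attr(pop, "grid")
    inside <- vapply(seq_len(n), function(i) {
      sector_in_box(pop$x[i], pop$y[i], pop$phi[i], R, theta, grid$L)
    }, logical(1))
    within[!inside, ] <- FALSE
  }
  idx <- which(within, arr.ind = TRUE)
  edges <- data.frame(
    from = idx[, 1L], to = idx[, 2L],
    distance = sqrt(d2[idx])
  )
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  recip <- within & t(within)
  edges$reciprocal <- recip[cbind(edges$from, edges$to)]
  structure(list(
    edges = edges,
    out_degree = as.integer(rowSums(within)),
    adjacency = apply(within, 1L, which, simplify = FALSE),
    n = n,
    theta = theta, R = R, model = attr(pop, "model")
  ), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction network: ", x$n, " individuals, ", nrow(x$edges),
      " directed edges (", sum(x$edges$reciprocal), " in reciprocal pairs), ",
      sum(x$out_degree == 0L), " leaders\n", sep = "")
  invisible(x)
}

# Exact test that the attention sector anchored at (x, y), axis phi, reach R,
# opening theta, lies inside the lattice box [0, L-1]^2. Uses the sector's
# support function: its extreme coordinate along each axis direction is
# attained either at an arc endpoint, at the axis direction itself (when that
# direction falls inside the angular interval), or at the apex (r = 0).
sector_in_box <- function(x, y, phi, R, theta, L) {
  half <- theta / 2
  extreme <- function(target_dir, coord_fun) {
    # max of coord_fun over unit directions within the angular interval
    cands <- c(phi - half, phi + half)
    if (ang_offset(target_dir, phi) <= half) cands <- c(cands, target_dir)
    m <- max(coord_fun(cands * pi / 180))
    max(m, 0) * R  # r = 0 (the apex) is always available
  }
  xmax <- x + extreme(0, cos)
  xmin <- x - extreme(180, function(a) -cos(a))
  ymax <- y + extreme(90, sin)
  ymin <- y - extreme(270, function(a) -sin(a))
  xmin >= 0 && ymin >= 0 && xmax <= L - 1 && ymax <= L - 1
}

# logical index of individuals inside the centered L_c x L_c subgrid
central_index <- function(pop) {
  grid <- attr(pop, "grid")
  lo <- (grid$L - grid$L_c) %/% 2L
  hi <- lo + grid$L_c - 1L
  pop$x >= lo & pop$x <= hi & pop$y >= lo & pop$y <= hi
}

#' Structural statistics of an interaction network
#'
#' A *leader* follows no one (out-degree 0, nobody in his field of
#' attention); a *follower* follows at least one other male. Reported are:
#'
#' * `n_leaders`, `n_followers`;
#' * `leaders_per_follower`: mean, over followers, of the number of leaders
#'   *directly inside* the follower's field of attention (`NA` with
#'   `leaders_per_follower_defined = FALSE` when there are no followers);
#' * `leaders_per_follower_influence`: mean, over followers, of the number
#'   of distinct leaders from which a directed chain of attention reaches
#'   the follower (the follower watches someone who watches ... a leader).
#'   Two or more unsynchronized leaders driving one follower make the
#'   group's synchronization impossible, so this count peaks together with
#'   the asynchrony band at intermediate densities;
#' * `reciprocal_per_participant`: mean number of reciprocal (bidirectional)
#'   couplings per individual having at least one;
#' * `component_sizes`: sizes of the connected components of the undirected
#'   projection (the "unlinked groups" of displaying males).
#'
#' With `central_only = TRUE` the leaders-per-follower average is restricted
#' to followers inside the centered `L_c x L_c` subgrid, which removes
#' lattice-boundary effects; the counted leaders may sit anywhere.
#'
#' @param net An `"interaction_network"`.
#' @param pop The population the network was built from.
#' @param central_only Restrict the leaders-per-follower mean to
#'   central-subgrid followers?
#' @return A list of class `"network_stats"`.
#' @export
network_statistics <- function(net, pop, central_only = TRUE) {
  stopifnot(inherits(net, "interaction_network"),
            inherits(pop, "crab_population"))
  is_leader <- net$out_degree == 0L
  is_follower <- !is_leader
  followers <- which(if (central_only) is_follower & central_index(pop)
                     else is_follower)
  lpf <- NA_real_
  lpf_inf <- NA_real_
  if (length(followers) > 0L) {
    lpf <- mean(vapply(followers, function(i) {
      sum(is_leader[net$adjacency[[i]]])
    }, numeric(1)))
    # influence count: BFS backwards from each leader along "is watched by"
    gd <- igraph::graph_from_data_frame(
      net$edges[, c("from", "to")], directed = TRUE,
      vertices = data.frame(name = seq_len(net$n)))
    influenced_by <- integer(net$n)
    for (l in which(is_leader)) {
      reach <- as.integer(names(igraph::subcomponent(gd, l, mode = "in")))
      influenced_by[reach] <- influenced_by[reach] + 1L
    }
    influenced_by[is_leader] <- 0L  # a leader influences, he is not influenced
    lpf_inf <- mean(influenced_by[followers])
  }
  recip_edges <- net$edges[net$edges$reciprocal, , drop = FALSE]
  recip_count <- tabulate(recip_edges$from, nbins = net$n)
  participants <- recip_count > 0L
  rpp <- if (any(participants)) mean(recip_count[participants]) else NA_real_
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(net$n))
  )
  comp <- igraph::components(g)
  structure(list(
    n_leaders = sum(is_leader),
    n_followers = sum(is_follower),
    leaders_per_follower = lpf,
    leaders_per_follower_influence = lpf_inf,
    leaders_per_follower_defined = length(followers) > 0L,
    reciprocal_per_participant = rpp,
    n_reciprocal_participants = sum(participants),
    component_sizes = sort(as.integer(comp$csize), decreasing = TRUE),
    central_only = central_only
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat("network stats: ", x$n_leaders, " leaders / ", x$n_followers,
      " followers\n  leaders per follower",
      if (x$central_only) " (central subgrid)" else "", ": ",
      if (x$leaders_per_follower_defined) signif(x$leaders_per_follower, 4)
      else "undefined (no followers)",
      "\n  leaders influencing each follower (via chains): ",
      if (x$leaders_per_follower_defined)
        signif(x$leaders_per_follower_influence, 4)
      else "undefined (no followers)",
      "\n  reciprocal couplings per participant: ",
      if (is.na(x$reciprocal_per_participant)) "undefined (none)"
      else signif(x$reciprocal_per_participant, 4),
      "\n  components: ", length(x$component_sizes), " (largest ",
      max(x$component_sizes), ")\n", sep = "")
  invisible(x)
}

#' Replicate network statistics over random placements
#'
#' Generates `replicates` independent populations under one configuration,
#' orients them with the chosen model, and collects the network statistics
#' of each, plus their means. This is the Monte-Carlo estimator behind the
#' leaders-per-follower and reciprocal-coupling density curves.
#'
#' @param grid A [grid_config()].
#' @param model `"M1"` or `"M2"`.
#' @param theta,R Sector parameters.
#' @param replicates Number of independent placements.
#' @param seed Master seed; each replicate receives an independent child
#'   seed so results do not depend on evaluation order.
#' @param central_only Passed to [network_statistics()].
#' @return A list with `per_replicate` (data frame, one row per replicate)
#'   and `summary` (means over replicates; the leaders-per-follower mean
#'   skips replicates where it is undefined).
#' @export
replicate_network_stats <- function(grid, model = c("M1", "M2"), theta = 60,
                                    R = 3, replicates = 500L, seed = NULL,
                                    central_only = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(grid, "grid_config"))
  seeds <- spawn_seeds(replicates, seed)
  rows <- lapply(seq_len(replicates), function(k) {
    set.seed(seeds[k])
    pop <- place_individuals(grid)
    pop <- if (model == "M1") orient_random(pop, theta, R)
           else orient_preferential(pop, theta, R)
    st <- network_statistics(build_network(pop), pop, central_only)
    data.frame(
      replicate = k,
      n_leaders = st$n_leaders,
      n_followers = st$n_followers,
      leaders_per_follower = st$leaders_per_follower,
      leaders_per_follower_influence = st$leaders_per_follower_influence,
      reciprocal_per_participant = st$reciprocal_per_participant,
      n_components = length(st$component_sizes),
      largest_component = max(st$component_sizes)
    )
  })
  per_rep <- do.call(rbind, rows)
  list(
    per_replicate = per_rep,
    summary = list(
      leaders_per_follower = mean(per_rep$leaders_per_follower, na.rm = TRUE),
      leaders_per_follower_influence =
        mean(per_rep$leaders_per_follower_influence, na.rm = TRUE),
      reciprocal_per_participant =
        mean(per_rep$reciprocal_per_participant, na.rm = TRUE),
      mean_n_leaders = mean(per_rep$n_leaders),
      replicates = replicates
    )
  )
}
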