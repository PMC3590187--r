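test_that("grid_config validates and sizes the population", {
  expect_equal(grid_config(30, 10, 0.4)$n_ind, 360L)
  expect_equal(grid_config(30, 10, 1.0)$n_ind, 900L)
  expect_error(grid_config(30, 10, 1.3), "rho")
  expect_error(grid_config(30, 10, 0), "rho")
  expect_error(grid_config(10, 12, 0.5), "L_c")
  expect_error(grid_config(2, 1, 0.05), "empty population")
})

test_that("placement fills distinct sites and is seed-reproducible", {
  grid <- grid_config(30, 10, 0.4)
  pop <- place_individuals(grid, seed = 3)
  expect_equal(nrow(pop), 360)
  expect_false(any(duplicated(pop[, c("x", "y")])))
  expect_true(all(pop$x >= 0 & pop$x < 30 & pop$y >= 0 & pop$y < 30))
  expect_identical(place_individuals(grid, seed = 3), pop)

  full <- place_individuals(grid_config(30, 10, 1.0), seed = 1)
  expect_equal(nrow(unique(full[, c("x", "y")])), 900)
})

test_that("in_sector applies inclusive distance and angle boundaries", {
  # target exactly at distance R along the axis: inside
  expect_true(in_sector(c(0, 0), 0, c(3, 0), R = 3, theta = 60))
  # just beyond the reach: outside
  expect_false(in_sector(c(0, 0), 0, c(3 + 1e-6, 0), R = 3, theta = 60))
  # exactly on the angular edge (theta/2 off axis): inside
  edge <- c(cos(pi / 6), sin(pi / 6)) * 2
  expect_true(in_sector(c(0, 0), 0, edge, R = 3, theta = 60))
  # slightly past the angular edge: outside
  past <- c(cos(pi / 6 + 1e-4), sin(pi / 6 + 1e-4)) * 2
  expect_false(in_sector(c(0, 0), 0, past, R = 3, theta = 60))
  # theta = 360: any target within reach, regardless of direction
  expect_true(in_sector(c(0, 0), 123, c(-2, -1), R = 3, theta = 360))
  expect_error(in_sector(c(1, 1), 0, c(1, 1), R = 3, theta = 60), "self")
})

test_that("random orientation is uniform and seed-stable", {
  pop <- place_individuals(grid_config(30, 10, 0.4), seed = 5)
  o1 <- orient_random(pop, seed = 9)
  expect_identical(orient_random(pop, seed = 9), o1)
  expect_true(all(o1$phi >= 0 & o1$phi < 360))

  big <- make_population(rep(0, 1), rep(0, 1), L = 100)
  set.seed(21)
  draws <- replicate(10000, orient_random(big)$phi)
  expect_gt(ks.test(draws, "punif", 0, 360)$p.value, 0.01)
})

test_that("preferential orientation points at a lone neighbor", {
  pop <- make_population(c(5, 7), c(5, 5))
  set.seed(2)
  o <- orient_preferential(pop, theta = 60, R = 3)
  net <- build_network(o)
  expect_true(all(net$out_degree == 1L))  # each sees the other: reciprocal
  expect_true(all(net$edges$reciprocal))
})

test_that("equally good orientations are chosen with equal probability", {
  # two candidates at distance 2, opposite directions; theta = 60 cannot
  # cover both, so each covered set {left} / {right} should win half the time
  pop <- make_population(c(5, 3, 7), c(5, 5, 5))
  set.seed(33)
  toward_right <- replicate(2000, {
    o <- orient_preferential(pop, theta = 60, R = 3)
    ang_offset(o$phi[1], 0) < 90
  })
  expect_lt(abs(mean(toward_right) - 0.5), 0.05)
})

test_that("similarity tie-break picks the set waving most like the focal male", {
  pop <- make_population(c(5, 3, 7), c(5, 5, 5))
  disp <- c(0.50, 0.10, 0.52)   # right-hand neighbor waves like the focal male
  o <- orient_preferential(pop, theta = 60, R = 3, seed = 1,
                           tie_rule = "similarity", displacement = disp)
  expect_lt(ang_offset(o$phi[1], 0), 90)  # oriented toward individual 3
})

test_that("preferential orientation attains the true maximum coverage", {
  # oracle: the classic maximum-points-in-a-closed-arc sweep — the largest
  # number of neighbor directions inside any closed arc of width theta
  oracle_max_cover <- function(pop, i, R, theta) {
    dx <- pop$x - pop$x[i]; dy <- pop$y - pop$y[i]
    d2 <- dx^2 + dy^2
    nb <- which(d2 > 0 & d2 <= R^2)
    if (!length(nb)) return(0L)
    dirs <- atan2(dy[nb], dx[nb]) * 180 / pi
    max(vapply(dirs, function(d0) {
      sum(((dirs - d0) %% 360) <= theta + 1e-9)
    }, numeric(1)))
  }
  set.seed(14)
  for (k in 1:15) {
    pop <- place_individuals(grid_config(12, 4, runif(1, 0.1, 0.5)))
    theta <- sample(c(40, 60, 90), 1)
    o <- orient_preferential(pop, theta = theta, R = 3)
    net <- build_network(o)
    for (i in seq_len(nrow(pop))) {
      expect_identical(net$out_degree[i],
                       as.integer(oracle_max_cover(pop, i, 3, theta)))
    }
  }
})

test_that("M2 never couples fewer individuals than M1 on the same positions", {
  set.seed(8)
  for (k in 1:10) {
    pop <- place_individuals(grid_config(15, 5, 0.3))
    m1 <- build_network(orient_random(pop, theta = 60, R = 3))
    m2 <- build_network(orient_preferential(pop, theta = 60, R = 3))
    expect_true(all(m2$out_degree >= 0))
    expect_gte(nrow(m2$edges), nrow(m1$edges))
    # every individual with someone in reach is a follower under M2
    d2 <- outer(pop$x, pop$x, "-")^2 + outer(pop$y, pop$y, "-")^2
    has_nb <- rowSums(d2 > 0 & d2 <= 9) > 0
    expect_true(all(m2$out_degree[has_nb] >= 1L))
  }
})

test_that("at theta = 360 both orientation rules give the same network", {
  pop <- place_individuals(grid_config(15, 5, 0.3), seed = 4)
  n1 <- build_network(orient_random(pop, theta = 360, R = 3, seed = 1))
  n2 <- build_network(orient_preferential(pop, theta = 360, R = 3, seed = 99))
  expect_identical(n1$edges[, c("from", "to")], n2$edges[, c("from", "to")])
  # and participation is symmetric: isolated individuals have no edges at all
  iso <- which(n1$out_degree == 0L)
  expect_false(any(n1$edges$to %in% iso))
})

test_that("a full lattice with global attention has no leaders", {
  pop <- place_individuals(grid_config(5, 3, 1.0), seed = 2)
  net <- build_network(orient_random(pop, theta = 360, R = 3))
  expect_identical(sum(net$out_degree == 0L), 0L)
})

test_that("network statistics handle the isolated reciprocal pair", {
  pn <- make_pair_network()
  st <- network_statistics(pn$net, pn$pop, central_only = FALSE)
  expect_equal(st$n_leaders, 0)
  expect_equal(st$n_followers, 2)
  expect_equal(st$reciprocal_per_participant, 1)
  expect_equal(st$component_sizes, 2L)
  expect_equal(st$leaders_per_follower, 0)
  expect_equal(st$leaders_per_follower_influence, 0)
})

test_that("leaders-per-follower is undefined without followers", {
  pop <- make_population(c(1, 20), c(1, 20), phi = c(0, 0))
  st <- network_statistics(build_network(pop), pop, central_only = FALSE)
  expect_false(st$leaders_per_follower_defined)
  expect_true(is.na(st$leaders_per_follower))
  expect_equal(st$n_leaders, 2)
})

test_that("M2 reorientation leaves no leader inside any follower's view", {
  # under M2 the only possible leaders are isolated males (no one within
  # reach); by distance symmetry they sit in nobody's field of attention,
  # so the leaders-per-follower statistic is exactly zero at every density
  for (rho in c(0.1, 0.3, 0.65)) {
    seeds <- spawn_seeds(5, round(100 * rho))
    for (s in seeds) {
      set.seed(s)
      pop <- place_individuals(grid_config(15, 5, rho))
      net <- build_network(orient_preferential(pop, theta = 60, R = 3))
      d2 <- outer(pop$x, pop$x, "-")^2 + outer(pop$y, pop$y, "-")^2
      isolated <- rowSums(d2 > 0 & d2 <= 9) == 0
      expect_true(all(isolated[net$out_degree == 0L]))
      st <- network_statistics(net, pop, central_only = FALSE)
      if (st$leaders_per_follower_defined) {
        expect_identical(st$leaders_per_follower, 0)
        expect_identical(st$leaders_per_follower_influence, 0)
      }
    }
  }
})

test_that("a follower chain is counted once per influencing leader", {
  # leader (no one in reach ahead) <- middle <- tail: the tail follower is
  # influenced by one leader through the chain, directly sees none
  pop <- make_population(c(4, 6, 8), c(5, 5, 5), phi = c(0, 0, 0), theta = 60)
  net <- build_network(pop)
  expect_identical(net$out_degree, c(1L, 1L, 0L))
  st <- network_statistics(net, pop, central_only = FALSE)
  expect_equal(st$leaders_per_follower, 0.5)           # only middle sees him
  expect_equal(st$leaders_per_follower_influence, 1)   # both are influenced
})

test_that("literal boundary handling cuts off overhanging sectors", {
  # crab at the edge looking outward: sector leaves the lattice
  pop <- make_population(c(0, 1), c(5, 5), phi = c(180, 180), theta = 60)
  clip <- build_network(pop, boundary = "clip")
  lit <- build_network(pop, boundary = "literal")
  expect_identical(clip$out_degree, c(0L, 1L))  # 2 watches 1 under clipping
  expect_identical(lit$out_degree, c(0L, 0L))   # 2's sector overhangs: cut
  # an interior sector pointing inward is unaffected
  pop2 <- make_population(c(10, 9), c(10, 10), phi = c(180, 180), theta = 60)
  expect_identical(build_network(pop2, boundary = "literal")$out_degree,
                   build_network(pop2, boundary = "clip")$out_degree)
})
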