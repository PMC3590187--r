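test_that("simulation_config validates every field it documents", {
  expect_error(simulation_config(mu = 4.5), "mu")
  expect_error(simulation_config(D = -0.1), "D")
  expect_error(simulation_config(D = 1.1), "D")
  expect_error(simulation_config(grid = grid_config(30, 10, 0.4), n_l = 1),
               "n_l")
  expect_error(simulation_config(s_t = 0), "s_t")
  expect_error(simulation_config(seed = 1.5), "seed")
  cfg <- simulation_config()
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$R, 3)
  expect_equal(cfg$grid$L, 30L)
  expect_equal(cfg$grid$L_c, 10L)
})

test_that("neighborhood_mean averages the watched individuals", {
  pn <- make_pair_network()
  state <- c(0.3, 0.7)
  expect_equal(neighborhood_mean(state, pn$net, 1), 0.7)  # single neighbor
  expect_equal(neighborhood_mean(state, pn$net, 1, variant = "distance-weighted"),
               0.7)

  # three in a row, middle sees both ends at distance 1: plain mean
  pop <- make_population(c(9, 10, 11), c(10, 10, 10),
                         phi = c(0, 0, 180), theta = 360, R = 1)
  net <- build_network(pop)
  expect_equal(neighborhood_mean(c(0.4, 0.1, 0.4), net, 2), 0.4)
  # unequal distances: weights proportional to 1/d
  pop2 <- make_population(c(8, 10, 11), c(10, 10, 10),
                          phi = c(0, 0, 180), theta = 360, R = 2)
  net2 <- build_network(pop2)
  w <- c(1 / 2, 1) / (1 / 2 + 1)
  expect_equal(
    neighborhood_mean(c(0.2, 0.5, 0.8), net2, 2, variant = "distance-weighted"),
    sum(w * c(0.2, 0.8)))
  # leader: no neighborhood mean
  lonely <- make_population(c(1, 20), c(1, 20), phi = c(0, 0))
  expect_true(is.na(neighborhood_mean(c(0.5, 0.5), build_network(lonely), 1)))
})

test_that("D = 0 decouples the lattice into independent logistic maps", {
  pn <- make_pair_network()
  state <- c(0.25, 0.9)
  expect_equal(coupled_step(state, pn$net, mu = 3.7, D = 0),
               logistic_step(state, 3.7))
})

test_that("a synchronized population stays synchronized", {
  set.seed(6)
  pop <- place_individuals(grid_config(12, 4, 0.4))
  net <- build_network(orient_random(pop, theta = 60, R = 3))
  for (form in c("map-of-mean", "mean-of-map")) {
    for (variant in c("plain", "distance-weighted")) {
      x <- rep(0.37, net$n)
      for (k in 1:20) {
        x <- coupled_step(x, net, mu = 3.9, D = 0.6, variant = variant,
                          coupling_form = form)
        expect_equal(max(x) - min(x), 0)
      }
    }
  }
})

test_that("a mutually coupled pair equalizes in one step at D = 0.5", {
  pn <- make_pair_network()
  set.seed(12)
  for (k in 1:20) {
    out <- coupled_step(runif(2), pn$net, mu = runif(1, 1.5, 4), D = 0.5)
    expect_equal(out[1], out[2])
  }
})

test_that("states stay in [0, 1] on random networks and parameters", {
  set.seed(19)
  for (k in 1:10) {
    pop <- place_individuals(grid_config(10, 4, runif(1, 0.1, 0.9)))
    net <- build_network(orient_random(pop, theta = sample(c(60, 360), 1),
                                       R = 3))
    x <- runif(net$n)
    mu <- runif(1, 1.1, 4)
    D <- runif(1)
    for (s in 1:50) {
      x <- coupled_step(x, net, mu, D)
      expect_true(all(x >= 0 & x <= 1))
    }
  }
})

test_that("two-node dynamics agree with the pair analytics at every step", {
  pn <- make_pair_network()
  # leader-follower geometry: 1 watches 2, 2 looks away
  pop_lf <- make_population(c(10, 11), c(10, 10), phi = c(0, 0))
  net_lf <- build_network(pop_lf)
  expect_identical(net_lf$out_degree, c(1L, 0L))
  set.seed(23)
  for (k in 1:25) {
    mu <- runif(1, 1.5, 4); D <- runif(1)
    lattice_bi <- runif(2)
    pair_bi <- pair_state(lattice_bi[1], lattice_bi[2])
    lattice_lf <- runif(2)
    pair_lf <- pair_state(lattice_lf[1], lattice_lf[2])
    for (s in 1:30) {
      lattice_bi <- coupled_step(lattice_bi, pn$net, mu, D)
      pair_bi <- pair_step(pair_bi, mu, D, "bidirectional")
      lattice_lf <- coupled_step(lattice_lf, net_lf, mu, D)
      pair_lf <- pair_step(pair_lf, mu, D, "leader-follower")
    }
    expect_equal(lattice_bi, c(pair_bi$x_i, pair_bi$x_j), tolerance = 1e-12)
    expect_equal(lattice_lf, c(pair_lf$x_i, pair_lf$x_j), tolerance = 1e-12)
  }
})

test_that("run_simulation is a pure function of config and seed", {
  cfg <- simulation_config(grid = grid_config(12, 4, 0.4), n_transient = 50,
                           n_l = 40, s_t = 1, seed = 77)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$traj, b$traj)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$population$phi, b$population$phi)
  c <- run_simulation(cfg, seed = 78)
  expect_false(identical(a$traj, c$traj))
})

test_that("lattice individuals inherit the period-two dynamics at mu = 3.2", {
  cfg <- simulation_config(mu = 3.2, D = 0.5, grid = grid_config(30, 10, 0.4),
                           model = "M1", n_transient = 500, n_l = 200,
                           seed = 101)
  sim <- run_simulation(cfg)
  periods <- apply(sim$traj[-1, ], 2, function(v) {
    detect_period(v, tol = 1e-6)$period
  })
  # every individual waves with period two; a few land on the zero-amplitude
  # (constant) version of the same orbit, reported as its divisor 1
  expect_true(all(periods %in% c(1L, 2L)))
  expect_gt(mean(periods == 2L), 0.9)
  # not all individuals share the same pair of orbit values
  orbit_pairs <- unique(round(t(tail(sim$traj, 2)), 6))
  expect_gt(nrow(orbit_pairs), 1)
})
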