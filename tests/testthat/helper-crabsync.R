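# Shared fixture builders: populations with hand-placed individuals and
# hand-set orientations, so geometric expectations can be written exactly.

# population at explicit coordinates (no randomness)
make_population <- function(x, y, L = 30L, L_c = 10L,
                            phi = rep(NA_real_, length(x)),
                            theta = 60, R = 3, model = "M1") {
  stopifnot(length(x) == length(y))
  grid <- structure(list(L = as.integer(L), L_c = as.integer(L_c),
                         rho = length(x) / L^2, n_ind = length(x)),
                    class = "grid_config")
  pop <- data.frame(id = seq_along(x), x = x, y = y, phi = phi)
  attr(pop, "grid") <- grid
  attr(pop, "theta") <- theta
  attr(pop, "R") <- R
  attr(pop, "model") <- model
  class(pop) <- c("crab_population", "data.frame")
  pop
}

# a mutually watching pair at distance 1
make_pair_network <- function(theta = 60, R = 3, L = 30L) {
  pop <- make_population(c(10, 11), c(10, 10), L = L,
                         phi = c(0, 180), theta = theta, R = R)
  list(pop = pop, net = build_network(pop))
}

# independent logistic iteration, used as an oracle against package paths
oracle_logistic <- function(x0, mu, n) {
  x <- x0
  for (k in seq_len(n)) x <- mu * x * (1 - x)
  x
}
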