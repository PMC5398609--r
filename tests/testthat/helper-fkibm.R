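# Shared fixtures for the test suite.  Everything is generated in code;
# parameter values mirror the idealised study conditions (dx = tau = 1,
# d0 = 0, theta = b0 / 10 for wave runs).

line_lattice <- function(n = 11, spacing = 1, mask = NULL)
  lattice_spec("line2", n, spacing = spacing, mask = mask)

rect_lattice <- function(nx = 5, ny = 4, spacing = 1, mask = NULL)
  lattice_spec("rect4", c(nx, ny), spacing = spacing, mask = mask)

hex_lattice <- function(nx = 7, ny = 7, spacing = 1, mask = NULL)
  lattice_spec("hex6", c(nx, ny), spacing = spacing, mask = mask)

# Independent finite-difference integrator of the 1-D growth-diffusion
# equation, written directly from the expected-update formula: logistic
# birth/death rates from the local density, survival-weighted transport
# (moved mass carries the survival factor 1 - delta), confining boundary.
# This is the oracle for the mean-field equivalence tests; it never calls
# the simulator.
fd_growth_diffusion_step <- function(N, b0, theta, d0, K, p) {
  beta <- b0 - (b0 - theta) * N / K
  delta <- d0 + (theta - d0) * N / K
  neg <- beta < 0
  delta[neg] <- delta[neg] - beta[neg]
  beta[neg] <- 0
  beta <- pmin(beta, 1)
  delta <- pmin(delta, 1)
  S <- (1 - delta) * N
  n <- length(N)
  inflow_left <- c(S[1] * p / 2, (p / 2) * S[-n])   # blocked edge slot stays
  inflow_right <- c((p / 2) * S[-1], S[n] * p / 2)
  beta * N + (1 - p) * S + inflow_left + inflow_right
}

# One replicated 1-D (or 2-D line-seeded) wave run returning the fitted
# speeds of `reps` independent realizations.
wave_speeds <- function(K, b0, reps, seed, dim = 1L, D = 0.2,
                        nx = 1000L, ny = 100L, stop_x = 300) {
  topo <- if (dim == 2L) "rect4" else "line2"
  lat <- lattice_spec(topo, if (dim == 2L) c(nx, ny) else nx)
  gp <- growth_params(b0, 0.1 * b0, 0, K)
  mp <- movement_params(D * n_neighbors(lat))
  init <- make_fixture(if (dim == 2L) "line_seed" else "point_seed",
                       lat, N0 = K)
  vapply(seq_len(reps), function(i) {
    set.seed(derive_seed(seed, i))
    sim <- simulate_wave(wave_state(lat, init, gp, mp), stop_x = stop_x)
    estimate_front_speed(sim$trace, 0.5)$v
  }, numeric(1))
}
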