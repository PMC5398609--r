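#' Parameters of the density-dependent stochastic birth-death process
#'
#' Per step, each of the `N` individuals in a cell gives birth with
#' probability `beta(N) = b0 - (b0 - theta) * N / K` and dies with
#' probability `delta(N) = d0 + (theta - d0) * N / K`.  At `N = K` both
#' equal the turnover `theta`, so `K` is the deterministic carrying
#' capacity and `theta` sets the magnitude of the demographic fluctuations
#' around it.  The deterministic growth rate is `r = (b0 - d0) / tau`.
#'
#' @param b0 small-population birth probability.
#' @param theta turnover: common birth/death probability at `N = K`; must
#'   satisfy `d0 < theta < b0`.
#' @param d0 small-population death probability (default 0).
#' @param K carrying capacity, individuals per cell, `>= 1`.
#' @param tau duration of one time step.
#' @return an object of class `growth_params`.
#' @examples
#' p <- growth_params(b0 = 0.8, theta = 0.4, K = 50)
#' effective_K_approx(p)  # 49.5
#' @export
growth_params <- function(b0, theta, d0 = 0, K, tau = 1) {
  stopifnot(is.numeric(b0), is.numeric(theta), is.numeric(d0), is.numeric(K),
            is.numeric(tau), length(b0) == 1L, length(theta) == 1L,
            length(d0) == 1L, length(K) == 1L, length(tau) == 1L)
  if (b0 <= 0 || b0 > 1) stop("'b0' must be in (0, 1]")
  if (d0 < 0 || d0 >= b0) stop("'d0' must satisfy 0 <= d0 < b0")
  if (theta <= d0 || theta >= b0) stop("'theta' must satisfy d0 < theta < b0")
  if (K < 1) stop("'K' must be >= 1")
  if (tau <= 0) stop("'tau' must be positive")
  structure(list(b0 = b0, theta = theta, d0 = d0, K = K, tau = tau),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("<growth_params> b0 =", format(x$b0), " theta =", format(x$theta),
      " d0 =", format(x$d0), " K =", format(x$K), " tau =", format(x$tau),
      " (r =", format(growth_rate(x)), "per unit time)\n")
  invisible(x)
}

#' Deterministic growth rate r = (b0 - d0) / tau
#' @param p a [growth_params()].
#' @return the growth rate per unit time.
#' @export
growth_rate <- function(p) (p$b0 - p$d0) / p$tau

#' Raw birth probability at local density N
#'
#' Linear decrease from `b0` at `N = 0` through `theta` at `N = K`; the raw
#' value becomes negative for `N > b0 * K / (b0 - theta)` and is folded into
#' the death rate by [effective_rates()].
#'
#' @param N local count (vectorised).
#' @param p a [growth_params()].
#' @return raw (unclamped) birth probability.
#' @export
birth_probability <- function(N, p) {
  stopifnot(all(N >= 0))
  p$b0 - (p$b0 - p$theta) * N / p$K
}

#' Raw death probability at local density N
#'
#' Linear increase from `d0` at `N = 0` through `theta` at `N = K`; values
#' above 1 (only reachable far above `K`) are clamped by
#' [effective_rates()].
#'
#' @inheritParams birth_probability
#' @return raw (unclamped) death probability.
#' @export
death_probability <- function(N, p) {
  stopifnot(all(N >= 0))
  p$d0 + (p$theta - p$d0) * N / p$K
}

#' Effective per-capita birth and death probabilities
#'
#' Negative raw birth rates are reinterpreted as additional mortality
#' (`delta* = |beta| + delta` when `beta < 0`, with `beta* = 0`), which
#' preserves the expected change `(beta - delta) N` and hence convergence to
#' logistic growth; both rates are clamped into \[0, 1\].
#'
#' @inheritParams birth_probability
#' @return list with numeric components `beta` and `delta`, each in
#'   \[0, 1\] and vectorised over `N`.
#' @export
effective_rates <- function(N, p) {
  beta <- birth_probability(N, p)
  delta <- death_probability(N, p)
  neg <- beta < 0
  delta[neg] <- delta[neg] - beta[neg]
  beta[neg] <- 0
  list(beta = pmin(beta, 1), delta = pmin(delta, 1))
}

#' One synchronous growth step
#'
#' Per cell, with `N` the start-of-step count and `(beta, delta)` its
#' effective rates: births ~ Binomial(N, beta) and deaths ~ Binomial(N,
#' delta) are drawn independently and the new count is `N + births -
#' deaths`.  Deaths are drawn among the `N` original individuals only
#' (newborns cannot die or reproduce in their birth step), but a dying
#' individual can still spawn, since the two draws are independent.  With
#' `deterministic = TRUE` the draws are replaced by their expectations,
#' which makes the map the Forward-Euler discretisation of the logistic
#' equation (counts then need not be integer).
#'
#' @param counts numeric vector (or array) of per-cell counts, `>= 0`.
#' @param p a [growth_params()].
#' @param deterministic replace binomial draws by their means.
#' @return updated counts, same shape as the input.
#' @export
step_growth <- function(counts, p, deterministic = FALSE) {
  stopifnot(all(counts >= 0))
  rates <- effective_rates(as.numeric(counts), p)
  if (deterministic) {
    new <- counts + (rates$beta - rates$delta) * counts
  } else {
    n <- as.integer(counts)
    births <- stats::rbinom(length(n), n, rates$beta)
    deaths <- stats::rbinom(length(n), n, rates$delta)
    new <- counts + births - deaths
  }
  new
}

#' Exact one-step transition kernel of the growth update
#'
#' The probability `T(M | N)` of moving from `N` to `M` individuals in one
#' step: births `b ~ Binomial(N, beta)` and deaths `d ~ Binomial(N, delta)`
#' are independent, and `M = N + b - d`, so the kernel is the convolution of
#' the birth distribution with the reflected death distribution, supported
#' on `0..2N` (no more than `N` individuals can be born because each
#' individual spawns at most once per step).
#'
#' @param N current count.
#' @param p a [growth_params()].
#' @return object of class `transition_kernel`: list with the origin state
#'   `N`, the support `states = 0:(2N)` and the probability vector `prob`
#'   over it (sums to 1).
#' @examples
#' # with beta = delta = 1/2 at N = 2 (e.g. theta = 0.5, K = 2):
#' k <- transition_kernel(2, growth_params(b0 = 1, theta = 0.5, K = 2))
#' k$prob[k$states == 3]  # 0.25
#' @export
transition_kernel <- function(N, p) {
  N <- as.integer(N)
  stopifnot(length(N) == 1L, N >= 0L)
  if (N == 0L) {
    prob <- 1
  } else {
    rates <- effective_rates(N, p)
    pb <- stats::dbinom(0:N, N, rates$beta)   # births
    pd <- stats::dbinom(0:N, N, rates$delta)  # deaths
    # M = N + b - d ranges over 0..2N; convolve birth with reflected death
    prob <- numeric(2L * N + 1L)
    for (b in 0:N)
      prob[(b + 1L):(b + N + 1L)] <- prob[(b + 1L):(b + N + 1L)] +
        pb[b + 1L] * rev(pd)
  }
  structure(list(N = N, states = 0:(2L * max(N, 0L)), prob = prob),
            class = "transition_kernel")
}

#' @export
print.transition_kernel <- function(x, ...) {
  cat("<transition_kernel> from N =", x$N, "over M = 0..", max(x$states),
      "\n")
  print(stats::setNames(x$prob, x$states))
  invisible(x)
}

#' Truncated transition matrix of the growth update
#'
#' Column `N + 1` holds `T(M | N)` for `M = 0..N_max`; probability mass
#' falling beyond the truncation (`M > N_max`) is reported per column in
#' the `"leak"` attribute.  With the default `N_max = 4 K` the binomial
#' tails make the leak negligible for states with non-negligible mass.
#'
#' @param p a [growth_params()].
#' @param N_max truncation state (default `4 * K`).
#' @return `(N_max + 1) x (N_max + 1)` matrix, columns indexed by the
#'   origin state `N = 0..N_max`, with attribute `leak`.
#' @export
transition_matrix <- function(p, N_max = 4 * p$K) {
  N_max <- as.integer(N_max)
  Tm <- matrix(0, N_max + 1L, N_max + 1L)
  leak <- numeric(N_max + 1L)
  for (N in 0:N_max) {
    k <- transition_kernel(N, p)
    keep <- k$states <= N_max
    Tm[k$states[keep] + 1L, N + 1L] <- k$prob[keep]
    leak[N + 1L] <- sum(k$prob[!keep])
  }
  attr(Tm, "leak") <- leak
  Tm
}

#' Probability-vector state of the master equation
#'
#' @param prob probability vector over counts `N = 0..N_max` (normalised to
#'   1 within 1e-12).
#' @param time step index.
#' @return an object of class `master_equation_state`.
#' @export
master_equation_state <- function(prob, time = 0L) {
  prob <- as.numeric(prob)
  if (any(prob < 0) || abs(sum(prob) - 1) > 1e-12)
    stop("'prob' must be a normalised probability vector")
  structure(list(prob = prob, N_max = length(prob) - 1L,
                 time = as.integer(time)),
            class = "master_equation_state")
}

#' @export
print.master_equation_state <- function(x, ...) {
  cat("<master_equation_state> N_max =", x$N_max, " step", x$time,
      " mean =", format(master_equation_mean(x)), "\n")
  invisible(x)
}

#' Mean of a master-equation state
#'
#' @param state a [master_equation_state()].
#' @param exclude_zero condition on non-extinction (renormalise after
#'   dropping the absorbing `N = 0` mass)?
#' @return the expected count.
#' @export
master_equation_mean <- function(state, exclude_zero = FALSE) {
  pr <- state$prob
  if (exclude_zero) {
    pr[1] <- 0
    pr <- pr / sum(pr)
  }
  sum((0:state$N_max) * pr)
}

#' Advance the master equation by one step
#'
#' Multiplies the state by the (truncated) transition matrix.  Mass is
#' conserved exactly up to the truncation leak; if the leaked mass in one
#' step exceeds `leak_tol` a warning reports it.
#'
#' @param state a [master_equation_state()].
#' @param p a [growth_params()].
#' @param Tm optional precomputed [transition_matrix()] with
#'   `N_max = state$N_max` (recomputed otherwise; precompute when
#'   iterating).
#' @param leak_tol tolerance on per-step leaked mass (default 1e-10).
#' @return the state one step later.
#' @export
master_equation_step <- function(state, p, Tm = NULL, leak_tol = 1e-10) {
  if (is.null(Tm)) Tm <- transition_matrix(p, state$N_max)
  new <- as.numeric(Tm %*% state$prob)
  lost <- sum(state$prob) - sum(new)
  if (lost > leak_tol)
    warning(sprintf("truncation leak of %.3g probability mass in one step",
                    lost))
  state$prob <- new
  state$time <- state$time + 1L
  state
}

#' Iterate the master equation
#'
#' @inheritParams master_equation_step
#' @param n_steps number of steps.
#' @return the final [master_equation_state()].
#' @export
master_equation_run <- function(state, p, n_steps, leak_tol = 1e-10) {
  Tm <- transition_matrix(p, state$N_max)
  total_leak <- 0
  for (i in seq_len(n_steps)) {
    new <- as.numeric(Tm %*% state$prob)
    total_leak <- total_leak + sum(state$prob) - sum(new)
    state$prob <- new
    state$time <- state$time + 1L
  }
  if (total_leak > leak_tol)
    warning(sprintf("truncation leak of %.3g probability mass over %d steps",
                    total_leak, n_steps))
  state
}

#' Renshaw-style approximation of the effective carrying capacity
#'
#' The mean steady-state count of the stochastic logistic model lies below
#' `K` because fluctuations interact with the curvature of the logistic
#' map: `<N> ~ K - 2 theta (1 - theta) / (2 r - r^2)`, with `r = b0 - d0`
#' the per-step growth probability.  At `theta = b0 / 2` (and `d0 = 0`) the
#' deviation is exactly 1/2 for every `b0`; as `theta -> 0` it reduces to
#' the continuous-time one-step value `2 theta / (2 r - r^2)`.
#'
#' @param p a [growth_params()].
#' @return the approximate expected steady-state count.
#' @export
effective_K_approx <- function(p) {
  r <- p$b0 - p$d0  # per-step growth probability
  if (r <= 0 || r >= 2) stop("per-step growth probability must be in (0, 2)")
  p$K - 2 * p$theta * (1 - p$theta) / (2 * r - r^2)
}

#' Dimensionless deviation of the effective carrying capacity
#'
#' With `d0 = 0` and `alpha = theta / b0`, the deviation `K - <N>` equals
#' `f = 2 alpha (1 - alpha b0) / (2 - b0)`, independent of `K`.  All curves
#' over `b0` intersect at `alpha = 1/2` where `f = 1/2`; for `b0 > 0.5` the
#' deviation is maximal where `alpha * b0 = 0.5` (the variance of a
#' binomial is largest at success probability one half).
#'
#' @param alpha turnover ratio `theta / b0`, in (0, 1).
#' @param b0 small-population birth probability, in (0, 1\].
#' @return the deviation `f` (individuals), vectorised over `alpha`.
#' @export
deviation_term <- function(alpha, b0) {
  stopifnot(all(alpha >= 0), all(alpha < 1), b0 > 0, b0 <= 1)
  2 * alpha * (1 - alpha * b0) / (2 - b0)
}

#' Estimate the effective carrying capacity by simulation
#'
#' Runs `n_realizations` independent single-cell growth trajectories from
#' `N0 = K` for `n_steps` steps, discards the first `burn_in` steps and
#' averages `N` over time and realizations.  Realizations that hit the
#' absorbing state `N = 0` are excluded from the average (their count is
#' reported); the SEM is taken across the per-realization time means.
#'
#' @param p a [growth_params()].
#' @param n_realizations number of independent trajectories.
#' @param n_steps steps per trajectory.
#' @param burn_in steps discarded before averaging (`0 <= burn_in <
#'   n_steps`).
#' @param seed optional integer seed for reproducibility.
#' @return object of class `effective_K_estimate`: list with `mean`, `sem`,
#'   `n_realizations`, `n_surviving`, `n_extinct` and `burn_in`.
#' @export
estimate_effective_K <- function(p, n_realizations = 100, n_steps = 500,
                                 burn_in = 100, seed = NULL) {
  stopifnot(n_steps > burn_in, burn_in >= 0)
  if (!is.null(seed)) set.seed(seed)
  counts <- rep(as.integer(round(p$K)), n_realizations)
  sums <- numeric(n_realizations)
  extinct <- logical(n_realizations)
  kept <- 0L
  for (s in seq_len(n_steps)) {
    counts <- step_growth(counts, p)
    extinct <- extinct | counts == 0L
    if (s > burn_in) {
      sums <- sums + counts
      kept <- kept + 1L
    }
  }
  means <- sums / kept
  alive <- !extinct
  if (!any(alive))
    stop("all realizations went extinct; cannot estimate the effective ",
         "carrying capacity")
  m <- means[alive]
  structure(
    list(mean = mean(m),
         sem = if (length(m) > 1L) stats::sd(m) / sqrt(length(m)) else NA_real_,
         n_realizations = n_realizations,
         n_surviving = sum(alive), n_extinct = sum(extinct),
         burn_in = burn_in),
    class = "effective_K_estimate")
}

#' @export
print.effective_K_estimate <- function(x, ...) {
  cat("<effective_K_estimate> <N> =", format(x$mean), "+/-", format(x$sem),
      " (", x$n_surviving, "of", x$n_realizations, "realizations surviving)\n")
  invisible(x)
}
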