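#' State of the growth-diffusion simulation
#'
#' Per-cell integer counts on a lattice, together with the growth and
#' movement parameters.  Counts on masked cells must be zero.
#'
#' @param lattice a [lattice_spec()].
#' @param counts numeric vector or matrix of per-cell counts, one entry per
#'   cell (`counts[x + 1]`, or `counts[x + 1, y + 1]` in 2-D).
#' @param growth a [growth_params()].
#' @param movement a [movement_params()].
#' @param step step index.
#' @return an object of class `wave_state`.
#' @export
wave_state <- function(lattice, counts, growth, movement, step = 0L) {
  nx <- lattice$shape[1]
  ny <- if (length(lattice$shape) == 2L) lattice$shape[2] else 1L
  counts <- matrix(as.numeric(counts), nrow = nx, ncol = ny)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(lattice$mask) && any(counts[!lattice$mask] != 0))
    stop("masked cells must hold zero individuals")
  structure(list(lattice = lattice, counts = counts, growth = growth,
                 movement = movement, step = as.integer(step)),
            class = "wave_state")
}

#' @export
print.wave_state <- function(x, ...) {
  cat("<wave_state>", sum(x$counts), "individuals on a", x$lattice$topology,
      "lattice", paste(x$lattice$shape, collapse = " x "),
      " step", x$step, "\n")
  invisible(x)
}

# Logical matrix per direction: TRUE where a move in that direction lands on
# an accessible (in-domain, unmasked) cell.  Blocked directions make the
# mover stay, which realises the anisotropy-corrected movement probability.
open_direction_masks <- function(lattice) {
  nx <- lattice$shape[1]
  ny <- if (length(lattice$shape) == 2L) lattice$shape[2] else 1L
  off <- neighbor_offsets(lattice)
  xs <- rep(0:(nx - 1L), times = ny)
  ys <- rep(if (ny > 1L) 0:(ny - 1L) else 0L, each = nx)
  lapply(seq_len(nrow(off)), function(d) {
    tgt <- cbind(xs + off[d, 1], if (ncol(off) == 2L) ys + off[d, 2] else NULL)
    if (ncol(off) == 1L) tgt <- tgt[, 1, drop = FALSE]
    matrix(is_accessible(lattice, tgt), nrow = nx, ncol = ny)
  })
}

# Shift a count matrix by one lattice offset with zero fill: mass at source
# (i, j) appears at (i + di, j + dj).
shift_counts <- function(m, di, dj = 0L) {
  out <- matrix(0, nrow(m), ncol(m))
  si <- seq_len(nrow(m))
  sj <- seq_len(ncol(m))
  from_i <- si[si + di >= 1L & si + di <= nrow(m)]
  from_j <- sj[sj + dj >= 1L & sj + dj <= ncol(m)]
  out[from_i + di, from_j + dj] <- m[from_i, from_j]
  out
}

# Binomial draw vectorised over a count matrix, drawing only where size > 0.
rbinom_counts <- function(n, prob) {
  out <- numeric(length(n))
  idx <- which(n > 0)
  if (length(idx))
    out[idx] <- stats::rbinom(length(idx), n[idx],
                              if (length(prob) == 1L) prob else prob[idx])
  matrix(out, nrow(n), ncol(n))
}

#' One synchronous growth-diffusion step
#'
#' All decisions are drawn from the start-of-step local counts: per cell,
#' births ~ Binomial(N, beta) and deaths ~ Binomial(N, delta) are drawn
#' independently ([effective_rates()]); the `N - deaths` survivors then each
#' move with per-direction probability `p_move / n_neighbors` (a move into a
#' masked or off-domain slot means staying, i.e. the anisotropy-corrected
#' probability); newborns appear in the parent's start-of-step cell and do
#' not move until the next step.  Draws are made cell-major (column-major
#' over the count array), one draw type at a time: births, deaths, then the
#' per-direction movement splits.
#'
#' With `deterministic = TRUE` every draw is replaced by its expectation;
#' the resulting map is an explicit finite-difference integrator of the
#' growth-diffusion (Fisher-Kolmogorov) equation in which transported mass
#' carries the survival factor `(1 - delta)`.  With `p_move = 0` the step
#' reduces exactly to [step_growth()]; with growth switched off it reduces
#' to pure movement.
#'
#' @param state a [wave_state()].
#' @param deterministic replace draws by their means (counts become
#'   continuous).
#' @param open optional precomputed result of the internal per-direction
#'   accessibility masks; passed by [simulate_wave()] to avoid recomputation.
#' @return the state one step later.
#' @export
step_growth_diffusion <- function(state, deterministic = FALSE, open = NULL) {
  lat <- state$lattice
  N <- state$counts
  rates <- effective_rates(as.numeric(N), state$growth)
  beta <- matrix(rates$beta, nrow(N), ncol(N))
  delta <- matrix(rates$delta, nrow(N), ncol(N))
  if (deterministic) {
    births <- beta * N
    deaths <- delta * N
  } else {
    births <- rbinom_counts(N, rates$beta)
    deaths <- rbinom_counts(N, rates$delta)
  }
  survivors <- N - deaths

  ndir <- n_neighbors(lat)
  p_dir <- state$movement$p_move / ndir
  if (is.null(open)) open <- open_direction_masks(lat)
  off <- neighbor_offsets(lat)

  remaining <- survivors
  new <- births
  taken <- 0  # probability mass already split off
  for (d in seq_len(ndir)) {
    q <- p_dir / (1 - taken)
    movers <- if (deterministic) remaining * q else rbinom_counts(remaining, q)
    remaining <- remaining - movers
    taken <- taken + p_dir
    go <- movers * open[[d]]                 # blocked movers stay
    new <- new + (movers - go) +
      shift_counts(go, off[d, 1], if (ncol(off) == 2L) off[d, 2] else 0L)
  }
  new <- new + remaining                     # non-movers stay
  state$counts <- new
  state$step <- state$step + 1L
  state
}

#' y-averaged density profile along the x axis
#'
#' @param state a [wave_state()].
#' @return numeric vector: mean count per cell at each `x` (the raw counts
#'   in 1-D).
#' @export
wave_profile <- function(state) rowMeans(state$counts)

#' Front position of a travelling wave profile
#'
#' The front is the rightmost crossing of the level `K / 2`, linearly
#' interpolated between the bracketing cells (cell `i`, 0-based, sits at
#' `x = i * spacing`).  If the profile never reaches `K / 2` the position
#' is `NA`.
#'
#' @param profile per-`x` counts (y-averaged in 2-D).
#' @param K carrying capacity defining the half-height level.
#' @param spacing cell spacing.
#' @return front position in length units, or `NA_real_`.
#' @examples
#' front_position(c(50, 50, 0, 0), K = 50)  # 1.5
#' @export
front_position <- function(profile, K, spacing = 1) {
  profile <- as.numeric(profile)
  if (length(profile) == 0L) stop("'profile' must be non-empty")
  level <- K / 2
  above <- which(profile >= level)
  if (length(above) == 0L) return(NA_real_)
  j <- max(above)
  if (j == length(profile)) return(spacing * (j - 1))
  frac <- (profile[j] - level) / (profile[j] - profile[j + 1L])
  spacing * (j - 1 + frac)
}

#' Simulate a travelling wave and track its front
#'
#' Iterates [step_growth_diffusion()], recording the front position
#' `x_{K/2}` of the (y-averaged) profile at every step, until the
#' population reaches `stop_x` (geometric position of the farthest occupied
#' cell) or `max_steps` is exhausted.
#'
#' @param state initial [wave_state()].
#' @param max_steps hard cap on the number of steps.
#' @param stop_x stop once any individual reaches this x position (in
#'   length units); `NULL` to run exactly `max_steps` steps.
#' @param deterministic run the mean-field (noise-free) dynamics.
#' @return list with the final `state` and `trace`, a `front_trace` data
#'   frame with columns `step`, `time` and `front`.
#' @export
simulate_wave <- function(state, max_steps = 20000L, stop_x = NULL,
                          deterministic = FALSE) {
  lat <- state$lattice
  open <- open_direction_masks(lat)
  K <- state$growth$K
  tau <- state$movement$tau
  dx <- lat$spacing
  steps <- integer(max_steps); fronts <- numeric(max_steps)
  done <- 0L
  for (i in seq_len(max_steps)) {
    state <- step_growth_diffusion(state, deterministic = deterministic,
                                   open = open)
    done <- i
    steps[i] <- state$step
    fronts[i] <- front_position(wave_profile(state), K, dx)
    if (!is.null(stop_x)) {
      occ <- which(rowSums(state$counts) > 0)
      if (length(occ) && (max(occ) - 1) * dx >= stop_x) break
    }
  }
  steps <- steps[seq_len(done)]; fronts <- fronts[seq_len(done)]
  trace <- data.frame(step = steps, time = steps * tau, front = fronts)
  class(trace) <- c("front_trace", "data.frame")
  attr(trace, "spacing") <- dx
  attr(trace, "K") <- K
  list(state = state, trace = trace)
}

#' Minimal deterministic front speed of the FK equation
#'
#' @param D diffusion coefficient.
#' @param r growth rate.
#' @return `2 * sqrt(D * r)`.
#' @examples
#' deterministic_speed(180, 0.06)  # ~6.57 km/yr
#' @export
deterministic_speed <- function(D, r) {
  stopifnot(D >= 0, r >= 0)
  2 * sqrt(D * r)
}

#' Fit the front speed from a front-position trace
#'
#' Discards the initial `stabilization` fraction of the trace (the
#' transient before the wave settles to linear motion), then fits the
#' retained front positions against time by least squares.
#'
#' @param trace a `front_trace` from [simulate_wave()], or any data frame
#'   with `time` and `front` columns.
#' @param stabilization fraction of the trace discarded from the start
#'   (default 0.5).
#' @param v_det optional deterministic speed used to report the normalised
#'   speed `v_norm = v / v_det`.
#' @return object of class `speed_estimate`: list with `v`, `se`, `v_det`,
#'   `v_norm`, `n_points` and the fitted time `window`.
#' @export
estimate_front_speed <- function(trace, stabilization = 0.5, v_det = NULL) {
  stopifnot(stabilization >= 0, stabilization < 1)
  keep <- trace[-seq_len(floor(nrow(trace) * stabilization)), , drop = FALSE]
  keep <- keep[!is.na(keep$front), , drop = FALSE]
  if (nrow(keep) < 10L)
    stop("fewer than 10 usable front positions after the stabilization cut")
  fit <- stats::lm(front ~ time, data = keep)
  v <- unname(stats::coef(fit)[2])
  se <- unname(sqrt(diag(stats::vcov(fit)))[2])
  structure(
    list(v = v, se = se, v_det = v_det,
         v_norm = if (is.null(v_det)) NA_real_ else v / v_det,
         n_points = nrow(keep), window = range(keep$time)),
    class = "speed_estimate")
}

#' @export
print.speed_estimate <- function(x, ...) {
  cat("<speed_estimate> v =", format(x$v), "+/-", format(x$se))
  if (!is.null(x$v_det) && is.finite(x$v_norm))
    cat("  (v_det =", format(x$v_det), ", v_norm =", format(x$v_norm), ")")
  cat("\n")
  invisible(x)
}

#' Dispersion relation of the discrete growth-diffusion update
#'
#' Speed of an exponentially decaying front profile `exp(-gamma x)` under
#' the synchronous update:
#' `v(gamma) = ln(1 + D' (exp(-gamma dx) - 1) + D' (exp(gamma dx) - 1)
#'             + (b0 - d0)) / (gamma tau)`,
#' where `D' = p_move / n_neighbors` is the per-direction hop probability.
#' The realised ("pulled") front travels at the minimum over `gamma`.
#'
#' @param gamma front decay rate(s), strictly positive (vectorised).
#' @param growth a [growth_params()].
#' @param movement a [movement_params()].
#' @param lattice a [lattice_spec()].
#' @return speed(s) in length per unit time.
#' @export
dispersion_speed <- function(gamma, growth, movement, lattice) {
  if (any(gamma <= 0)) stop("'gamma' must be strictly positive")
  Dp <- movement$p_move / n_neighbors(lattice)
  dx <- lattice$spacing
  arg <- 1 + Dp * (exp(-gamma * dx) - 1) + Dp * (exp(gamma * dx) - 1) +
    (growth$b0 - growth$d0)
  log(arg) / (gamma * movement$tau)
}

#' Minimise the dispersion relation
#'
#' Locates the decay rate `gamma0` minimising [dispersion_speed()] by
#' bracketed scalar minimisation (tolerance 1e-10), and evaluates the
#' curvature `v''(gamma0)` by Richardson-extrapolated central differences.
#'
#' @inheritParams dispersion_speed
#' @param interval search interval for `gamma`.
#' @return object of class `dispersion_result`: list with `gamma0`,
#'   `v_min = v(gamma0)`, the second derivative `v2`, and the inputs.
#' @export
minimal_dispersion_speed <- function(growth, movement, lattice,
                                     interval = c(1e-4, 60)) {
  stopifnot(growth$b0 > growth$d0)
  f <- function(g) dispersion_speed(g, growth, movement, lattice)
  opt <- stats::optimize(f, interval = interval, tol = 1e-10)
  g0 <- opt$minimum
  width <- diff(interval)
  if (g0 - interval[1] < 1e-3 * width || interval[2] - g0 < 1e-3 * width)
    stop("no interior minimum of the dispersion relation found in [",
         interval[1], ", ", interval[2], "]; v(", format(g0), ") = ",
         format(opt$objective))
  h <- 1e-4 * max(1, g0)
  curv <- function(h) (f(g0 + h) - 2 * f(g0) + f(g0 - h)) / h^2
  a1 <- curv(h); a2 <- curv(2 * h)
  v2 <- (4 * a1 - a2) / 3                 # Richardson extrapolation
  if (!is.finite(v2) || abs(a1 - a2) > 0.05 * max(abs(v2), 1e-12))
    warning("second derivative of the dispersion relation is poorly ",
            "resolved at gamma0")
  structure(list(gamma0 = g0, v_min = opt$objective, v2 = v2,
                 growth = growth, movement = movement, lattice = lattice),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("<dispersion_result> gamma0 =", format(x$gamma0),
      " v(gamma0) =", format(x$v_min), " v''(gamma0) =", format(x$v2), "\n")
  invisible(x)
}

#' Finite-population correction to the front speed
#'
#' For a finite local carrying capacity the pulled front is slowed by the
#' discreteness of its leading edge; to second order
#' `v = v(gamma0) - pi^2 v''(gamma0) / (2 L^2)` with a cutoff length `L`
#' growing like `ln K`.  The default form is `L = ln(K) / gamma0` (the
#' standard cutoff-theory choice); the correction vanishes as `K -> Inf`
#' and the corrected speed increases monotonically in `K`.  For very small
#' `K` the second-order expansion can undershoot (even below zero); results
#' there are indicative only.
#'
#' @param disp a [minimal_dispersion_speed()] result.
#' @param K carrying capacity, `>= 2` (vectorised).
#' @param L_form functional form of the cutoff length; currently
#'   `"log_K_over_gamma0"`.
#' @return corrected speed(s).
#' @export
finite_K_speed <- function(disp, K, L_form = c("log_K_over_gamma0")) {
  L_form <- match.arg(L_form)
  stopifnot(all(K >= 2))
  L <- log(K) / disp$gamma0
  disp$v_min - pi^2 * disp$v2 / (2 * L^2)
}
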