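#' Movement parameters of the synchronous random walk
#'
#' Each individual moves with probability `p_move` per time step `tau` to a
#' uniformly chosen neighbour slot; a blocked (masked or off-domain) slot
#' means the individual stays put, which keeps the per-open-direction
#' probability at `p_move / n_neighbors` (anisotropy correction).
#'
#' @param p_move probability of attempting a move per step, in \[0, 1\].
#' @param tau duration of one time step, positive.
#' @return an object of class `movement_params`.
#' @export
movement_params <- function(p_move, tau = 1) {
  if (!is.numeric(p_move) || length(p_move) != 1L || p_move < 0 || p_move > 1)
    stop("'p_move' must be a single probability in [0, 1]")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("'tau' must be a single positive number")
  structure(list(p_move = p_move, tau = tau), class = "movement_params")
}

#' @export
print.movement_params <- function(x, ...) {
  cat("<movement_params> p_move =", format(x$p_move),
      " tau =", format(x$tau), "\n")
  invisible(x)
}

#' Cloud of independent random walkers
#'
#' The Markov state of the pure-movement model: one lattice cell per
#' individual plus a step counter.  Movement conserves the number of
#' individuals.
#'
#' @param positions integer matrix of 0-based cell coordinates, one row per
#'   individual (a vector is accepted for `line2`).
#' @param lattice a [lattice_spec()].
#' @param time integer step counter.
#' @return an object of class `walker_cloud`.
#' @export
walker_cloud <- function(positions, lattice, time = 0L) {
  pos <- coord_matrix(lattice, positions)
  if (!all(is_accessible(lattice, pos)))
    stop("all walker positions must be habitable in-domain cells")
  structure(list(positions = pos, lattice = lattice, time = as.integer(time)),
            class = "walker_cloud")
}

#' @export
print.walker_cloud <- function(x, ...) {
  cat("<walker_cloud>", nrow(x$positions), "walkers on a", x$lattice$topology,
      "lattice, step", x$time, "\n")
  invisible(x)
}

#' Microscopic (large-scale) diffusion coefficient of the walk
#'
#' The per-axis diffusion coefficient implied by the microscopic movement
#' rule.  For a walk that moves with probability `p_move` by one lattice
#' spacing in a uniformly chosen direction, the per-axis displacement
#' variance per step is `p_move * mean(dx_axis^2)`, and
#' `D = p_move * mean(dx_axis^2) / (2 * tau)`.  On `line2` and `rect4` this
#' reduces to the textbook form
#' `D = p_move * (1 / n_neighbors) * spacing^2 / tau`; on the hexagonal grid
#' the mean squared per-axis step is `spacing^2 / 2` (mean of `cos^2` over
#' six directions), giving `D = p_move * spacing^2 / (4 * tau)`.
#'
#' @param params a [movement_params()].
#' @param lattice a [lattice_spec()].
#' @return diffusion coefficient in units of `spacing^2 / tau`.
#' @examples
#' microscopic_D(movement_params(2 / 5), lattice_spec("line2", 11))  # 0.2
#' @export
microscopic_D <- function(params, lattice) {
  disp <- displacement_vectors(lattice)
  params$p_move * mean(disp[, 1]^2) / (2 * params$tau)
}

#' Anisotropy-corrected movement probability
#'
#' Near inaccessible cells (or the domain edge) the total movement
#' probability is rescaled so that the probability of moving into any given
#' open direction remains `p_move / n_tot`; the diffusion coefficient along
#' open directions is therefore unchanged by the local anisotropy.
#'
#' @param p_move base movement probability.
#' @param n_tot total number of neighbour slots.
#' @param n_inaccess number of inaccessible neighbour slots; when all slots
#'   are blocked the result is 0 (the individual cannot move).
#' @return the effective movement probability
#'   `p_move * (n_tot - n_inaccess) / n_tot`.
#' @export
effective_move_probability <- function(p_move, n_tot, n_inaccess) {
  if (any(n_inaccess < 0) || any(n_inaccess > n_tot))
    stop("'n_inaccess' must lie in [0, n_tot]")
  p_move * (n_tot - n_inaccess) / n_tot
}

#' Advance a walker cloud by one synchronous movement step
#'
#' Every individual independently moves with probability `p_move`, choosing
#' uniformly among all `n_neighbors` direction slots; if the chosen slot is
#' off-domain or masked the individual stays (this is exactly the
#' anisotropy-corrected rule: per open direction the probability is
#' `p_move / n_neighbors`).  All decisions use positions at the start of the
#' step; draws come from R's global RNG in individual order (movement
#' indicator first, then the direction of each mover).
#'
#' @param cloud a [walker_cloud()].
#' @param params a [movement_params()].
#' @return the cloud one step later; individual count is conserved.
#' @export
step_movement <- function(cloud, params) {
  lat <- cloud$lattice
  pos <- cloud$positions
  n <- nrow(pos)
  moving <- stats::runif(n) < params$p_move
  if (any(moving)) {
    off <- neighbor_offsets(lat)
    dir <- sample.int(nrow(off), sum(moving), replace = TRUE)
    prop <- pos[moving, , drop = FALSE] + off[dir, , drop = FALSE]
    ok <- is_accessible(lat, prop)
    idx <- which(moving)[ok]
    pos[idx, ] <- prop[ok, , drop = FALSE]
  }
  cloud$positions <- pos
  cloud$time <- cloud$time + 1L
  cloud
}

#' Cartesian positions of walkers
#'
#' Converts lattice coordinates to geometric positions (see
#' [lattice_spec()] for the embedding of each topology).
#'
#' @param cloud a [walker_cloud()].
#' @return numeric matrix, one row per walker, one column per Cartesian axis.
#' @export
walker_positions <- function(cloud) {
  cell_positions(cloud$lattice, cloud$positions)
}

cell_positions <- function(lattice, cells) {
  cells <- coord_matrix(lattice, cells)
  dx <- lattice$spacing
  switch(lattice$topology,
    line2 = cbind(x = dx * cells[, 1]),
    rect4 = cbind(x = dx * cells[, 1], y = dx * cells[, 2]),
    hex6  = cbind(x = dx * (cells[, 1] + cells[, 2] / 2),
                  y = dx * sqrt(3) / 2 * cells[, 2]))
}

#' Simulate a walker cloud and record the positional variance
#'
#' Runs `n_steps` synchronous movement steps and records, per step, the
#' variance of the Cartesian position of all individuals along each axis.
#' This is the protocol behind the variance-slope estimator of the
#' macroscopic diffusion coefficient.  If any walker ever sits on a domain
#' boundary cell a warning is issued, because the confined boundary then
#' distorts the free-walk variance.
#'
#' @param cloud a [walker_cloud()].
#' @param params a [movement_params()].
#' @param n_steps number of steps to simulate.
#' @return data frame with columns `step`, `time` and one variance column
#'   per axis (`var_x`, and `var_y` in 2-D).
#' @export
simulate_variance_series <- function(cloud, params, n_steps) {
  lat <- cloud$lattice
  axes <- colnames(cell_positions(lat, cloud$positions[1, , drop = FALSE]))
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = length(axes))
  touched_edge <- FALSE
  record <- function(i, cl) {
    p <- walker_positions(cl)
    out[i, ] <<- apply(p, 2, stats::var)
    if (!touched_edge) {
      cells <- cl$positions
      for (d in seq_along(lat$shape))
        if (any(cells[, d] == 0L) || any(cells[, d] == lat$shape[d] - 1L))
          touched_edge <<- TRUE
    }
  }
  record(1L, cloud)
  for (i in seq_len(n_steps)) {
    cloud <- step_movement(cloud, params)
    record(i + 1L, cloud)
  }
  if (touched_edge)
    warning("walkers reached the domain boundary; variance series may be ",
            "distorted by confinement")
  res <- data.frame(step = 0:n_steps, time = (0:n_steps) * params$tau)
  res[paste0("var_", axes)] <- as.data.frame(out)
  res
}

#' Variance-slope estimator of the macroscopic diffusion coefficient
#'
#' For a diffusive cloud the positional variance grows linearly,
#' `Var(x) = 2 D t`.  The estimator takes the one-step differences of the
#' variance series, averages them (the mean time derivative) and divides by
#' `2 tau`; the standard error of the mean difference is propagated.
#'
#' @param variance_series numeric vector of per-step positional variances
#'   (at least 2 values), ordered in time with one entry per step.
#' @param tau duration of one step.
#' @return object of class `diffusion_estimate`: a list with the mean
#'   variance derivative `slope` and its standard error `slope_se`, and the
#'   diffusion coefficient `D = slope / (2 tau)` with standard error `D_se`.
#' @examples
#' estimate_macroscopic_D(0.4 * (0:100), tau = 1)$D  # exactly 0.2
#' @export
estimate_macroscopic_D <- function(variance_series, tau = 1) {
  v <- as.numeric(variance_series)
  if (length(v) < 2L)
    stop("'variance_series' must contain at least 2 values")
  dv <- diff(v)
  slope <- mean(dv)
  slope_se <- if (length(dv) > 1L) stats::sd(dv) / sqrt(length(dv)) else NA_real_
  structure(
    list(slope = slope, slope_se = slope_se,
         D = slope / (2 * tau), D_se = slope_se / (2 * tau)),
    class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat("<diffusion_estimate> D =", format(x$D), "+/-", format(x$D_se),
      " (variance slope", format(x$slope), "+/-", format(x$slope_se), ")\n")
  invisible(x)
}
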