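#' Derive a reproducible per-realization seed
#'
#' Counter-based derivation so that realization `i` of an experiment can be
#' re-run in isolation: a fixed multiplicative hash of `(master, i)` folded
#' into the 31-bit integer range.
#'
#' @param master master seed (integer).
#' @param i realization counter (integer `>= 0`).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + as.double(i) * 16807 + 12345) %%
               2147483647)
}

#' Build a synthetic initial state or mask
#'
#' Generates the initial conditions of the idealised experiments:
#' `"point_seed"` places `N0` individuals in the single cell at `x = 0`
#' (1-D) or `(0, floor(ny/2))` (2-D); `"line_seed"` places `N0` in every
#' cell of the `x = 0` column; `"uniform_fill"` places `N0` in every
#' habitable cell; `"random_mask"` returns a copy of the lattice with a
#' Bernoulli-masked habitability field (each cell independently blocked
#' with probability `blocked_fraction`).
#'
#' @param kind one of `"point_seed"`, `"line_seed"`, `"uniform_fill"`,
#'   `"random_mask"`.
#' @param lattice a [lattice_spec()].
#' @param N0 individuals per seeded cell (`>= 1`); ignored for
#'   `"random_mask"`.
#' @param seed optional integer seed (only `"random_mask"` draws).
#' @param blocked_fraction fraction of cells blocked by `"random_mask"`.
#' @return a count matrix (`nx x ny`) for the seed kinds, or a
#'   [lattice_spec()] for `"random_mask"`.  Seeding a masked cell is a
#'   configuration error.
#' @export
make_fixture <- function(kind = c("point_seed", "line_seed", "uniform_fill",
                                  "random_mask"),
                         lattice, N0 = 1L, seed = NULL,
                         blocked_fraction = 0) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  nx <- lattice$shape[1]
  ny <- if (length(lattice$shape) == 2L) lattice$shape[2] else 1L
  if (kind == "random_mask") {
    stopifnot(blocked_fraction >= 0, blocked_fraction <= 1)
    mask <- matrix(stats::runif(nx * ny) >= blocked_fraction, nx, ny)
    lattice$mask <- if (ny == 1L) mask[, 1] else mask
    return(lattice)
  }
  stopifnot(N0 >= 1)
  counts <- matrix(0, nx, ny)
  counts[switch(kind,
    point_seed   = matrix(c(1L, ny %/% 2L + 1L), 1),
    line_seed    = cbind(1L, seq_len(ny)),
    uniform_fill = cbind(rep(seq_len(nx), ny), rep(seq_len(ny), each = nx))
  )] <- N0
  if (!is.null(lattice$mask)) {
    mask <- matrix(lattice$mask, nx, ny)
    if (kind == "uniform_fill") counts[!mask] <- 0
    else if (any(counts[!mask] > 0))
      stop("initial individuals placed on a masked cell")
  }
  counts
}

#' Experiment configuration
#'
#' A fully reproducible description of one experiment: its identifier,
#' parameter list and master seed.  Runs are a pure function of
#' `(config, seed)`.  Configurations round-trip losslessly through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param experiment one of `"table1"`, `"growth_sweep"`,
#'   `"speed_sweep_1d"`, `"speed_sweep_2d"`, `"masked_demo"`.
#' @param params named list of experiment parameters overriding the
#'   driver's defaults.
#' @param seed master seed.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("table1", "growth_sweep",
                                             "speed_sweep_1d",
                                             "speed_sweep_2d", "masked_demo"),
                              params = list(), seed = 1L) {
  experiment <- match.arg(experiment)
  stopifnot(is.list(params))
  structure(list(experiment = experiment, params = params,
                 seed = as.integer(seed), version = 1L),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>", x$experiment, " seed", x$seed, "\n")
  if (length(x$params)) utils::str(x$params, give.attr = FALSE)
  invisible(x)
}

#' @rdname experiment_config
#' @param config an `experiment_config`.
#' @param path file path for the YAML representation.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  experiment_config(x$experiment, params = x$params, seed = x$seed)
}

#' Write a result table with a JSON metadata sidecar
#'
#' Writes `x` as UTF-8 CSV ("." decimal, header row) and a `<path>.json`
#' sidecar holding the seed, parameters and package version, so every
#' emitted table carries its provenance.
#'
#' @param x data frame.
#' @param path CSV output path.
#' @param config the [experiment_config()] that produced the table.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, config) {
  utils::write.csv(x, path, row.names = FALSE)
  meta <- list(experiment = config$experiment, seed = config$seed,
               params = config$params,
               package_version = as.character(utils::packageVersion("fkibm")),
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

# Merge user params over driver defaults, rejecting unknown names.  Flat
# replacement: a supplied value replaces the default wholesale (no
# recursive merging into data frames or nested lists).
merge_params <- function(defaults, params) {
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown experiment parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  defaults
}

#' Replicate the 1-D diffusion calibration table
#'
#' For each movement probability, simulates `n0` independent walkers on a
#' 1-D lattice for `n_steps` steps (domain wide enough that no walker can
#' reach the edge), and reports the microscopic diffusion coefficient
#' beside the variance-slope estimate.
#'
#' @param config an [experiment_config()] (experiment `"table1"`).
#'   Parameters: `p_move` (default `c(1, 2/5, 1/5)`), `n0` (3000),
#'   `n_steps` (500), `spacing` (1), `tau` (1).
#' @return data frame with columns `p_move`, `D_micro`, `var_slope`,
#'   `var_slope_se`, `D_macro`, `D_macro_se`.
#' @export
run_table1 <- function(config = experiment_config("table1")) {
  par <- merge_params(
    list(p_move = c(1, 2 / 5, 1 / 5), n0 = 3000L, n_steps = 500L,
         spacing = 1, tau = 1),
    config$params)
  rows <- lapply(seq_along(par$p_move), function(i) {
    set.seed(derive_seed(config$seed, i))
    p <- par$p_move[i]
    nx <- 2L * par$n_steps + 3L
    lat <- lattice_spec("line2", nx, spacing = par$spacing)
    mp <- movement_params(p, par$tau)
    cloud <- walker_cloud(matrix(rep(par$n_steps + 1L, par$n0), ncol = 1),
                          lat)
    vs <- simulate_variance_series(cloud, mp, par$n_steps)
    est <- estimate_macroscopic_D(vs$var_x, par$tau)
    data.frame(p_move = p, D_micro = microscopic_D(mp, lat),
               var_slope = est$slope, var_slope_se = est$slope_se,
               D_macro = est$D, D_macro_se = est$D_se)
  })
  do.call(rbind, rows)
}

# Default (K, b0, theta) grid of the growth experiments.
growth_grid_defaults <- function() {
  data.frame(
    b0 = rep(c(0.8, 0.3), each = 4),
    theta = c(0.7, 0.4, 0.08, 0.008, 0.2625, 0.15, 0.03, 0.003))
}

#' Sweep the effective carrying capacity over the growth parameter grid
#'
#' Runs [estimate_effective_K()] for every combination of `K` and
#' `(b0, theta)` in the grid, and reports the simulated normalised
#' effective carrying capacity beside its analytic prediction
#' ([effective_K_approx()]).
#'
#' @param config an [experiment_config()] (experiment `"growth_sweep"`).
#'   Parameters: `K` (default `c(10, 50, 100, 500)`), `grid` (data frame
#'   with `b0`, `theta`; default the standard 8-pair grid), `d0` (0),
#'   `n_realizations` (100), `n_steps` (500), `burn_in` (100).
#' @return tidy data frame with one row per `(K, b0, theta)`:
#'   `N_eff`, `sem`, `n_extinct`, `ratio = N_eff / K` and the predicted
#'   `ratio_pred`.
#' @export
run_growth_sweep <- function(config = experiment_config("growth_sweep")) {
  par <- merge_params(
    list(K = c(10, 50, 100, 500), grid = growth_grid_defaults(), d0 = 0,
         n_realizations = 100L, n_steps = 500L, burn_in = 100L),
    config$params)
  grid <- as.data.frame(par$grid)
  cases <- merge(data.frame(K = par$K), grid)
  rows <- lapply(seq_len(nrow(cases)), function(i) {
    gp <- growth_params(b0 = cases$b0[i], theta = cases$theta[i],
                        d0 = par$d0, K = cases$K[i])
    est <- estimate_effective_K(gp, n_realizations = par$n_realizations,
                                n_steps = par$n_steps, burn_in = par$burn_in,
                                seed = derive_seed(config$seed, i))
    data.frame(K = cases$K[i], b0 = cases$b0[i], theta = cases$theta[i],
               N_eff = est$mean, sem = est$sem, n_extinct = est$n_extinct,
               ratio = est$mean / cases$K[i],
               ratio_pred = effective_K_approx(gp) / cases$K[i])
  })
  do.call(rbind, rows)
}

#' Sweep the front speed over carrying capacity and growth probability
#'
#' For each `(K, b0)` (with `theta = 0.1 b0`, `d0 = 0`) runs replicated
#' wave simulations at diffusion coefficient `D` — 1-D point seed or 2-D
#' line seed — fits the front speed, and reports the normalised speed
#' beside the dispersion-relation prediction with its finite-`K`
#' correction.
#'
#' @param config an [experiment_config()] (`"speed_sweep_1d"` or
#'   `"speed_sweep_2d"`).  Parameters: `K` (default
#'   `c(10, 50, 100, 500)`), `b0` (`c(0.8, 0.3, 0.1, 0.01)`),
#'   `theta_ratio` (0.1), `D` (0.2), `reps` (10), `nx` (1000), `ny` (100,
#'   2-D only), `stop_x` (300), `stabilization` (0.5), `max_steps`
#'   (200000).
#' @return tidy data frame, one row per `(dim, K, b0)`: mean fitted speed
#'   `v`, standard error `v_se` across replicates, `v_det`, `v_norm`,
#'   and the analytic `gamma0`, `v_disp` (infinite-`K` dispersion minimum)
#'   and `v_pred` (finite-`K` corrected speed, normalised in
#'   `v_norm_pred`).
#' @export
run_speed_sweep <- function(config = experiment_config("speed_sweep_1d")) {
  dim2 <- identical(config$experiment, "speed_sweep_2d")
  par <- merge_params(
    list(K = c(10, 50, 100, 500), b0 = c(0.8, 0.3, 0.1, 0.01),
         theta_ratio = 0.1, D = 0.2, reps = 10L, nx = 1000L, ny = 100L,
         stop_x = 300, stabilization = 0.5, max_steps = 200000L),
    config$params)
  topo <- if (dim2) "rect4" else "line2"
  shape <- if (dim2) c(par$nx, par$ny) else par$nx
  lat <- lattice_spec(topo, shape)
  # P_move realising D on this topology: D = p_move / n_neighbors (dx = tau = 1)
  p_move <- par$D * n_neighbors(lat)
  if (p_move > 1)
    stop("requested D = ", par$D, " needs p_move > 1 on ", topo)
  mp <- movement_params(p_move)
  cases <- expand.grid(K = par$K, b0 = par$b0)
  rows <- lapply(seq_len(nrow(cases)), function(i) {
    K <- cases$K[i]; b0 <- cases$b0[i]
    gp <- growth_params(b0 = b0, theta = par$theta_ratio * b0, d0 = 0, K = K)
    v_det <- deterministic_speed(par$D, growth_rate(gp))
    init <- make_fixture(if (dim2) "line_seed" else "point_seed", lat, N0 = K)
    vs <- vapply(seq_len(par$reps), function(rep) {
      set.seed(derive_seed(config$seed, i * 1000L + rep))
      sim <- simulate_wave(wave_state(lat, init, gp, mp),
                           max_steps = par$max_steps, stop_x = par$stop_x)
      estimate_front_speed(sim$trace, par$stabilization)$v
    }, numeric(1))
    disp <- minimal_dispersion_speed(gp, mp, lat)
    v_pred <- finite_K_speed(disp, K)
    data.frame(dim = if (dim2) 2L else 1L, K = K, b0 = b0,
               theta = gp$theta, D = par$D, reps = par$reps,
               v = mean(vs),
               v_se = if (par$reps > 1) stats::sd(vs) / sqrt(par$reps)
                      else NA_real_,
               v_det = v_det, v_norm = mean(vs) / v_det,
               gamma0 = disp$gamma0, v_disp = disp$v_min,
               v_pred = v_pred, v_norm_pred = v_pred / v_det)
  })
  do.call(rbind, rows)
}

#' Simulate colonisation of a masked landscape and record arrival times
#'
#' Runs the growth-diffusion model on a habitability-masked lattice
#' (anisotropy-corrected movement is implied by the blocked-slot rule) and
#' records, per cell, the first step at which it is colonised.
#'
#' @param config an [experiment_config()] (experiment `"masked_demo"`).
#'   Parameters: `nx` (default 60), `ny` (30), `mask` (logical `nx x ny`
#'   matrix, default a vertical wall at `x = nx/2` with a one-cell gap),
#'   `K` (20), `b0` (0.3), `theta` (0.03), `d0` (0), `p_move` (0.8),
#'   `seed_cell` (`c(0, floor(ny/2))`), `max_steps` (5000).
#' @return list with `arrival` (an `nx x ny` matrix of first-colonisation
#'   steps; `NA` for cells never reached, `-1` for masked cells), the
#'   `lattice` and the final `state`.
#' @export
run_masked_demo <- function(config = experiment_config("masked_demo")) {
  par <- merge_params(
    list(nx = 60L, ny = 30L, mask = NULL, K = 20, b0 = 0.3, theta = 0.03,
         d0 = 0, p_move = 0.8, seed_cell = NULL, max_steps = 5000L),
    config$params)
  mask <- par$mask
  if (is.null(mask)) {
    mask <- matrix(TRUE, par$nx, par$ny)
    mask[par$nx %/% 2L + 1L, ] <- FALSE          # wall ...
    mask[par$nx %/% 2L + 1L, par$ny %/% 2L + 1L] <- TRUE  # ... with a gap
  }
  lat <- lattice_spec("rect4", c(par$nx, par$ny), mask = mask)
  seed_cell <- if (is.null(par$seed_cell)) c(0L, par$ny %/% 2L)
               else as.integer(par$seed_cell)
  if (!is_accessible(lat, matrix(seed_cell, 1)))
    stop("seed cell is masked or outside the domain")
  counts <- matrix(0, par$nx, par$ny)
  counts[seed_cell[1] + 1L, seed_cell[2] + 1L] <- par$K
  gp <- growth_params(par$b0, par$theta, par$d0, par$K)
  mp <- movement_params(par$p_move)
  state <- wave_state(lat, counts, gp, mp)
  open <- open_direction_masks(lat)
  arrival <- matrix(NA_real_, par$nx, par$ny)
  arrival[counts > 0] <- 0
  set.seed(derive_seed(config$seed, 0L))
  for (s in seq_len(par$max_steps)) {
    state <- step_growth_diffusion(state, open = open)
    fresh <- is.na(arrival) & state$counts > 0
    arrival[fresh] <- s
    if (!anyNA(arrival[mask])) break
  }
  arrival[!mask] <- -1
  list(arrival = arrival, lattice = lat, state = state)
}
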