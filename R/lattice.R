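#' Spatial lattice substrate
#'
#' Defines the spatial substrate on which individuals live: a one-dimensional
#' chain (`"line2"`, 2 neighbours per interior cell), a rectangular grid with
#' von Neumann neighbourhood (`"rect4"`, 4 neighbours) or a planar hexagonal
#' grid (`"hex6"`, 6 neighbours).  Cells carry an optional habitability mask;
#' individuals never enter inaccessible cells.  The domain boundary is
#' confining: off-domain neighbour slots behave exactly like masked cells, so
#' a single mechanism covers both geography and domain edges.
#'
#' Cells are addressed by 0-based integer coordinates: `x` for `line2`,
#' `(x, y)` for `rect4`, and axial `(q, r)` for `hex6`.  The geometric
#' (Cartesian) position of a cell is `x * spacing` on the line,
#' `(x, y) * spacing` on the rectangle, and
#' `(spacing * (q + r/2), spacing * sqrt(3)/2 * r)` on the hexagonal grid,
#' so that every neighbour displacement has length `spacing`.
#'
#' @param topology one of `"line2"`, `"rect4"`, `"hex6"`.
#' @param shape integer vector of cells per axis: length 1 for `line2`,
#'   length 2 (`nx`, `ny`) otherwise.
#' @param spacing distance between neighbouring cells (length of one step),
#'   must be positive.
#' @param mask optional logical habitability mask, `TRUE` = habitable.
#'   A vector of length `nx` for `line2`, else a matrix with `nx` rows and
#'   `ny` columns (`mask[x + 1, y + 1]`).  Default: all cells habitable.
#' @return an object of class `lattice_spec`.
#' @examples
#' lat <- lattice_spec("rect4", shape = c(10, 5))
#' neighbors(lat, c(0, 0))
#' @export
lattice_spec <- function(topology = c("line2", "rect4", "hex6"),
                         shape, spacing = 1, mask = NULL) {
  topology <- match.arg(topology)
  shape <- as.integer(shape)
  ndim <- if (topology == "line2") 1L else 2L
  if (length(shape) != ndim)
    stop("'shape' must have length ", ndim, " for topology '", topology, "'")
  if (any(shape < 1L)) stop("all 'shape' entries must be >= 1")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("'spacing' must be a single positive number")
  if (!is.null(mask)) {
    if (length(mask) != prod(shape))
      stop("'mask' must have exactly one flag per cell")
    mask <- if (ndim == 1L) as.logical(mask) else
      matrix(as.logical(mask), nrow = shape[1], ncol = shape[2])
    if (anyNA(mask)) stop("'mask' must not contain NA")
  }
  structure(
    list(topology = topology, shape = shape, spacing = spacing,
         boundary = "confined", mask = mask),
    class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat("<lattice_spec> ", x$topology, " ",
      paste(x$shape, collapse = " x "),
      " cells, spacing ", format(x$spacing), sep = "")
  if (!is.null(x$mask))
    cat(", ", sum(!x$mask), " masked cell(s)", sep = "")
  cat("\n")
  invisible(x)
}

#' Number of neighbour slots per interior cell
#'
#' @param lattice a [lattice_spec()].
#' @return 2 for `line2`, 4 for `rect4`, 6 for `hex6`.
#' @export
n_neighbors <- function(lattice) {
  switch(lattice$topology, line2 = 2L, rect4 = 4L, hex6 = 6L)
}

# Neighbour offsets in lattice (integer) coordinates, one row per direction.
# Order is fixed and documented: line2 (-x, +x); rect4 (-x, +x, -y, +y);
# hex6 axial directions at 0, 60, ..., 300 degrees.
neighbor_offsets <- function(lattice) {
  switch(lattice$topology,
    line2 = matrix(c(-1L, 1L), ncol = 1),
    rect4 = matrix(c(-1L, 0L, 1L, 0L, 0L, -1L, 0L, 1L),
                   ncol = 2, byrow = TRUE),
    hex6  = matrix(c(1L, 0L, 0L, 1L, -1L, 1L, -1L, 0L, 0L, -1L, 1L, -1L),
                   ncol = 2, byrow = TRUE))
}

#' Geometric displacement vectors of the neighbour directions
#'
#' Cartesian displacement of each neighbour step, in the same order as
#' [neighbors()].  Every row has length `spacing`; for `hex6` the six vectors
#' point at 0, 60, ..., 300 degrees and sum to zero (isotropy).
#'
#' @param lattice a [lattice_spec()].
#' @return numeric matrix, one row per direction, one column per Cartesian
#'   axis.
#' @export
displacement_vectors <- function(lattice) {
  dx <- lattice$spacing
  switch(lattice$topology,
    line2 = matrix(c(-dx, dx), ncol = 1, dimnames = list(NULL, "x")),
    rect4 = dx * matrix(c(-1, 0, 1, 0, 0, -1, 0, 1), ncol = 2, byrow = TRUE,
                        dimnames = list(NULL, c("x", "y"))),
    hex6  = {
      ang <- (0:5) * pi / 3
      dx * cbind(x = cos(ang), y = sin(ang))
    })
}

# TRUE for coordinate rows that lie inside the domain.
in_domain <- function(lattice, cells) {
  cells <- coord_matrix(lattice, cells)
  ok <- rep(TRUE, nrow(cells))
  for (d in seq_along(lattice$shape))
    ok <- ok & cells[, d] >= 0L & cells[, d] < lattice$shape[d]
  ok
}

# TRUE for in-domain, unmasked coordinate rows; off-domain rows are FALSE.
is_accessible <- function(lattice, cells) {
  cells <- coord_matrix(lattice, cells)
  ok <- in_domain(lattice, cells)
  if (!is.null(lattice$mask) && any(ok)) {
    idx <- cells[ok, 1] + 1L
    if (length(lattice$shape) == 2L)
      idx <- idx + cells[ok, 2] * lattice$shape[1]
    ok[ok] <- lattice$mask[idx]
  }
  ok
}

coord_matrix <- function(lattice, cells) {
  ndim <- length(lattice$shape)
  if (is.null(dim(cells))) {
    if (length(cells) %% ndim != 0L)
      stop("cell coordinates must have ", ndim, " entries per cell")
    cells <- matrix(cells, ncol = ndim, byrow = ndim > 1L)
  }
  storage.mode(cells) <- "integer"
  cells
}

#' Neighbourhood of a cell
#'
#' Returns the full, ordered set of neighbour slots of `cell`, including
#' slots that fall outside the domain or on masked cells; those are flagged
#' `accessible = FALSE` so that movement can count them (the confined
#' boundary is treated exactly like an inaccessible cell).
#'
#' @param lattice a [lattice_spec()].
#' @param cell integer coordinates of one in-domain cell (0-based).
#' @return data frame with the neighbour coordinates (columns `x`, and `y`
#'   for 2-D topologies) and a logical column `accessible`, in the fixed
#'   direction order of [displacement_vectors()].
#' @export
neighbors <- function(lattice, cell) {
  cell <- coord_matrix(lattice, cell)
  if (nrow(cell) != 1L) stop("'cell' must be a single cell")
  if (!in_domain(lattice, cell)) stop("cell is outside the lattice domain")
  off <- neighbor_offsets(lattice)
  nb <- sweep(off, 2, cell[1, ], "+")
  out <- as.data.frame(nb)
  names(out) <- if (ncol(nb) == 1L) "x" else
    if (lattice$topology == "hex6") c("q", "r") else c("x", "y")
  out$accessible <- is_accessible(lattice, nb)
  out
}

#' Count inaccessible neighbour slots
#'
#' Used by the anisotropy correction of the movement probability: near
#' masked cells or the domain edge, the number of blocked directions
#' rescales the total movement probability (see
#' [effective_move_probability()]).
#'
#' @param lattice a [lattice_spec()].
#' @param cell integer coordinates of one habitable in-domain cell.
#' @return named integer vector `c(n_tot, n_inaccess)`; `n_tot` is always
#'   the full neighbour count of the topology, off-domain boundary slots
#'   count as inaccessible.
#' @export
count_inaccessible <- function(lattice, cell) {
  nb <- neighbors(lattice, cell)
  c(n_tot = nrow(nb), n_inaccess = sum(!nb$accessible))
}

#' Read a habitability mask from a plain-text matrix file
#'
#' The file holds one row of 0/1 values per grid row, whitespace or comma
#' separated, with the first file row corresponding to the smallest `y`
#' (row-major, documented orientation).  `1` marks a habitable cell.
#'
#' @param path file path.
#' @param sep field separator passed to [utils::read.table()]; `""` (any
#'   whitespace) by default.
#' @return logical matrix with `nx` rows and `ny` columns, suitable for the
#'   `mask` argument of [lattice_spec()].
#' @export
read_mask <- function(path, sep = "") {
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  # file rows are y levels (row 1 = smallest y); internal layout is [x, y]
  unname(t(m != 0))
}
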