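#' Gridded potential of mean force
#'
#' A `pmf_grid` holds free energies on a regular 2D grid: origin, spacing,
#' values (kcal/mol, minimum over occupied cells shifted to 0), occupancy
#' counts, and the kT used.  Unoccupied cells are `NA` and flagged, never
#' silently interpolated.
#'
#' @param origin length-2 numeric, coordinates of the center of cell (1, 1).
#' @param spacing length-2 numeric, cell sizes.
#' @param values `nx x ny` matrix of free energies (kcal/mol).
#' @param counts `nx x ny` matrix of occupancy counts.
#' @param kT thermal energy used to construct the grid.
#' @return object of class `pmf_grid`.
#' @export
new_pmf_grid <- function(origin, spacing, values, counts, kT) {
  stopifnot(length(origin) == 2L, length(spacing) == 2L,
            all(dim(values) == dim(counts)))
  occ <- counts > 0
  if (any(occ)) values <- values - min(values[occ], na.rm = TRUE)
  values[!occ] <- NA_real_
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 nx = nrow(values), ny = ncol(values),
                 values = values, counts = counts, occupied = occ, kT = kT),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat(sprintf("<pmf_grid> %d x %d cells, spacing (%.3g, %.3g), %d occupied, kT=%g\n",
              x$nx, x$ny, x$spacing[1L], x$spacing[2L], sum(x$occupied),
              x$kT))
  if (any(x$occupied))
    cat(sprintf("  F range on occupied cells: [0, %.3g] kcal/mol\n",
                max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Regular 2D grid specification
#'
#' @param xlim,ylim numeric length-2 ranges covered by the grid.
#' @param nx,ny number of cells per axis.
#' @return list with `origin` (center of the first cell), `spacing`, `nx`,
#'   `ny`.
#' @export
grid_spec <- function(xlim, ylim, nx = 60L, ny = 60L) {
  dx <- diff(xlim) / nx; dy <- diff(ylim) / ny
  list(origin = c(xlim[1L] + dx / 2, ylim[1L] + dy / 2),
       spacing = c(dx, dy), nx = as.integer(nx), ny = as.integer(ny))
}

# default grid: sample bounding box + 5% padding
.default_grid_spec <- function(xy, nx = 60L, ny = 60L) {
  rx <- range(xy[, 1L]); ry <- range(xy[, 2L])
  # degenerate (zero-extent) sample sets still get a usable grid
  px <- max(0.05 * diff(rx), 0.5e-3 * max(abs(rx), 1))
  py <- max(0.05 * diff(ry), 0.5e-3 * max(abs(ry), 1))
  grid_spec(rx + c(-px, px), ry + c(-py, py), nx, ny)
}

.cell_of <- function(gs, xy) {
  ix <- floor((xy[, 1L] - gs$origin[1L]) / gs$spacing[1L] + 0.5) + 1L
  iy <- floor((xy[, 2L] - gs$origin[2L]) / gs$spacing[2L] + 0.5) + 1L
  cbind(ix, iy)
}

.cell_centers <- function(gs) {
  list(x = gs$origin[1L] + (seq_len(gs$nx) - 1L) * gs$spacing[1L],
       y = gs$origin[2L] + (seq_len(gs$ny) - 1L) * gs$spacing[2L])
}

#' Weighted 2D PMF from unbiased sample weights
#'
#' Bins samples with their MBAR (or other normalized) weights and sets
#' \eqn{F(\mathrm{cell}) = -kT \ln \sum_{n \in \mathrm{cell}} w_n}, shifted
#' so the minimum over occupied cells is 0.  The PMF is invariant to a
#' rescaling of the weights.
#'
#' @param samples a `window_samples` object (or data.frame with `cv_1`,
#'   `cv_2` columns).
#' @param weights normalized per-sample weights (e.g. from [mbar_solve()]).
#' @param gs a [grid_spec()]; defaults to the sample bounding box + 5%
#'   padding at 60 x 60.
#' @param kT thermal energy, kcal/mol.
#' @return a [new_pmf_grid()].
#' @export
pmf_2d <- function(samples, weights, gs = NULL,
                   kT = thermal_energy(300, "K")) {
  df <- if (inherits(samples, "window_samples")) samples$samples else samples
  xy <- as.matrix(df[, c("cv_1", "cv_2")])
  stopifnot(length(weights) == nrow(xy))
  weights <- weights / sum(weights)
  if (is.null(gs)) gs <- .default_grid_spec(xy)
  cells <- .cell_of(gs, xy)
  inside <- cells[, 1L] >= 1L & cells[, 1L] <= gs$nx &
            cells[, 2L] >= 1L & cells[, 2L] <= gs$ny
  if (!any(inside)) stop("all samples fall outside the grid")
  idx <- (cells[inside, 2L] - 1L) * gs$nx + cells[inside, 1L]
  wsum <- numeric(gs$nx * gs$ny)
  tap <- tapply(weights[inside], idx, sum)
  wsum[as.integer(names(tap))] <- tap
  counts <- numeric(gs$nx * gs$ny)
  tct <- table(idx)
  counts[as.integer(names(tct))] <- as.integer(tct)
  vals <- ifelse(wsum > 0, -kT * log(wsum), NA_real_)
  new_pmf_grid(gs$origin, gs$spacing,
               matrix(vals, gs$nx, gs$ny),
               matrix(counts, gs$nx, gs$ny), kT)
}

#' Evaluate an analytic potential on a grid
#'
#' Exact gridding of an analytic surface (every cell occupied, count 1),
#' gauge-shifted so the minimum cell is 0.  This is the deterministic route
#' to a `pmf_grid` for path/barrier analysis of fixture landscapes.
#'
#' @param potential a 2D [new_potential()].
#' @param gs a [grid_spec()].
#' @param kT recorded on the grid (no effect on values).
#' @return a [new_pmf_grid()].
#' @export
potential_to_grid <- function(potential, gs,
                              kT = thermal_energy(300, "K")) {
  stopifnot(potential$dimensionality == 2L)
  cc <- .cell_centers(gs)
  pts <- as.matrix(expand.grid(x = cc$x, y = cc$y))
  vals <- matrix(potential$energy(pts), gs$nx, gs$ny)
  new_pmf_grid(gs$origin, gs$spacing, vals,
               matrix(1L, gs$nx, gs$ny), kT)
}

#' Free-energy offset between two points of a PMF
#'
#' Returns \eqn{F(b) - F(a)} where each point's value is read as the minimum
#' over the 3 x 3 cell neighborhood of the cell containing it (reduces
#' binning noise at basin bottoms; recorded choice).
#'
#' @param pmf a `pmf_grid`.
#' @param point_a,point_b length-2 coordinates (e.g. detected minima).
#' @return offset in kcal/mol.
#' @export
pmf_offset <- function(pmf, point_a, point_b) {
  val <- function(p) {
    ij <- .cell_of(pmf, rbind(as.numeric(p)))
    if (ij[1L] < 1L || ij[1L] > pmf$nx || ij[2L] < 1L || ij[2L] > pmf$ny)
      stop("point (", p[1L], ", ", p[2L], ") is outside the grid")
    ix <- max(1L, ij[1L] - 1L):min(pmf$nx, ij[1L] + 1L)
    iy <- max(1L, ij[2L] - 1L):min(pmf$ny, ij[2L] + 1L)
    block <- pmf$values[ix, iy]
    if (all(is.na(block)))
      stop("point (", p[1L], ", ", p[2L], ") maps to unoccupied cells")
    min(block, na.rm = TRUE)
  }
  val(point_b) - val(point_a)
}
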