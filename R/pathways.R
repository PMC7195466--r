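#' Local minima of a gridded PMF
#'
#' Finds connected plateaus of occupied cells (8-connectivity, equal values)
#' that lie strictly below every occupied cell adjacent to the plateau, then
#' filters shallow minima by topographic prominence: a non-global minimum is
#' kept only if the minimax barrier separating it from any lower minimum
#' exceeds `min_prominence` above its own value.  The plateau definition
#' makes detection robust to exact value ties (e.g. the mirror-symmetric
#' cell pairs of a symmetric landscape); each plateau is reported once, at
#' its lexicographically first cell.  A flat surface has no strictly higher
#' surroundings and yields no minima.
#'
#' @param pmf a `pmf_grid`.
#' @param min_prominence prominence threshold, kcal/mol (config-exposed;
#'   default 0.5, roughly three times the binning noise of the default
#'   sampling budget).
#' @param min_count minimum occupancy count for a cell to seed a candidate
#'   minimum (default 5).  Free energies of barely-occupied fringe cells
#'   carry shot noise of order kT and produce spurious dimples; such cells
#'   stay occupied for path purposes but cannot nucleate minima.  The
#'   threshold is capped at the grid's maximum count, so deterministic
#'   grids (every cell evaluated once, e.g. [potential_to_grid()]) are
#'   unaffected.
#' @return data.frame with columns `ix`, `iy` (cell indices), `x`, `y` (cell
#'   centers) and `value`, sorted by value.  May be empty.
#' @export
find_minima <- function(pmf, min_prominence = 0.5, min_count = 5L) {
  v <- pmf$values
  nx <- pmf$nx; ny <- pmf$ny
  occ <- pmf$occupied
  min_count <- min(min_count, max(pmf$counts))
  visited <- matrix(FALSE, nx, ny)
  neighbors_of <- function(ix, iy) {
    out <- NULL
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      jx <- ix + dx; jy <- iy + dy
      if (jx >= 1 && jx <= nx && jy >= 1 && jy <= ny && occ[jx, jy])
        out <- rbind(out, c(jx, jy))
    }
    out
  }
  cand <- list()
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    if (!occ[ix, iy] || visited[ix, iy]) next
    if (pmf$counts[ix, iy] < min_count) next
    val <- v[ix, iy]
    # flood-fill the equal-value plateau containing this cell
    stack <- list(c(ix, iy))
    plateau <- NULL
    has_higher <- FALSE
    has_lower <- FALSE
    while (length(stack)) {
      c0 <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (visited[c0[1L], c0[2L]]) next
      visited[c0[1L], c0[2L]] <- TRUE
      plateau <- rbind(plateau, c0)
      nb0 <- neighbors_of(c0[1L], c0[2L])
      for (m in seq_len(if (is.null(nb0)) 0L else nrow(nb0))) {
        jx <- nb0[m, 1L]; jy <- nb0[m, 2L]
        if (v[jx, jy] == val) {
          if (!visited[jx, jy]) stack[[length(stack) + 1L]] <- c(jx, jy)
        } else if (v[jx, jy] > val) {
          has_higher <- TRUE
        } else {
          has_lower <- TRUE
        }
      }
    }
    if (has_higher && !has_lower) {
      ord <- order(plateau[, 1L], plateau[, 2L])
      cand[[length(cand) + 1L]] <- c(plateau[ord[1L], ], val)
    }
  }
  if (!length(cand))
    return(data.frame(ix = integer(), iy = integer(), x = numeric(),
                      y = numeric(), value = numeric()))
  m <- do.call(rbind, cand)
  m <- m[order(m[, 3L]), , drop = FALSE]
  keep <- rep(TRUE, nrow(m))
  if (nrow(m) > 1L && min_prominence > 0) {
    for (i in 2:nrow(m)) {
      # topographic prominence: the key saddle is the lowest point over
      # which any strictly lower candidate can be reached; candidates on
      # occupied islands disconnected from all lower ones are sampling
      # debris and dropped
      lower <- m[seq_len(i - 1L), 1:2, drop = FALSE]
      sad <- tryCatch(.minimax_to_set(pmf, m[i, 1:2], lower),
                      error = function(e) NA_real_)
      keep[i] <- !is.na(sad) && (sad - m[i, 3L]) >= min_prominence
    }
  }
  m <- m[keep, , drop = FALSE]
  cc <- .cell_centers(pmf)
  data.frame(ix = as.integer(m[, 1L]), iy = as.integer(m[, 2L]),
             x = cc$x[m[, 1L]], y = cc$y[m[, 2L]], value = m[, 3L])
}

# Exact widest-path (minimax) value between two cells over the occupied
# 8-connected grid: sort cells by value, union-find until connected; the
# value of the connecting cell is the minimax path maximum.  Ties broken by
# lexicographic cell order for determinism.
.minimax_value <- function(pmf, cell_a, cell_b) {
  .minimax_to_set(pmf, cell_a, rbind(cell_b))
}

# minimax value from cell_a to the nearest (in the minimax sense) of a set
# of target cells
.minimax_to_set <- function(pmf, cell_a, targets) {
  nx <- pmf$nx; ny <- pmf$ny
  occ <- pmf$occupied
  v <- pmf$values
  id <- function(ix, iy) (iy - 1L) * nx + ix
  if (is.null(dim(targets))) targets <- rbind(targets)
  if (nrow(targets) == 0L) stop("no target cells")
  a <- id(cell_a[1L], cell_a[2L])
  bs <- id(targets[, 1L], targets[, 2L])
  if (!occ[cell_a[1L], cell_a[2L]] || !all(occ[targets]))
    stop("start/end cells must be occupied")
  if (a %in% bs) return(v[cell_a[1L], cell_a[2L]])
  occ_idx <- which(occ)
  ord <- occ_idx[order(v[occ_idx], occ_idx)]
  parent <- seq_len(nx * ny)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  added <- logical(nx * ny)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
  off <- off[!(off[, 1L] == 0 & off[, 2L] == 0), ]
  for (cell in ord) {
    iy <- (cell - 1L) %/% nx + 1L
    ix <- cell - (iy - 1L) * nx
    added[cell] <- TRUE
    for (o in seq_len(nrow(off))) {
      jx <- ix + off[o, 1L]; jy <- iy + off[o, 2L]
      if (jx < 1L || jx > nx || jy < 1L || jy > ny) next
      j <- id(jx, jy)
      if (added[j]) {
        ra <- find(cell); rb <- find(j)
        if (ra != rb) parent[ra] <- rb
      }
    }
    ra <- find(a)
    for (b in bs) if (ra == find(b)) return(v[ix, iy])
  }
  stop("start and end cells are disconnected in the occupied region")
}

#' Minimax (widest-path) barrier between two minima
#'
#' Brute-force oracle for the saddle height: the minimum over all
#' 8-connected occupied grid paths of the maximum cell value along the path.
#' Exact on the grid.
#'
#' @param pmf a `pmf_grid`.
#' @param start_min,end_min rows of [find_minima()] output (or any list with
#'   `ix`, `iy`).
#' @return the minimax path maximum, kcal/mol (in the grid's global-minimum
#'   gauge).
#' @export
minimax_barrier <- function(pmf, start_min, end_min) {
  .minimax_value(pmf, c(start_min$ix, start_min$iy),
                 c(end_min$ix, end_min$iy))
}

# bilinear interpolation of the PMF (unoccupied cells filled with a finite
# ceiling so gradients always point back into sampled territory)
.pmf_interp <- function(pmf) {
  cc <- .cell_centers(pmf)
  v <- pmf$values
  fill <- max(v, na.rm = TRUE) + 5
  v[is.na(v)] <- fill
  function(p) {
    # returns list(value, grad) at points p (n x 2), clamped to the grid
    x <- pmin(pmax(p[, 1L], cc$x[1L]), cc$x[pmf$nx])
    y <- pmin(pmax(p[, 2L], cc$y[1L]), cc$y[pmf$ny])
    ix <- pmin(pmax(findInterval(x, cc$x), 1L), pmf$nx - 1L)
    iy <- pmin(pmax(findInterval(y, cc$y), 1L), pmf$ny - 1L)
    tx <- (x - cc$x[ix]) / pmf$spacing[1L]
    ty <- (y - cc$y[iy]) / pmf$spacing[2L]
    i00 <- cbind(ix, iy); i10 <- cbind(ix + 1L, iy)
    i01 <- cbind(ix, iy + 1L); i11 <- cbind(ix + 1L, iy + 1L)
    v00 <- v[i00]; v10 <- v[i10]; v01 <- v[i01]; v11 <- v[i11]
    val <- (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
           (1 - tx) * ty * v01 + tx * ty * v11
    gx <- ((1 - ty) * (v10 - v00) + ty * (v11 - v01)) / pmf$spacing[1L]
    gy <- ((1 - tx) * (v01 - v00) + tx * (v11 - v10)) / pmf$spacing[2L]
    list(value = val, grad = cbind(gx, gy))
  }
}

#' Minimum free-energy path on a gridded PMF
#'
#' Zero-temperature string method on the bilinearly interpolated grid: the
#' path is initialized as a quadratic Bezier arc from `start_min` to
#' `end_min` (bulging into the requested branch half-plane, or the straight
#' segment when unconstrained), then evolved by steepest descent with
#' arc-length reparameterization each step and pinned endpoints, until the
#' maximum point displacement per iteration falls below `tol`.
#'
#' The branch constraint restricts the path to one side of the axis through
#' the two endpoint minima (the symmetry axis of the two-branch loading
#' landscape): points that cross are projected back onto the axis.
#'
#' @param pmf a `pmf_grid`.
#' @param start_min,end_min rows of [find_minima()] output.
#' @param branch `"upper"`, `"lower"` or `"unconstrained"`.
#' @param n_points number of path points.
#' @param tol convergence threshold on per-iteration displacement (defaults
#'   to 1e-3 of the grid spacing).
#' @param max_iter maximum string iterations.
#' @param path_smoothing light per-iteration smoothing weight kappa on the
#'   evolving path (`p_i <- (1-2k)p_i + k(p_{i-1}+p_{i+1})`); acts as a
#'   curvature penalty that keeps the string from being trapped by
#'   cell-level noise of sampled PMFs.  0 disables.
#' @return object of class `fe_path`: data.frame with columns `index`, `x`,
#'   `y`, `F` plus attributes `branch`, `converged`, `iterations`.  Errors
#'   if the converged path runs through unoccupied cells.
#' @export
mfep_on_grid <- function(pmf, start_min, end_min,
                         branch = c("unconstrained", "upper", "lower"),
                         n_points = 100L, tol = NULL, max_iter = 5000L,
                         path_smoothing = 0.1) {
  branch <- match.arg(branch)
  p0 <- c(start_min$x, start_min$y)
  p1 <- c(end_min$x, end_min$y)
  h <- min(pmf$spacing)
  if (is.null(tol)) tol <- 1e-3 * h
  interp <- .pmf_interp(pmf)
  if (all(p0 == p1)) {
    path <- data.frame(index = 0L, x = p0[1L], y = p0[2L],
                       F = interp(rbind(p0))$value)
    attr(path, "branch") <- branch
    attr(path, "converged") <- TRUE
    attr(path, "iterations") <- 0L
    class(path) <- c("fe_path", "data.frame")
    return(path)
  }
  u <- p1 - p0
  len <- sqrt(sum(u^2))
  u <- u / len
  nrm <- c(-u[2L], u[1L])             # left normal of start->end
  side <- switch(branch, upper = 1, lower = -1, unconstrained = 0)
  tpar <- seq(0, 1, length.out = n_points)
  if (side == 0) {
    pts <- cbind(p0[1L] + tpar * (p1[1L] - p0[1L]),
                 p0[2L] + tpar * (p1[2L] - p0[2L]))
  } else {
    ctrl <- (p0 + p1) / 2 + side * nrm * len    # quadratic Bezier control
    pts <- outer((1 - tpar)^2, p0) + outer(2 * tpar * (1 - tpar), ctrl) +
           outer(tpar^2, p1)
  }
  clamp_branch <- function(pts) {
    if (side == 0) return(pts)
    s <- (pts[, 1L] - p0[1L]) * nrm[1L] + (pts[, 2L] - p0[2L]) * nrm[2L]
    bad <- side * s < 0
    if (any(bad)) {
      pts[bad, 1L] <- pts[bad, 1L] - s[bad] * nrm[1L]
      pts[bad, 2L] <- pts[bad, 2L] - s[bad] * nrm[2L]
    }
    pts
  }
  inner <- 2:(n_points - 1L)
  converged <- FALSE
  iters <- 0L
  step <- NULL
  step0 <- NULL
  for (it in seq_len(max_iter)) {
    old <- pts
    g <- interp(pts)$grad
    # move only by the gradient component normal to the path, so the update
    # vanishes on the converged MFEP instead of cycling tangentially
    tang <- pts[c(2:n_points, n_points), ] - pts[c(1L, 1:(n_points - 1L)), ]
    tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
    g <- g - rowSums(g * tang) * tang
    gmax <- max(sqrt(rowSums(g^2)), 1e-12)
    # fixed descent step (frozen at the first iteration) so the update
    # magnitude tracks |g_perp|; annealed afterwards because the bilinear
    # gradient changes sign discontinuously across cell edges at the valley
    # floor, leaving a residual oscillation proportional to the step
    if (is.null(step)) step <- step0 <- 0.2 * h / gmax
    if (it > 500L && it %% 100L == 0L) step <- step * 0.7
    move <- step * g[inner, , drop = FALSE]
    mmax <- max(sqrt(rowSums(move^2)))
    if (mmax > 0.5 * h) move <- move * (0.5 * h / mmax)
    pts[inner, ] <- pts[inner, ] - move
    if (path_smoothing > 0) {
      # anneal the smoothing with the step so its contraction pressure
      # cannot outlive the gradient forces that balance it
      ka <- path_smoothing * step / step0
      pts[inner, ] <- (1 - 2 * ka) * pts[inner, , drop = FALSE] +
        ka * (pts[inner - 1L, , drop = FALSE] + pts[inner + 1L, , drop = FALSE])
    }
    pts <- clamp_branch(pts)
    pts <- .resample_polyline(pts, n_points)
    pts[1L, ] <- p0; pts[n_points, ] <- p1
    iters <- it
    if (max(sqrt(rowSums((pts - old)^2))) < tol) { converged <- TRUE; break }
  }
  cells <- .cell_of(pmf, pts)
  cells[, 1L] <- pmin(pmax(cells[, 1L], 1L), pmf$nx)
  cells[, 2L] <- pmin(pmax(cells[, 2L], 1L), pmf$ny)
  on_occ <- pmf$occupied[cells]
  if (!all(on_occ)) {
    first <- which(!on_occ)[1L]
    stop("MFEP escaped the occupied region at cell (",
         cells[first, 1L], ", ", cells[first, 2L], ")")
  }
  path <- data.frame(index = seq_len(n_points) - 1L,
                     x = pts[, 1L], y = pts[, 2L],
                     F = interp(pts)$value)
  attr(path, "branch") <- branch
  attr(path, "converged") <- converged
  attr(path, "iterations") <- iters
  class(path) <- c("fe_path", "data.frame")
  path
}

#' Energy barrier of a path, measured from a reference minimum
#'
#' The barrier is estimated as the maximum free-energy difference from the
#' reference (interfacial) position: peak = max F along the path (in the
#' grid's global-minimum gauge), baseline = F at the reference endpoint,
#' barrier = peak - baseline.
#'
#' @param path an `fe_path` from [mfep_on_grid()].
#' @param reference `"start"` or `"end"`: which endpoint is the reference
#'   (interfacial) minimum.
#' @param profile_window odd integer; width of a centered running mean
#'   applied to the path's free-energy profile before reading peak and
#'   baseline.  1 (default) reads the raw profile; paths extracted from
#'   sampled PMFs carry cell-level noise whose maximum is biased upward, and
#'   a short window (the full-study pipeline uses 9, about half a saddle
#'   width) suppresses that bias at a negligible cost in true peak height.
#' @return object of class `barrier_report`: list with `peak`, `baseline`,
#'   `barrier` (= peak - baseline exactly) and `branch`.
#' @export
barrier_from_path <- function(path, reference = c("start", "end"),
                              profile_window = 1L) {
  reference <- match.arg(reference)
  if (!nrow(path)) stop("empty path")
  stopifnot(profile_window >= 1L, profile_window %% 2L == 1L)
  f <- path$F
  if (profile_window > 1L && nrow(path) > profile_window) {
    half <- (profile_window - 1L) %/% 2L
    padded <- c(rep(f[1L], half), f, rep(f[length(f)], half))
    f <- as.numeric(stats::filter(padded, rep(1 / profile_window,
                                              profile_window),
                                  sides = 2L))[(half + 1L):(half + length(f))]
  }
  peak <- max(f)
  baseline <- if (reference == "start") f[1L] else f[length(f)]
  structure(list(peak = peak, baseline = baseline,
                 barrier = peak - baseline,
                 branch = attr(path, "branch")),
            class = "barrier_report")
}

#' @export
print.barrier_report <- function(x, ...) {
  cat(sprintf("<barrier_report> branch %s: peak %.3f - baseline %.3f = barrier %.3f kcal/mol\n",
              x$branch, x$peak, x$baseline, x$barrier))
  invisible(x)
}

#' Resample a transition-state ensemble from one PMF cell
#'
#' Draws `n` samples with replacement from the samples falling in the target
#' cell, with probability proportional to their unbiased weights — the
#' reweighted resampling used to extract representative transition-state
#' configurations from the highest-energy cell of a path.
#'
#' @param samples a `window_samples` object (or its `samples` data.frame).
#' @param weights normalized per-sample weights (same order).
#' @param pmf the `pmf_grid` defining the cells.
#' @param target_cell list/row with `ix`, `iy`.
#' @param n number of draws (default 100).
#' @param seed integer RNG seed (required).
#' @return data.frame of the resampled rows (with a `draw` column).
#' @export
resample_transition_ensemble <- function(samples, weights, pmf, target_cell,
                                         n = 100L, seed) {
  if (missing(seed)) stop("seed is required")
  df <- if (inherits(samples, "window_samples")) samples$samples else samples
  cells <- .cell_of(pmf, as.matrix(df[, c("cv_1", "cv_2")]))
  in_cell <- cells[, 1L] == target_cell$ix & cells[, 2L] == target_cell$iy
  if (!any(in_cell)) stop("target cell contains no samples")
  idx <- which(in_cell)
  w <- weights[idx]
  set.seed(as.integer(seed))
  draw <- sample(idx, n, replace = TRUE, prob = w / sum(w))
  out <- df[draw, , drop = FALSE]
  out$draw <- seq_len(n)
  rownames(out) <- NULL
  out
}
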