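#' Weighted histogram analysis method (WHAM)
#'
#' Standard binned WHAM iteration, used as the independent oracle against
#' the MBAR route.  With per-window histograms \eqn{H_{kb}} over bins b,
#' iterate to self-consistency
#' \deqn{p_b = \frac{\sum_k H_{kb}}{\sum_k N_k e^{f_k - u_k(x_b)}},\qquad
#'       e^{-f_k} = \sum_b p_b\, e^{-u_k(x_b)},}
#' with \eqn{u_k(x_b)} the reduced window bias at the bin center.  The PMF is
#' \eqn{-kT \ln p_b}, min-shifted to 0; empty bins are flagged, never
#' interpolated.
#'
#' Works in the native dimension of the samples: 1D samples use `bins` bins
#' along `cv_1` (returned as an `nx x 1` grid), 2D samples a `bins x bins`
#' grid.
#'
#' @param samples a `window_samples` object.
#' @param windows the [build_windows()] object that generated the biases.
#' @param bins number of bins per axis.
#' @param kT thermal energy, kcal/mol.
#' @param tol convergence tolerance on max |f change|.
#' @param max_iter maximum iterations.
#' @param gs optional [grid_spec()] (2D only); defaults to the sample
#'   bounding box + 5% padding.
#' @return a [new_pmf_grid()] with attributes `f` (per-window free energies,
#'   reduced units, gauge `f[1] = 0`) and `iterations`.
#' @export
wham_solve <- function(samples, windows, bins = 60L,
                       kT = thermal_energy(300, "K"), tol = 1e-10,
                       max_iter = 50000L, gs = NULL) {
  df <- samples$samples
  cv_cols <- grep("^cv_", names(df), value = TRUE)
  d <- length(cv_cols)
  stopifnot(d %in% c(1L, 2L))
  cvs <- as.matrix(df[, cv_cols, drop = FALSE])
  win_of <- match(df$window, windows$ids)
  K <- nrow(windows$centers)
  N_k <- tabulate(win_of, nbins = K)
  if (any(N_k == 0)) stop("every window must contribute samples")
  if (d == 1L) {
    rx <- range(cvs[, 1L]); px <- 0.05 * diff(rx)
    gs <- grid_spec(rx + c(-px, px), c(-0.5, 0.5), nx = bins, ny = 1L)
    centers <- cbind(.cell_centers(gs)$x)
    idx <- pmin(pmax(.cell_of(gs, cbind(cvs[, 1L], 0))[, 1L], 1L), gs$nx)
  } else {
    if (is.null(gs)) gs <- .default_grid_spec(cvs, bins, bins)
    cc <- .cell_centers(gs)
    centers <- as.matrix(expand.grid(x = cc$x, y = cc$y))
    ij <- .cell_of(gs, cvs)
    keep <- ij[, 1L] >= 1L & ij[, 1L] <= gs$nx &
            ij[, 2L] >= 1L & ij[, 2L] <= gs$ny
    if (!all(keep)) stop("bin spec does not cover all samples")
    idx <- (ij[, 2L] - 1L) * gs$nx + ij[, 1L]
  }
  B <- nrow(centers)
  H <- numeric(B)
  tb <- tapply(rep(1, length(idx)), idx, sum)
  H[as.integer(names(tb))] <- tb
  # reduced bias at bin centers: u[b, k]
  u <- matrix(0, B, K)
  kvec <- rep_len(windows$k, K)
  for (k in seq_len(K)) {
    dxb <- sweep(centers, 2L, windows$centers[k, seq_len(d)])
    u[, k] <- kvec[k] * rowSums(dxb^2) / kT
  }
  eu <- exp(-u)                      # B x K
  f <- rep(0, K)
  iters <- 0L
  repeat {
    denom <- drop(eu %*% (N_k * exp(f)))
    p <- ifelse(denom > 0, H / denom, 0)
    f_new <- -log(pmax(drop(crossprod(eu, p)), .Machine$double.xmin))
    f_new <- f_new - f_new[1L]
    delta <- max(abs(f_new - f))
    f <- f_new
    iters <- iters + 1L
    if (delta < tol || iters >= max_iter) break
  }
  if (delta >= tol)
    stop("WHAM did not converge: residual ", signif(delta, 3), " after ",
         iters, " iterations")
  vals <- ifelse(p > 0, -kT * log(p), NA_real_)
  grid <- new_pmf_grid(gs$origin, gs$spacing,
                       matrix(vals, gs$nx, gs$ny),
                       matrix(H, gs$nx, gs$ny), kT)
  attr(grid, "f") <- f
  attr(grid, "iterations") <- iters
  grid
}
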