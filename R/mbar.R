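#' Multistate Bennett acceptance ratio (MBAR) estimator
#'
#' Solves the MBAR self-consistent equations for the per-window reduced free
#' energies \eqn{f_k} from umbrella-window samples.  Only the bias energies
#' enter: with a shared unbiased surface the reduced potential of sample
#' \eqn{x_n} in window \eqn{k} is \eqn{u_k(x_n) = V_k(x_n)/kT}, and the
#' unbiased surface cancels from the estimating equations
#' \deqn{f_k = -\ln \sum_n \frac{\exp(-u_k(x_n))}
#'       {\sum_j N_j \exp(f_j - u_j(x_n))}.}
#' The gauge is fixed by \eqn{f_1 = 0}.  The solver minimises the convex MBAR
#' objective by BFGS (analytic gradient) and then polishes with
#' self-consistent iteration until the residual
#' \eqn{\max_k |f_k - \mathrm{SC}(f)_k|} falls below `tol`.  Unbiased sample
#' weights are
#' \eqn{w_n \propto 1 / \sum_k N_k \exp(f_k - u_k(x_n))}, normalized to 1.
#'
#' @param samples a `window_samples` object from [run_reus()] (or any list
#'   with a `samples` data.frame holding `window` and `cv_*` columns).
#' @param windows the [build_windows()] object that generated the biases.
#' @param kT thermal energy, kcal/mol.
#' @param tol convergence tolerance on the self-consistency residual.
#' @param max_iter maximum polish iterations.
#' @return object of class `mbar_result`: list with `f` (per-window reduced
#'   free energies, `f[1] == 0`), `weights` (normalized unbiased weights, one
#'   per sample, in the row order of `samples$samples`), `iterations`,
#'   `residual`, `window_ids`, `kT`.
#' @export
mbar_solve <- function(samples, windows, kT = thermal_energy(300, "K"),
                       tol = 1e-8, max_iter = 10000L) {
  df <- samples$samples
  cvs <- as.matrix(df[, grep("^cv_", names(df)), drop = FALSE])
  win_of <- match(df$window, windows$ids)
  if (anyNA(win_of)) stop("samples refer to unknown window ids")
  K <- nrow(windows$centers)
  N_k <- tabulate(win_of, nbins = K)
  if (any(N_k == 0))
    stop("window(s) ", paste(windows$ids[N_k == 0], collapse = ", "),
         " contributed no samples")
  N <- nrow(cvs)
  # u[k, n]: reduced bias energy of sample n evaluated in window k
  u <- matrix(0, K, N)
  kvec <- rep_len(windows$k, K)
  for (k in seq_len(K)) {
    dx <- sweep(cvs, 2L, windows$centers[k, ])
    u[k, ] <- kvec[k] * rowSums(dx^2) / kT
  }
  logN <- log(N_k)

  # log denominator log sum_j N_j exp(f_j - u_jn), stabilised
  log_denom <- function(f) {
    a <- f + logN - u            # K x N
    m <- apply(a, 2L, max)
    m + log(colSums(exp(sweep(a, 2L, m))))
  }
  self_consistent <- function(f) {
    ld <- log_denom(f)
    b <- -u - rep(ld, each = K)  # K x N
    m <- apply(b, 1L, max)
    -(m + log(rowSums(exp(b - m))))
  }
  # convex MBAR objective over f[2:K] (gauge f1 = 0)
  obj <- function(f_free) {
    f <- c(0, f_free)
    sum(log_denom(f)) - sum(N_k * f)
  }
  grad <- function(f_free) {
    f <- c(0, f_free)
    ld <- log_denom(f)
    w <- exp(sweep(f + logN - u, 2L, ld))  # K x N window responsibilities
    (rowSums(w) - N_k)[-1L]
  }
  f <- rep(0, K)
  if (K > 1L) {
    opt <- stats::optim(f[-1L], obj, grad, method = "BFGS",
                        control = list(maxit = 500L, reltol = 1e-14))
    f <- c(0, opt$par)
  }
  residual <- Inf
  iters <- 0L
  repeat {
    f_new <- self_consistent(f)
    f_new <- f_new - f_new[1L]
    residual <- max(abs(f_new - f))
    f <- f_new
    iters <- iters + 1L
    if (residual < tol || iters >= max_iter) break
  }
  if (residual >= tol)
    stop("MBAR did not converge: residual ", signif(residual, 3),
         " after ", iters, " iterations (tol ", tol, ")")
  log_w <- -log_denom(f)
  log_w <- log_w - max(log_w)
  w <- exp(log_w)
  w <- w / sum(w)
  structure(list(f = f, weights = w, iterations = iters,
                 residual = residual, window_ids = windows$ids,
                 N_k = N_k, kT = kT),
            class = "mbar_result")
}

#' @export
print.mbar_result <- function(x, ...) {
  cat(sprintf("<mbar_result> %d windows, %d samples; residual %.2e after %d iterations\n",
              length(x$f), length(x$weights), x$residual, x$iterations))
  invisible(x)
}
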