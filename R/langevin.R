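#' Overdamped Langevin dynamics on an analytic potential
#'
#' Euler-Maruyama integration of the overdamped Langevin equation
#' \deqn{x \leftarrow x - \frac{\nabla F + \sum_b \nabla V_b}{\gamma}\,dt
#'       + \sqrt{2\,kT\,dt/\gamma}\;\xi,\qquad \xi \sim N(0, I).}
#' Bias potentials may be time dependent (e.g. the moving flat-bottom exit
#' restraint); they are evaluated at the time of each step.  The trajectory is
#' stride-thinned inside the sampler so sample counts are reproducible from
#' the configuration alone.  Identical seeds give bit-identical trajectories.
#'
#' @param potential a [new_potential()].
#' @param biases list of `bias` objects (possibly empty).
#' @param x0 starting point (length-d vector).
#' @param dt time step (> 0).
#' @param friction friction coefficient gamma (> 0).
#' @param kT thermal energy, kcal/mol (>= 0; 0 gives pure gradient descent).
#' @param n_steps number of integrator steps.
#' @param stride record every `stride`-th step; `floor(n_steps/stride)`
#'   samples are returned.
#' @param seed integer RNG seed (required).
#' @return object of class `trajectory`: list with `times`, `x`
#'   (samples x d matrix), `bias_energy`, and the integrator parameters.
#' @export
run_langevin <- function(potential, biases = list(), x0, dt = 1e-3,
                         friction = 1, kT = thermal_energy(300, "K"),
                         n_steps, stride = 1L, seed) {
  stopifnot(inherits(potential, "potential"), dt > 0, friction > 0, kT >= 0,
            n_steps >= 1, stride >= 1)
  if (missing(seed)) stop("seed is required")
  d <- potential$dimensionality
  x0 <- .as_points(x0, d)
  set.seed(as.integer(seed))
  res <- .propagate(potential, biases, x0, dt, friction, kT,
                    as.integer(n_steps), as.integer(stride), t0 = 0)
  structure(
    list(times = res$times, x = res$samples[[1L]],
         bias_energy = res$bias_energy[, 1L],
         seed = as.integer(seed),
         params = list(dt = dt, friction = friction, kT = kT,
                       n_steps = as.integer(n_steps),
                       stride = as.integer(stride),
                       potential = potential$metadata$name,
                       biases = lapply(biases, function(b) b$metadata))),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples x %dD, t in [%g, %g], kT=%g, seed=%d\n",
              nrow(x$x), ncol(x$x), min(x$times), max(x$times),
              x$params$kT, x$seed))
  invisible(x)
}

# Core propagator: steps n_walkers in parallel (rows of x).  Global `biases`
# apply to all walkers; `centers`/`k_win` optionally add a per-walker harmonic
# window restraint V = k |x - center_w|^2, evaluated vectorised across
# walkers (the umbrella-sampling hot path).  Returns strided samples per
# walker plus the final state.  Uses the current RNG stream (caller seeds).
# `offset` is the number of steps already taken before this call in the same
# recording series: records land on global steps that are multiples of
# stride, so stride may exceed the per-call step count (e.g. exchange blocks
# shorter than the recording stride).
.propagate <- function(potential, biases, x, dt, friction, kT,
                       n_steps, stride, t0 = 0, centers = NULL, k_win = NULL,
                       offset = 0L) {
  d <- potential$dimensionality
  nw <- nrow(x)
  n_rec <- (offset + n_steps) %/% stride - offset %/% stride
  rec <- vector("list", nw)
  samples <- array(NA_real_, c(n_rec, nw, d))
  bias_e <- matrix(NA_real_, n_rec, nw)
  times <- numeric(n_rec)
  noise_sd <- sqrt(2 * kT * dt / friction)
  bound <- potential$domain_bound
  irec <- 0L
  for (step in seq_len(n_steps)) {
    t_now <- t0 + (step - 1L) * dt
    g <- potential$gradient(x)
    for (b in biases) g <- g + b$gradient(x, t_now)
    if (!is.null(centers)) g <- g + 2 * k_win * (x - centers)
    x <- x - g * (dt / friction)
    if (noise_sd > 0)
      x <- x + matrix(stats::rnorm(nw * d, sd = noise_sd), nw, d)
    if (any(!is.finite(x)) || any(abs(x) > bound))
      stop("trajectory diverged: |x| exceeded the domain bound ", bound,
           " at step ", step)
    if ((offset + step) %% stride == 0L) {
      irec <- irec + 1L
      t_rec <- t0 + step * dt
      times[irec] <- t_rec
      samples[irec, , ] <- x
      be <- numeric(nw)
      for (b in biases) be <- be + b$energy(x, t_rec)
      if (!is.null(centers)) be <- be + k_win * rowSums((x - centers)^2)
      bias_e[irec, ] <- be
    }
  }
  list(times = times,
       samples = lapply(seq_len(nw), function(w)
         matrix(samples[, w, ], ncol = d)),
       bias_energy = bias_e, final = x)
}
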