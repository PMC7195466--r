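#' One Hamiltonian replica-exchange sweep
#'
#' Attempts Metropolis swaps of configurations between neighboring umbrella
#' windows, in two alternating phases around the ring: first the even edges
#' (0-1, 2-3, ...), then the odd edges (1-2, 3-4, ..., including the closing
#' n-1 to 0 edge on a cyclic path).  A swap of configurations \eqn{x_i, x_j}
#' between windows i and j is accepted with probability
#' \deqn{\min\{1, \exp(-[V_i(x_j) + V_j(x_i) - V_i(x_i) - V_j(x_j)]/kT)\}.}
#'
#' @param windows an [build_windows()] object.
#' @param states `n x d` matrix; row w is the configuration currently held by
#'   window w.
#' @param kT thermal energy, kcal/mol.
#' @param replica_of integer vector tracking which replica each window holds
#'   (permuted alongside the states); defaults to `1:n`.
#' @return list with `states`, `replica_of`, and `log` — a data.frame with
#'   one row per attempted edge (`edge_i`, `edge_j` 0-based ids, `accepted`).
#' @export
replica_exchange_sweep <- function(windows, states, kT,
                                   replica_of = seq_len(nrow(states))) {
  stopifnot(inherits(windows, "umbrella_windows"))
  n <- nrow(windows$centers)
  if (nrow(states) != n)
    stop("need exactly one walker per window (", n, "), got ", nrow(states))
  edges <- windows$neighbors
  phase <- (seq_len(nrow(edges)) - 1L) %% 2L
  accepted <- logical(nrow(edges))
  for (ph in c(0L, 1L)) {
    sel <- which(phase == ph)
    if (!length(sel)) next
    i <- edges[sel, 1L]; j <- edges[sel, 2L]
    d_e <- .window_energy(windows, states[j, , drop = FALSE], i) +
           .window_energy(windows, states[i, , drop = FALSE], j) -
           .window_energy(windows, states[i, , drop = FALSE], i) -
           .window_energy(windows, states[j, , drop = FALSE], j)
    acc <- stats::runif(length(sel)) < exp(-d_e / kT)
    swap <- sel[acc]
    if (length(swap)) {
      si <- edges[swap, 1L]; sj <- edges[swap, 2L]
      tmp <- states[si, , drop = FALSE]
      states[si, ] <- states[sj, , drop = FALSE]
      states[sj, ] <- tmp
      tmpr <- replica_of[si]
      replica_of[si] <- replica_of[sj]
      replica_of[sj] <- tmpr
    }
    accepted[sel] <- acc
  }
  list(states = states, replica_of = replica_of,
       log = data.frame(edge_i = windows$ids[edges[, 1L]],
                        edge_j = windows$ids[edges[, 2L]],
                        accepted = accepted))
}

#' Replica-exchange umbrella sampling on a cyclic window set
#'
#' Propagates one overdamped Langevin walker per umbrella window and attempts
#' replica-exchange sweeps every `exchange_interval` integrator steps.
#' Samples are recorded stride-thinned and attributed to the window whose
#' restraint was acting when they were recorded.  An equilibration phase of
#' `equilibration` time-units (with exchange active but nothing recorded)
#' precedes the production phase, mirroring the
#' equilibrate-then-produce protocol of umbrella-sampling practice.
#'
#' @param potential a [new_potential()].
#' @param windows an [build_windows()] object.
#' @param kT thermal energy, kcal/mol.
#' @param n_steps integrator steps per window.
#' @param dt,friction integrator parameters.
#' @param stride record every `stride`-th step.
#' @param exchange_interval steps between exchange sweeps (0 disables
#'   exchange).
#' @param equilibration equilibration length in time-units, discarded before
#'   recording (default one tenth of the production length).
#' @param seed integer RNG seed (required).
#' @param x0 optional `n x d` start configuration; defaults to the window
#'   centers.
#' @return object of class `window_samples`: list with `samples` (data.frame
#'   `window`, `replica`, `time`, `cv_1`..`cv_d`, `bias_energy`),
#'   `exchange_log` (data.frame `sweep`, `edge_i`, `edge_j`, `accepted`),
#'   `windows`, and the run parameters.
#' @export
run_reus <- function(potential, windows, kT = thermal_energy(300, "K"),
                     n_steps = 400000L, dt = 5e-5, friction = 0.1,
                     stride = 200L, exchange_interval = 12L, seed,
                     x0 = NULL, equilibration = n_steps * dt / 10) {
  stopifnot(inherits(potential, "potential"),
            inherits(windows, "umbrella_windows"))
  if (missing(seed)) stop("seed is required")
  n <- nrow(windows$centers)
  d <- potential$dimensionality
  if (ncol(windows$centers) != d)
    stop("window centers are ", ncol(windows$centers), "D, potential is ",
         d, "D")
  x <- if (is.null(x0)) windows$centers else .as_points(x0, d)
  set.seed(as.integer(seed))
  replica_of <- seq_len(n)
  block <- if (exchange_interval > 0) exchange_interval else n_steps
  # equilibration: propagate + exchange without recording
  eq_steps <- round(equilibration / dt)
  while (eq_steps > 0L) {
    n_this <- min(block, eq_steps)
    res <- .propagate(potential, list(), x, dt, friction, kT,
                      n_this, n_this + 1L, t0 = 0,
                      centers = windows$centers,
                      k_win = rep_len(windows$k, n))
    x <- res$final
    eq_steps <- eq_steps - n_this
    if (exchange_interval > 0 && eq_steps > 0L) {
      sw <- replica_exchange_sweep(windows, x, kT, replica_of)
      x <- sw$states
      replica_of <- sw$replica_of
    }
  }
  n_blocks <- ceiling(n_steps / block)
  chunks <- vector("list", n_blocks)
  xlogs <- vector("list", n_blocks)
  t0 <- 0
  steps_done <- 0L
  for (bl in seq_len(n_blocks)) {
    n_this <- min(block, n_steps - steps_done)
    res <- .propagate(potential, list(), x, dt, friction, kT,
                      n_this, stride, t0 = t0,
                      centers = windows$centers,
                      k_win = rep_len(windows$k, n),
                      offset = steps_done)
    x <- res$final
    if (length(res$times)) {
      n_rec <- length(res$times)
      chunks[[bl]] <- data.frame(
        window = rep(windows$ids, each = n_rec),
        replica = rep(replica_of, each = n_rec),
        time = rep(res$times, n),
        do.call(rbind, res$samples),
        bias_energy = as.vector(res$bias_energy))
    }
    steps_done <- steps_done + n_this
    t0 <- t0 + n_this * dt
    if (exchange_interval > 0 && steps_done < n_steps) {
      sw <- replica_exchange_sweep(windows, x, kT, replica_of)
      x <- sw$states
      replica_of <- sw$replica_of
      xlogs[[bl]] <- cbind(sweep = bl, sw$log)
    }
  }
  samples <- do.call(rbind, chunks)
  names(samples)[4:(3 + d)] <- paste0("cv_", seq_len(d))
  samples <- samples[order(samples$window, samples$time), ]
  rownames(samples) <- NULL
  structure(
    list(samples = samples,
         exchange_log = if (any(!vapply(xlogs, is.null, TRUE)))
           do.call(rbind, xlogs) else NULL,
         windows = windows,
         params = list(kT = kT, n_steps = as.integer(n_steps), dt = dt,
                       friction = friction, stride = as.integer(stride),
                       exchange_interval = as.integer(exchange_interval),
                       seed = as.integer(seed))),
    class = "window_samples")
}

#' @export
print.window_samples <- function(x, ...) {
  nacc <- if (is.null(x$exchange_log)) NA else mean(x$exchange_log$accepted)
  cat(sprintf("<window_samples> %d samples in %d windows; exchange acceptance %s\n",
              nrow(x$samples), nrow(x$windows$centers),
              if (is.na(nacc)) "(no exchange)" else sprintf("%.2f", nacc)))
  invisible(x)
}

#' String-method optimization of a guiding path
#'
#' Iteratively refines a guiding path toward the minimum free-energy loop of
#' a potential using sampled window means: each round (i) samples every
#' window with a harmonic restraint of constant `k_string` at the current
#' guiding points (overdamped Langevin, all windows propagated in parallel),
#' (ii) moves every non-fixed point toward the mean sampled CV of its
#' window by a damped update \eqn{p_i \leftarrow p_i + \eta\,(\bar{x}_i -
#' p_i)} (damping absorbs the sampling noise of the window means),
#' (iii) applies cyclic smoothing
#' \eqn{p_i \leftarrow (1 - 2\kappa) p_i + \kappa (p_{i-1} + p_{i+1})}, and
#' (iv) reparameterizes to equal arc length with the fixed points pinned.
#' Stops early when the maximum point displacement in a round falls below
#' `tol`.
#'
#' @param potential a [new_potential()].
#' @param path a `guiding_path`.
#' @param k_string restraint constant for the string phase (kcal/mol/A^2).
#' @param rounds maximum optimization rounds (>= 1).
#' @param samples_per_round integrator steps per window per round.
#' @param kappa smoothing weight in `[0, 0.5)`.
#' @param damping update weight eta in `(0, 1]`: 1 jumps to the window
#'   mean, smaller values average means over rounds.
#' @param tol convergence threshold on the root-mean-square point
#'   displacement per round (defaults to 2% of the path's bounding-box
#'   diagonal; window means are stochastic, so displacements never fall
#'   below their sampling noise).
#' @param kT,dt,friction,stride sampler parameters.
#' @param burn_in fraction of each round's samples discarded before the mean.
#' @param seed integer RNG seed (required).
#' @return the optimized `guiding_path`, with attributes `converged`
#'   (logical), `rounds_used` and `max_displacement`.  Non-convergence is
#'   reported with a warning, never silently.
#' @export
string_optimize <- function(potential, path, k_string = 2.39, rounds = 30L,
                            samples_per_round = 1000L, kappa = 0.1,
                            damping = 0.5, tol = NULL,
                            kT = thermal_energy(300, "K"),
                            dt = 1e-3, friction = 1, stride = 5L,
                            burn_in = 0.3, seed) {
  stopifnot(inherits(path, "guiding_path"), rounds >= 1,
            kappa >= 0, kappa < 0.5, k_string > 0,
            damping > 0, damping <= 1)
  if (missing(seed)) stop("seed is required")
  if (is.null(tol)) {
    diam <- sqrt(sum((apply(path$points, 2L, max) -
                      apply(path$points, 2L, min))^2))
    tol <- 0.02 * max(diam, 1)
  }
  set.seed(as.integer(seed))
  n <- nrow(path$points)
  fixed <- path$fixed
  free <- setdiff(seq_len(n), fixed)
  max_disp <- Inf
  used <- 0L
  for (round in seq_len(rounds)) {
    old <- path$points
    res <- .propagate(potential, list(), path$points, dt, friction, kT,
                      as.integer(samples_per_round), as.integer(stride),
                      centers = path$points, k_win = k_string)
    keep <- seq_along(res$times) > burn_in * length(res$times)
    means <- t(vapply(res$samples, function(s)
      colMeans(s[keep, , drop = FALSE]), numeric(ncol(old))))
    pts <- path$points
    pts[free, ] <- (1 - damping) * pts[free, , drop = FALSE] +
      damping * means[free, , drop = FALSE]
    if (kappa > 0 && path$cyclic) {
      prev <- pts[c(n, seq_len(n - 1L)), , drop = FALSE]
      nxt <- pts[c(seq_len(n)[-1L], 1L), , drop = FALSE]
      sm <- (1 - 2 * kappa) * pts + kappa * (prev + nxt)
      sm[fixed, ] <- pts[fixed, , drop = FALSE]
      pts <- sm
    }
    path$points <- pts
    path <- reparameterize_path(path)
    path$iteration <- path$iteration + 1L
    used <- round
    max_disp <- sqrt(mean(rowSums((path$points - old)^2)))
    if (max_disp < tol) break
  }
  converged <- max_disp < tol
  if (!converged)
    warning("string method did not converge in ", rounds,
            " rounds (RMS displacement ", signif(max_disp, 3), " > tol ",
            signif(tol, 3), ")")
  attr(path, "converged") <- converged
  attr(path, "rounds_used") <- used
  attr(path, "max_displacement") <- max_disp
  path
}
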