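# Shared fixtures and small numeric oracles used across test files.

kT300 <- thermal_energy(300, "K")

# central finite-difference gradient of a potential at one point
fd_gradient <- function(pot, p, h = 1e-6) {
  d <- pot$dimensionality
  vapply(seq_len(d), function(i) {
    e <- rep(0, d); e[i] <- h
    (energy_at(pot, p + e) - energy_at(pot, p - e)) / (2 * h)
  }, 0)
}

# random points in an annulus around the valley circle (avoids the origin,
# where polar coordinates are singular)
annulus_points <- function(n, r_min = 0.5, r_max = 3.5, seed = 1) {
  set.seed(seed)
  rho <- runif(n, r_min, r_max)
  th <- runif(n, -pi, pi)
  cbind(rho * cos(th), rho * sin(th))
}

# rigid-body transform of an n x 3 coordinate set
rigid_transform <- function(x, angles = c(0.3, -0.8, 1.2), shift = c(1, -2, 3)) {
  rx <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
  rz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  R <- rz(angles[3]) %*% ry(angles[2]) %*% rx(angles[1])
  sweep(x %*% t(R), 2, shift, `+`)
}

# window_samples object assembled from externally drawn samples, for
# estimator tests that need exact (non-dynamical) input
manual_window_samples <- function(samples_by_window, windows) {
  stopifnot(length(samples_by_window) == nrow(windows$centers))
  df <- do.call(rbind, lapply(seq_along(samples_by_window), function(i) {
    s <- as.matrix(samples_by_window[[i]])
    cvs <- as.data.frame(s)
    names(cvs) <- paste0("cv_", seq_len(ncol(s)))
    cbind(data.frame(window = windows$ids[i], replica = i,
                     time = seq_len(nrow(s))),
          cvs, data.frame(bias_energy = 0))
  }))
  structure(list(samples = df, exchange_log = NULL, windows = windows,
                 params = list()), class = "window_samples")
}

# two-window umbrella set sharing one center (flat-potential closed form)
two_windows_at_origin <- function(k1, k2, d = 2) {
  path <- init_guiding_path(4, "explicit",
                            points = matrix(0, 4, d),
                            active_id = 2, interface_id = 0)
  win <- build_windows(path, k = 1)
  win$centers <- win$centers[1:2, , drop = FALSE]
  win$k <- c(k1, k2)
  win$ids <- 0:1
  win$neighbors <- cbind(1:2, c(2L, 1L))
  win
}
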