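test_that("cyclic guiding paths have the documented ring geometry", {
  p <- init_guiding_path(48, "circle", radius = 2)
  expect_equal(nrow(p$points), 48)
  seg <- sqrt(rowSums((p$points[c(2:48, 1), ] - p$points)^2))
  # uniform chord spacing, chord of arc 2*pi*R/48
  expect_equal(seg, rep(2 * 2 * sin(pi / 48), 48), tolerance = 1e-10)
  # interface point (id 0) at angle pi, active point (id 24) at angle 0
  expect_equal(p$points[1, ], c(-2, 0), tolerance = 1e-12)
  expect_equal(p$points[25, ], c(2, 0), tolerance = 1e-12)
  # ring closure: windows n-1 and 0 are neighbors
  w <- build_windows(p, 0.48)
  expect_true(any(w$neighbors[, 1] == 48 & w$neighbors[, 2] == 1))
  p4 <- init_guiding_path(4, "circle", radius = 1, active_id = 2,
                          interface_id = 0)
  th <- sort(atan2(p4$points[, 2], p4$points[, 1]))
  expect_equal(th, c(-pi / 2, 0, pi / 2, pi), tolerance = 1e-12)
  expect_error(init_guiding_path(3), "at least 4")
  expect_error(init_guiding_path(8, active_id = 9), "out of range")
  expect_error(init_guiding_path(8, active_id = 2, interface_id = 2),
               "distinct")
})

test_that("reparameterization is idempotent, equalizes arcs, pins fixed points", {
  p <- init_guiding_path(24, "circle", radius = 2, active_id = 12,
                         interface_id = 0)
  theta <- atan2(p$points[, 2], p$points[, 1])
  rho <- 2 + 0.2 * sin(2 * theta)        # smooth non-uniform perturbation
  rho[p$fixed] <- 2
  p$points <- cbind(rho * cos(theta), rho * sin(theta))
  fixed_before <- p$points[p$fixed, ]
  # each application equalizes spacing along the current polyline; iterating
  # reaches the fixed point where consecutive chords are exactly equal
  r1 <- p
  for (i in 1:100) r1 <- reparameterize_path(r1)
  for (idx in list(1:13, c(13:24, 1))) {
    seg <- sqrt(rowSums(diff(r1$points[idx, ])^2))
    expect_lt(diff(range(seg)) / mean(seg), 1e-8)
  }
  expect_identical(r1$points[r1$fixed, ], fixed_before)
  # idempotent at the fixed point, with fixed points pinned exactly
  r2 <- reparameterize_path(r1)
  expect_equal(r2$points, r1$points, tolerance = 1e-12)
  expect_identical(r2$points[r2$fixed, ], fixed_before)
})

test_that("umbrella windows follow the stated bias convention", {
  p <- init_guiding_path(48, "circle", radius = 2)
  w <- build_windows(p, k = 0.48)
  expect_equal(nrow(w$centers), 48)
  # zero at its own center, k * d^2 at displacement d
  expect_equal(ligload:::.window_energy(w, w$centers[5, , drop = FALSE], 5L),
               0)
  shifted <- w$centers[5, , drop = FALSE] + c(1, 0)
  expect_equal(ligload:::.window_energy(w, shifted, 5L), 0.48)
  expect_error(build_windows(p, k = 0), "k > 0")
})

test_that("exchange accepts surely when the energy change vanishes", {
  p <- init_guiding_path(8, "circle", radius = 2, active_id = 4,
                         interface_id = 0)
  w <- build_windows(p, 1)
  states <- w$centers
  set.seed(1)
  # x_i = x_j for each attempted pair: force all states identical
  same <- matrix(rep(c(1, 1), each = 8), 8, 2)
  sw <- replica_exchange_sweep(w, same, kT = kT300)
  expect_true(all(sw$log$accepted))
  # identical centers, distinct samples: V_i == V_j, still always accepted
  w0 <- two_windows_at_origin(1, 1)
  st <- rbind(c(0.7, 0), c(-0.3, 0.2))
  sw0 <- replica_exchange_sweep(w0, st, kT = kT300)
  expect_true(all(sw0$log$accepted))
  expect_error(replica_exchange_sweep(w, states[1:3, ], kT300),
               "one walker per window")
})

test_that("empirical exchange acceptance matches the Metropolis integral", {
  kT <- kT300
  k <- 0.8
  d <- 1.1      # center separation
  pts <- rbind(c(0, 0), c(d, 0), c(2 * d, 0), c(3 * d, 0))
  path <- init_guiding_path(4, "explicit", points = pts, active_id = 2,
                            interface_id = 0, cyclic = FALSE)
  w <- build_windows(path, k)
  sigma <- sqrt(kT / (2 * k))
  # oracle: E[min(1, exp(-dE/kT))] by exact-sample Monte Carlo quadrature
  set.seed(301)
  m <- 400000
  xi <- rnorm(m, 0, sigma); xj <- rnorm(m, d, sigma)
  d_e <- k * ((xj)^2 + (xi - d)^2 - xi^2 - (xj - d)^2)
  p_oracle <- mean(pmin(1, exp(-d_e / kT)))
  # empirical: fresh exact states each sweep, read edge (0,1)
  set.seed(302)
  n_sweep <- 4000
  acc <- logical(n_sweep)
  for (s in seq_len(n_sweep)) {
    st <- cbind(rnorm(4, pts[, 1], sigma), rnorm(4, 0, sigma))
    sw <- replica_exchange_sweep(w, st, kT)
    acc[s] <- sw$log$accepted[sw$log$edge_i == 0 & sw$log$edge_j == 1]
  }
  se <- sqrt(p_oracle * (1 - p_oracle) / n_sweep)
  expect_lt(abs(mean(acc) - p_oracle), 3 * se + 3 / sqrt(m))
})

test_that("exchange changes mixing, not the per-window marginals", {
  rv <- make_test_potential("ring_valley", list(A = 5, R = 2))
  p <- init_guiding_path(8, "circle", radius = 2, active_id = 4,
                         interface_id = 0)
  w <- build_windows(p, 0.6)
  kT <- kT300
  with_ex <- run_reus(rv, w, kT = kT, n_steps = 40000, dt = 1e-3,
                      friction = 1, stride = 200, exchange_interval = 100,
                      seed = 401, equilibration = 2)
  no_ex <- run_reus(rv, w, kT = kT, n_steps = 40000, dt = 1e-3,
                    friction = 1, stride = 200, exchange_interval = 0,
                    seed = 402, equilibration = 2)
  for (win_id in c(0, 3)) {
    a <- subset(with_ex$samples, window == win_id)
    b <- subset(no_ex$samples, window == win_id)
    r_a <- sqrt(a$cv_1^2 + a$cv_2^2)
    r_b <- sqrt(b$cv_1^2 + b$cv_2^2)
    expect_gt(suppressWarnings(ks.test(r_a, r_b))$p.value, 0.01)
  }
})

test_that("replica-exchange walkers stay centred on their windows", {
  pot <- make_ga2ox_landscape()
  p <- init_guiding_path(48, "circle", radius = 2)
  w <- build_windows(p, 0.48)
  kT <- kT300
  ws <- run_reus(pot, w, kT = kT, n_steps = 20000, dt = 5e-4, friction = 0.5,
                 stride = 20, exchange_interval = 20, seed = 411,
                 equilibration = 1)
  mu <- aggregate(cbind(cv_1, cv_2) ~ window, ws$samples, mean)
  drift <- sqrt(rowSums((as.matrix(mu[, 2:3]) -
                         w$centers[match(mu$window, w$ids), ])^2))
  expect_lt(max(drift), 3 * sqrt(kT / (2 * 0.48)))
})

test_that("string method leaves a valley-resident path in place", {
  rv <- make_test_potential("ring_valley", list(A = 20, R = 2))
  p <- init_guiding_path(16, "circle", radius = 2, active_id = 8,
                         interface_id = 0)
  p2 <- string_optimize(rv, p, k_string = 10, rounds = 10,
                        samples_per_round = 3000, tol = 0.05, seed = 421)
  expect_true(attr(p2, "converged"))
  expect_lte(attr(p2, "rounds_used"), 3)
})

test_that("string method finds a quadratic trough from a perturbed start", {
  rv <- make_test_potential("ring_valley", list(A = 20, R = 2))
  set.seed(99)
  n <- 32
  theta <- pi - 2 * pi * (0:(n - 1)) / n
  rho0 <- 2 + ifelse(0:(n - 1) %in% c(0, 16), 0, rnorm(n, 0, 0.25))
  pts <- cbind(rho0 * cos(theta), rho0 * sin(theta))
  p <- init_guiding_path(n, "explicit", points = pts, active_id = 16,
                         interface_id = 0)
  p2 <- string_optimize(rv, p, k_string = 10, rounds = 40,
                        samples_per_round = 8000, tol = 0.006,
                        damping = 0.8, seed = 4)
  rho <- sqrt(rowSums(p2$points^2))
  expect_true(attr(p2, "converged"))
  expect_lt(max(abs(rho - 2)), 0.05)
})

test_that("string method routes the loading path over both saddles", {
  pot <- make_ga2ox_landscape()
  set.seed(12)
  p <- init_guiding_path(48, "circle", radius = 2)
  p$points <- p$points + matrix(rnorm(96, sd = 0.15), 48, 2)
  p$points[p$fixed, ] <- rbind(c(-2, 0), c(2, 0))
  p2 <- suppressWarnings(
    string_optimize(pot, p, k_string = 2.39, rounds = 20,
                    samples_per_round = 4000, dt = 5e-4, friction = 0.5,
                    seed = 431))
  sad_angle <- pot$metadata$params$saddle_angle
  spacing <- 2 * pi * 2 / 48
  for (sgn in c(-1, 1)) {
    saddle <- 2 * c(cos(sgn * sad_angle), sin(sgn * sad_angle))
    d_min <- min(sqrt(rowSums(sweep(p2$points, 2, saddle)^2)))
    expect_lt(d_min, spacing)
  }
})
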