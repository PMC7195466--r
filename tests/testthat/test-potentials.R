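test_that("gradients match central finite differences on random points", {
  pots <- list(
    make_ga2ox_landscape(),
    make_test_potential("harmonic", list(k = c(1, 3), center = c(0.5, -1))),
    make_test_potential("ring_valley", list(A = 5, R = 2)))
  pts <- annulus_points(25, seed = 42)
  for (pot in pots) {
    for (i in seq_len(nrow(pts))) {
      g <- gradient_at(pot, pts[i, ])
      gfd <- fd_gradient(pot, pts[i, ])
      expect_lt(max(abs(g - gfd)) / max(1, max(abs(gfd))), 1e-5)
    }
  }
  dw <- make_test_potential("double_well_1d", list(dG = 1, barrier = 3))
  for (x in c(-1.4, -0.9, -0.1, 0.12, 0.8, 1.3)) {
    gfd <- (energy_at(dw, x + 1e-6) - energy_at(dw, x - 1e-6)) / 2e-6
    expect_lt(abs(gradient_at(dw, x) - gfd), 1e-4)
  }
})

test_that("calibrated loading landscape carries the printed depths and peaks", {
  pot <- make_ga2ox_landscape()
  R <- pot$metadata$params$ring_radius
  expect_equal(energy_at(pot, c(R, 0)), 0, tolerance = 1e-3)
  expect_equal(energy_at(pot, c(-R, 0)), 2.5, tolerance = 1e-3)
  prof <- angular_profile(pot, n = 7201)
  upper <- prof$energy[prof$theta > 0 & prof$theta < pi]
  lower <- prof$energy[prof$theta < 0 & prof$theta > -pi]
  expect_equal(max(upper), 4.2, tolerance = 1e-3)
  expect_equal(max(lower), 4.2, tolerance = 1e-3)
  # both branch maxima identical by symmetry
  expect_lt(abs(max(upper) - max(lower)), 1e-6)
})

test_that("loading landscape is mirror symmetric and finite", {
  pot <- make_ga2ox_landscape()
  pts <- annulus_points(60, seed = 7)
  mirrored <- cbind(pts[, 1], -pts[, 2])
  expect_lt(max(abs(energy_at(pot, pts) - energy_at(pot, mirrored))), 1e-10)
  expect_true(all(is.finite(energy_at(pot, pts))))
  # bump leakage at the two minima stays below 1e-3
  p <- pot$metadata$params
  bare <- make_ga2ox_landscape(bump_height = 0)
  expect_lt(abs(energy_at(pot, c(p$ring_radius, 0)) -
                energy_at(bare, c(p$ring_radius, 0))), 1e-3)
})

test_that("landscape calibration rejects infeasible targets", {
  expect_error(make_ga2ox_landscape(minima_offset = 4.2, saddle_height = 2.5),
               "saddle_height")
  expect_error(make_ga2ox_landscape(well_stiffness = 0.1), "well_stiffness")
})

test_that("asymmetric bump option breaks the branch degeneracy", {
  pot <- make_ga2ox_landscape(bump_delta = 0.2)
  prof <- angular_profile(pot, n = 3601)
  upper <- max(prof$energy[prof$theta > 0 & prof$theta < pi])
  lower <- max(prof$energy[prof$theta < 0])
  expect_gt(abs(upper - lower), 0.05)
})

test_that("test potentials evaluate to their closed forms", {
  harm <- make_test_potential("harmonic", list(k = 1, center = c(0, 0)))
  expect_equal(energy_at(harm, c(1, 0)), 0.5)
  flat <- make_test_potential("flat", list(dim = 2))
  expect_equal(energy_at(flat, c(3.2, -1.7)), 0)
  expect_error(make_test_potential("harmonic", list(k = -1)), "positive")
  expect_error(make_test_potential("nonsense"), "arg")
})

test_that("double-well free-energy difference equals dG by quadrature", {
  # the two wells are congruent shapes offset by dG, so the well
  # free-energy difference -kT log(Z+/Z-) is dG at any kT at which the
  # barrier-top transition region contributes negligibly
  dw <- make_test_potential("double_well_1d", list(dG = 1, barrier = 3))
  kT <- 0.1
  zminus <- integrate(function(x) exp(-energy_at(dw, cbind(x)) / kT),
                      -3, 0, rel.tol = 1e-12)$value
  zplus <- integrate(function(x) exp(-energy_at(dw, cbind(x)) / kT),
                     0, 3, rel.tol = 1e-12)$value
  expect_equal(-kT * log(zplus / zminus), 1, tolerance = 1e-6)
})

test_that("Boltzmann rejection sampling reproduces the angular profile", {
  pot <- make_ga2ox_landscape()
  kT <- 2 * kT300   # warmer sampling populates the saddles adequately
  n <- 20000
  s <- sample_boltzmann(pot, kT, n, lower = c(-4, -4), upper = c(4, 4),
                        seed = 11)
  theta <- atan2(s[, 2], s[, 1])
  # inverse-CDF draws from the exact angular marginal as the reference
  th_grid <- seq(-pi, pi, length.out = 2001)
  prof <- angular_profile(pot, n = 2001)
  # marginal over rho: p(theta) ~ exp(-ang/kT) * const (radial part separable)
  dens <- exp(-prof$energy / kT)
  cdf <- cumsum(dens) / sum(dens)
  set.seed(12)
  ref <- approx(cdf, th_grid, xout = runif(n), rule = 2)$y
  ks <- suppressWarnings(ks.test(theta, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("kinetics fixtures encode the printed fold-changes in their truth", {
  fx <- make_kinetics_fixture("dao_mimetic", seed = 1)
  expect_equal(attr(fx$dimer, "truth")$Vmax / attr(fx$monomer, "truth")$Vmax,
               22)
  expect_equal(attr(fx$monomer, "truth")$Km / attr(fx$dimer, "truth")$Km, 5)
  gx <- make_kinetics_fixture("ga2ox_mimetic", seed = 1)
  expect_equal(attr(gx$monomer, "truth")$Km / attr(gx$tetramer, "truth")$Km,
               10)
  # invariants: concentrations positive, increasing, >= 5 distinct
  for (d in c(fx, gx)) {
    conc <- unique(d$concentration_M)
    expect_true(all(conc > 0))
    expect_true(all(diff(conc) > 0))
    expect_gte(length(conc), 5)
    expect_true(all(d$rate >= 0))
  }
})

test_that("noiseless kinetics fixtures lie exactly on the hyperbola", {
  fx <- make_kinetics_fixture("dao_mimetic", seed = 3, cv = 0)
  tr <- attr(fx$monomer, "truth")
  v_expect <- tr$Vmax * fx$monomer$concentration_M /
    (tr$Km + fx$monomer$concentration_M)
  expect_equal(fx$monomer$rate, v_expect)
})

test_that("kinetics fixture rejects invalid noise settings", {
  expect_error(make_kinetics_fixture("dao_mimetic", seed = 1, cv = -0.1),
               "cv")
  expect_error(make_kinetics_fixture("dao_mimetic", seed = 1, replicates = 0),
               "replicates")
  expect_error(make_kinetics_fixture("dao_mimetic"), "seed")
})

test_that("gate ensembles are reproducible and respect their geometry", {
  e1 <- make_gate_ensemble(n_sites = 50, gate_range = "10-15", n_runs = 2,
                           frames_per_window = 10, n_windows = 4,
                           sigma_base = 0.3, gate_amplification = 2, seed = 5)
  e2 <- make_gate_ensemble(n_sites = 50, gate_range = "10-15", n_runs = 2,
                           frames_per_window = 10, n_windows = 4,
                           sigma_base = 0.3, gate_amplification = 2, seed = 5)
  expect_identical(e1, e2)
  expect_equal(dim(e1[[1]]), c(40L, 50L, 3L))
  expect_true(all(is.finite(e1[[1]])))
  expect_error(make_gate_ensemble(n_sites = 50, gate_range = "45-60",
                                  seed = 1), "outside")
  frozen <- make_gate_ensemble(n_sites = 20, gate_range = "5-8", n_runs = 1,
                               frames_per_window = 5, n_windows = 2,
                               sigma_base = 0, seed = 2)
  expect_equal(sd(frozen[[1]][, 1, 1]), 0)
})
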