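test_that("residue-selection parser expands, deduplicates and round-trips", {
  expect_equal(parse_residue_selection("1-3")$indices, 1:3)
  expect_equal(parse_residue_selection("5,5,4-6")$indices, 4:6)
  expect_equal(parse_residue_selection("5,5,4-6")$count, 3)
  # en-dash ranges parse like hyphens
  expect_equal(parse_residue_selection("89–92")$indices, 89:92)
  sel <- parse_residue_selection("2-4, 9, 11-12")
  expect_equal(parse_residue_selection(format_residue_selection(sel))$indices,
               sel$indices)
  expect_error(parse_residue_selection("3-1"), "descending")
  expect_error(parse_residue_selection("a-5"), "malformed")
})

test_that("the ligand-shell selection counts 61 residues", {
  expect_equal(ligand_shell_selection()$count, 61)
})

test_that("Kabsch superposition is exact on rigid transforms", {
  set.seed(21)
  x <- matrix(rnorm(30 * 3), ncol = 3)
  expect_equal(kabsch_rmsd(x, x)$rmsd, 0, tolerance = 1e-12)
  y <- rigid_transform(x)
  k <- kabsch_rmsd(x, y)
  expect_lt(k$rmsd, 1e-10)
  expect_equal(det(k$rotation), 1, tolerance = 1e-10)
  # symmetry of the distance
  set.seed(22)
  z <- y + matrix(rnorm(30 * 3, sd = 0.2), ncol = 3)
  expect_equal(kabsch_rmsd(x, z)$rmsd, kabsch_rmsd(z, x)$rmsd,
               tolerance = 1e-10)
  # invariance under rigid motion of either argument
  expect_equal(kabsch_rmsd(rigid_transform(x, c(1, 0.2, -0.5), c(9, 9, 9)),
                           z)$rmsd,
               kabsch_rmsd(x, z)$rmsd, tolerance = 1e-10)
  expect_error(kabsch_rmsd(x[1:2, ], y[1:2, ]), "3 sites")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_rmsd(line, line + 1), "degenerate")
})

test_that("Kabsch matches a brute-force rotation grid search", {
  # two small 3D point sets; oracle scans rotations about z after centroid
  # alignment (sets constructed in the xy-plane so a z-rotation suffices)
  a <- cbind(c(0, 1, 0, -1), c(0, 0, 2, 1), 0)
  b0 <- cbind(c(0.1, 1.2, -0.2, -0.9), c(-0.1, 0.2, 1.8, 1.1), 0)
  ang <- 0.7
  rot <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  b <- b0 %*% t(rot)
  grid_rmsd <- function(theta) {
    r <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0), c(0, 0, 1))
    ac <- scale(a, scale = FALSE); bc <- scale(b, scale = FALSE)
    sqrt(mean(rowSums((ac %*% t(r) - bc)^2)))
  }
  oracle <- optimize(grid_rmsd, c(-pi, pi), tol = 1e-10)$objective
  expect_equal(kabsch_rmsd(a, b)$rmsd, oracle, tolerance = 1e-4)
})

test_that("RMSD series behave under rigid motion and register gate opening", {
  ens <- make_gate_ensemble(n_sites = 60, gate_range = "20-30", n_runs = 1,
                            frames_per_window = 25, n_windows = 4,
                            sigma_base = 0.2, gate_amplification = 3,
                            seed = 31)[[1]]
  gate <- parse_residue_selection("20-30")
  rs <- rmsd_series(ens, 1, report_selection = gate)
  expect_equal(rs$rmsd[1], 0, tolerance = 1e-12)
  # rigid-body-moved copies of one frame give an all-zero series
  frame <- ens[1, , ]
  rigid <- ens
  for (f in seq_len(dim(ens)[1]))
    rigid[f, , ] <- rigid_transform(frame, runif(3), rnorm(3))
  rs0 <- rmsd_series(rigid, 1)
  expect_lt(max(rs0$rmsd), 1e-9)
  # constructed gate destabilisation shows up late in the run
  half <- nrow(rs) / 2
  expect_lt(t.test(rs$rmsd[(half + 1):nrow(rs)], rs$rmsd[2:half],
                   alternative = "greater")$p.value, 0.01)
  expect_error(rmsd_series(ens, 1, report_selection = integer()), "empty")
})

test_that("windowed RMSF matches the sigma*sqrt(3) closed form", {
  sigma <- 0.4
  ens <- make_gate_ensemble(n_sites = 40, gate_range = "10-12", n_runs = 8,
                            frames_per_window = 400, n_windows = 2,
                            sigma_base = sigma, gate_amplification = 1,
                            seed = 41)
  tab <- rmsf_windows(ens, 400)
  expect_equal(dim(tab$mean), c(40L, 2L))
  # iid isotropic jitter: RMSF = sigma * sqrt(3); superposition onto the
  # window mean removes ~6 rigid-body dof, a < 1% effect at 40 sites
  se <- sigma * sqrt(3) / sqrt(2 * 400 * 8 / 3)
  expect_lt(max(abs(tab$mean - sigma * sqrt(3))), max(3 * se, 0.02))
})

test_that("RMSF is zero for a frozen ensemble and flags short runs", {
  frozen <- make_gate_ensemble(n_sites = 15, gate_range = "3-5", n_runs = 2,
                               frames_per_window = 10, n_windows = 2,
                               sigma_base = 0, seed = 51)
  tab <- rmsf_windows(frozen, 10)
  expect_equal(max(tab$mean), 0)
  expect_error(rmsf_windows(frozen, 100), "longer than run")
})

test_that("gate amplification separates gate from non-gate RMSF late on", {
  ens <- make_gate_ensemble(n_sites = 80, gate_range = "30-40", n_runs = 8,
                            frames_per_window = 60, n_windows = 4,
                            sigma_base = 0.3, gate_amplification = 2,
                            seed = 61)
  tab <- rmsf_windows(ens, 60)
  gate <- 30:40
  late <- tab$mean[, 4]
  early <- tab$mean[, 1]
  # late-window gate RMSF roughly doubles its early value
  expect_equal(mean(late[gate]) / mean(early[gate]), 2, tolerance = 0.1)
  # and clearly exceeds the non-gate sites
  expect_gt(mean(late[gate]), 1.5 * mean(late[-gate]))
  # run-average is the arithmetic mean over runs
  expect_equal(tab$mean, Reduce(`+`, tab$per_run) / length(tab$per_run))
  # relabeling runs leaves the average unchanged
  tab_rev <- rmsf_windows(rev(ens), 60)
  expect_equal(tab_rev$mean, tab$mean)
})
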