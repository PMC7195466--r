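# shared analytic grid of the loading landscape
mimetic_grid <- local({
  pot <- make_ga2ox_landscape()
  gs <- grid_spec(c(-2.8, 2.8), c(-2.8, 2.8), 60, 60)
  list(pot = pot, pmf = potential_to_grid(pot, gs))
})

test_that("minima detection: paraboloid, flat surface, loading landscape", {
  gs <- grid_spec(c(-1, 1), c(-1, 1), 21, 21)
  para <- potential_to_grid(
    make_test_potential("harmonic", list(k = 1, center = c(0.05, -0.03))),
    gs)
  m <- find_minima(para)
  expect_equal(nrow(m), 1)
  expect_lt(abs(m$x - 0.05), gs$spacing[1])
  expect_lt(abs(m$y + 0.03), gs$spacing[2])
  flat <- potential_to_grid(make_test_potential("flat", list(dim = 2)), gs)
  expect_equal(nrow(find_minima(flat)), 0)
  mm <- find_minima(mimetic_grid$pmf)
  expect_equal(nrow(mm), 2)
  expect_equal(mm$value[1], 0)
  expect_equal(mm$value[2], 2.5, tolerance = 0.05)
  # the two minima sit near the active-site and interface poses
  expect_lt(abs(mm$x[1] - 2), 0.1)
  expect_lt(abs(mm$x[2] + 2), 0.1)
})

test_that("minimax search is exact on trivial cell configurations", {
  gs <- grid_spec(c(0, 2), c(0, 1), 2, 1)
  vals <- matrix(c(1.2, 3.4), 2, 1)
  pmf <- new_pmf_grid(gs$origin, gs$spacing, vals, matrix(1, 2, 1), kT300)
  # adjacent pair: the minimax value is the larger of the two (min-shifted)
  expect_equal(minimax_barrier(pmf, list(ix = 1L, iy = 1L),
                               list(ix = 2L, iy = 1L)), 3.4 - 1.2)
  expect_equal(minimax_barrier(pmf, list(ix = 1L, iy = 1L),
                               list(ix = 1L, iy = 1L)), 0)
})

test_that("minimax matches the landscape saddle and bounds the string peak", {
  pmf <- mimetic_grid$pmf
  m <- find_minima(pmf)
  mm <- minimax_barrier(pmf, m[1, ], m[2, ])
  expect_equal(mm, 4.2, tolerance = 0.05)
  up <- mfep_on_grid(pmf, m[2, ], m[1, ], "upper")
  lo <- mfep_on_grid(pmf, m[2, ], m[1, ], "lower")
  peak_up <- max(up$F); peak_lo <- max(lo$F)
  # the minimax value is the exact grid lower bound for any path maximum
  h <- min(pmf$spacing)
  expect_gte(peak_up, mm - h)
  expect_gte(peak_lo, mm - h)
  expect_lt(abs(peak_up - mm), 0.15)
  expect_lt(abs(peak_lo - mm), 0.15)
  # branch symmetry of the two loading routes
  expect_lt(abs(peak_up - peak_lo), 0.1)
  # and the paths stay on their own sides of the symmetry axis
  expect_true(all(up$y >= min(m$y) - 1e-9))
  expect_true(all(lo$y <= max(m$y) + 1e-9))
})

test_that("grid string follows a known curved valley", {
  # quadratic trough along y = 0.3 x^2 with a double well in x
  valley <- new_potential(2L,
    energy = function(x) 10 * (x[, 2] - 0.3 * x[, 1]^2)^2 +
      (x[, 1]^2 - 1)^2,
    gradient = function(x) {
      d <- x[, 2] - 0.3 * x[, 1]^2
      cbind(-12 * d * x[, 1] + 4 * x[, 1] * (x[, 1]^2 - 1), 20 * d)
    },
    name = "curved_valley")
  gs <- grid_spec(c(-1.6, 1.6), c(-0.4, 1.2), 60, 60)
  pmf <- potential_to_grid(valley, gs)
  m <- find_minima(pmf, min_prominence = 0.3)
  expect_equal(nrow(m), 2)
  path <- mfep_on_grid(pmf, m[1, ], m[2, ], "unconstrained")
  dev <- abs(path$y - 0.3 * path$x^2)
  expect_lt(max(dev), max(gs$spacing) * 1.5)
})

test_that("degenerate paths and barrier arithmetic behave", {
  pmf <- mimetic_grid$pmf
  m <- find_minima(pmf)
  same <- mfep_on_grid(pmf, m[1, ], m[1, ])
  expect_equal(nrow(same), 1)
  expect_equal(barrier_from_path(same, "start")$barrier, 0)
  up <- mfep_on_grid(pmf, m[2, ], m[1, ], "upper")
  rep <- barrier_from_path(up, "start")
  expect_identical(rep$barrier, rep$peak - rep$baseline)
  expect_gte(rep$barrier, 0)
  expect_equal(rep$barrier, 1.7, tolerance = 0.1)
  # a monotone path has its barrier at the far endpoint
  mono <- structure(
    data.frame(index = 0:9, x = 0:9, y = 0, F = seq(0, 4.5, length.out = 10)),
    class = c("fe_path", "data.frame"))
  expect_equal(barrier_from_path(mono, "start")$barrier, 4.5)
  # a flat path has no barrier
  flat <- structure(data.frame(index = 0:4, x = 0:4, y = 0, F = rep(1, 5)),
                    class = c("fe_path", "data.frame"))
  expect_equal(barrier_from_path(flat, "start")$barrier, 0)
})

test_that("transition-state resampling is seeded multinomial with replacement", {
  pmf <- mimetic_grid$pmf
  set.seed(601)
  df <- data.frame(cv_1 = rnorm(400, 2, 0.02), cv_2 = rnorm(400, 0, 0.02))
  wts <- rep(1 / 400, 400)
  cell <- list(ix = ligload:::.cell_of(pmf, rbind(c(2, 0)))[1],
               iy = ligload:::.cell_of(pmf, rbind(c(2, 0)))[2])
  rs <- resample_transition_ensemble(df, wts, pmf, cell, seed = 17)
  expect_equal(nrow(rs), 100)
  rs2 <- resample_transition_ensemble(df, wts, pmf, cell, seed = 17)
  expect_identical(rs, rs2)
  # single candidate in the cell: all draws identical
  one <- data.frame(cv_1 = c(2, -2), cv_2 = c(0, 0))
  rs1 <- resample_transition_ensemble(one, c(0.5, 0.5), pmf, cell,
                                      n = 25, seed = 18)
  expect_equal(nrow(unique(rs1[, c("cv_1", "cv_2")])), 1)
  # uniform weights: empirical frequencies approach 1/m
  m_in <- 8
  # candidates packed well inside the target cell (cells are ~0.09 wide)
  cc <- ligload:::.cell_centers(pmf)
  dfu <- data.frame(cv_1 = rnorm(m_in, cc$x[cell$ix], 0.005),
                    cv_2 = rnorm(m_in, cc$y[cell$iy], 0.005))
  rsu <- resample_transition_ensemble(dfu, rep(1 / m_in, m_in), pmf, cell,
                                      n = 1e5, seed = 19)
  counts <- table(factor(rsu$cv_1, levels = dfu$cv_1))
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.01)
  expect_error(resample_transition_ensemble(one, c(1, 1), pmf,
                                            list(ix = 1L, iy = 1L), seed = 2),
               "no samples")
})
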