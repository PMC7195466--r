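#' Configuration of the full loading free-energy study
#'
#' Bundles every knob of the end-to-end pipeline.  The defaults reproduce
#' the modelled protocol: 48 cyclic windows with points 0 and 24 fixed at the
#' interface and active-site poses, a string phase restrained at
#' 2.39 kcal/mol/A^2, a production replica-exchange phase at
#' 0.48 kcal/mol/A^2 with 20 time-units per window (48 x 20 = 960 total
#' production time-units), kT at 300 K, and a 60 x 60 analysis grid.
#'
#' @param landscape a 2D [new_potential()]; defaults to the calibrated
#'   loading landscape [make_ga2ox_landscape()].
#' @param n_windows number of guiding points / windows.
#' @param interface_id,active_id 0-based ids of the fixed points.
#' @param k_string,k_production force constants, kcal/mol/A^2.
#' @param production_length production time-units per window.
#' @param equilibration equilibration time-units per window, discarded
#'   before production (mirrors the equilibrate-then-produce protocol).
#' @param dt,friction,stride,exchange_interval sampler parameters
#'   (`exchange_interval` in integrator steps).
#' @param kT thermal energy, kcal/mol.
#' @param string_rounds,string_samples string-method budget (rounds and
#'   integrator steps per window per round).
#' @param grid_nx,grid_ny PMF grid resolution.
#' @param min_prominence minimum prominence for reported minima, kcal/mol.
#' @param seed master seed; stage seeds are derived deterministically.
#' @param outdir optional output directory; when set, all intermediates are
#'   written there and listed in the report manifest.
#' @return object of class `study_config`.
#' @export
study_config <- function(landscape = make_ga2ox_landscape(),
                         n_windows = 48L, interface_id = 0L, active_id = 24L,
                         k_string = 2.39, k_production = 0.48,
                         production_length = 20, equilibration = 2,
                         dt = 5e-5, friction = 0.1,
                         stride = 200L, exchange_interval = 12L,
                         kT = thermal_energy(300, "K"),
                         string_rounds = 20L, string_samples = 4000L,
                         grid_nx = 60L, grid_ny = 60L,
                         min_prominence = 0.5, seed = 1L, outdir = NULL) {
  cfg <- list(landscape = landscape, n_windows = as.integer(n_windows),
              interface_id = as.integer(interface_id),
              active_id = as.integer(active_id),
              k_string = k_string, k_production = k_production,
              production_length = production_length,
              equilibration = equilibration, dt = dt,
              friction = friction, stride = as.integer(stride),
              exchange_interval = as.integer(exchange_interval), kT = kT,
              string_rounds = as.integer(string_rounds),
              string_samples = as.integer(string_samples),
              grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
              min_prominence = min_prominence, seed = as.integer(seed),
              outdir = outdir)
  class(cfg) <- "study_config"
  cfg
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("<study_config> %d windows x %g time-units (total %g), k=%g/%g, kT=%g, seed=%d\n",
              x$n_windows, x$production_length,
              x$n_windows * x$production_length,
              x$k_string, x$k_production, x$kT, x$seed))
  invisible(x)
}

# deterministic stage seeds derived from the master seed (kept < 2^31)
.stage_seed <- function(seed, stage) {
  (seed * 1000003 + stage * 7919) %% 2147483647
}

#' Run the full loading free-energy study
#'
#' End-to-end pipeline: string-method optimization of the cyclic guiding
#' path, production umbrella windows, replica-exchange umbrella sampling,
#' MBAR, 2D PMF, minima detection, per-branch minimum free-energy paths, and
#' barrier reports measured from the interfacial minimum.  Rerunning with
#' the same config (and therefore seeds) reproduces the report exactly.
#'
#' With fewer than 2 windows the sampling stage still runs but path/barrier
#' extraction is skipped and the report carries an `insufficient_windows`
#' flag.
#'
#' @param config a [study_config()].
#' @return object of class `study_report`: list with `minima`, `offset`
#'   (interface minus active-site free energy, kcal/mol), `barriers` (per
#'   branch), `peak` (mean branch peak vs the global minimum), the
#'   convergence diagnostic (`pmf_rms_75`), the sampling `accounting`, the
#'   `manifest` of written files, and the intermediate objects.
#' @export
run_loading_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  chash <- config_hash(config[setdiff(names(config), "landscape")])
  pot <- config$landscape
  R <- pot$metadata$params$ring_radius %||% 2
  accounting <- list(windows = config$n_windows,
                     production_length = config$production_length,
                     total = config$n_windows * config$production_length)
  if (config$n_windows < 2L) {
    return(structure(list(minima = NULL, offset = NA_real_, barriers = NULL,
                          peak = NA_real_, accounting = accounting,
                          insufficient_windows = TRUE,
                          config_hash = chash, manifest = list()),
                     class = "study_report"))
  }
  path <- init_guiding_path(config$n_windows, "circle", radius = R,
                            active_id = config$active_id,
                            interface_id = config$interface_id)
  path <- string_optimize(pot, path, k_string = config$k_string,
                          rounds = config$string_rounds,
                          samples_per_round = config$string_samples,
                          kT = config$kT, dt = config$dt,
                          friction = config$friction,
                          seed = .stage_seed(config$seed, 1L))
  windows <- build_windows(path, k = config$k_production)
  n_steps <- round(config$production_length / config$dt)
  ws <- run_reus(pot, windows, kT = config$kT, n_steps = n_steps,
                 dt = config$dt, friction = config$friction,
                 stride = config$stride,
                 exchange_interval = config$exchange_interval,
                 equilibration = config$equilibration,
                 seed = .stage_seed(config$seed, 2L))
  mbar <- mbar_solve(ws, windows, kT = config$kT)
  gs <- .default_grid_spec(as.matrix(ws$samples[, c("cv_1", "cv_2")]),
                           config$grid_nx, config$grid_ny)
  pmf <- pmf_2d(ws, mbar$weights, gs, kT = config$kT)
  # convergence: PMF from the first 75% of each window's samples vs all
  frac <- ws
  frac$samples <- do.call(rbind, lapply(split(ws$samples, ws$samples$window),
    function(d) d[seq_len(floor(0.75 * nrow(d))), , drop = FALSE]))
  w75 <- mbar_solve(frac, windows, kT = config$kT)
  pmf75 <- pmf_2d(frac, w75$weights, gs, kT = config$kT)
  both <- pmf$occupied & pmf75$occupied
  pmf_rms_75 <- sqrt(mean((pmf$values[both] - pmf75$values[both])^2))
  minima <- find_minima(pmf, config$min_prominence)
  report <- list(minima = minima, accounting = accounting,
                 pmf_rms_75 = pmf_rms_75,
                 exchange_acceptance = if (!is.null(ws$exchange_log))
                   mean(ws$exchange_log$accepted) else NA_real_,
                 mbar_residual = mbar$residual,
                 config_hash = chash)
  if (nrow(minima) >= 2L) {
    interface_min <- minima[which.max(minima$value), ]
    active_min <- minima[which.min(minima$value), ]
    report$offset <- pmf_offset(pmf, c(active_min$x, active_min$y),
                                c(interface_min$x, interface_min$y))
    paths <- lapply(c(upper = "upper", lower = "lower"), function(br)
      tryCatch(mfep_on_grid(pmf, interface_min, active_min, br),
               error = function(e) {
                 warning("MFEP stage failed on the ", br, " branch (config ",
                         chash, "): ", conditionMessage(e), call. = FALSE)
                 structure(conditionMessage(e), class = "path_error")
               }))
    ok <- !vapply(paths, inherits, TRUE, "path_error")
    report$path_errors <- lapply(paths[!ok], unclass)
    report$barriers <- lapply(paths[ok], barrier_from_path,
                              reference = "start", profile_window = 9L)
    report$peak <- if (any(ok))
      mean(vapply(report$barriers, `[[`, 0, "peak")) else NA_real_
    report$paths <- paths[ok]
  } else {
    report$offset <- NA_real_
    report$barriers <- NULL
    report$peak <- NA_real_
  }
  report$guiding_path <- path
  report$window_samples <- ws
  report$mbar <- mbar
  report$pmf <- pmf
  manifest <- list()
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(name) file.path(config$outdir, name)
    write_window_samples(ws, fp("window_samples.tsv"))
    write_pmf(pmf, fp("pmf.tsv"))
    for (br in names(report$paths))
      write_fe_path(report$paths[[br]], fp(paste0("mfep_", br, ".tsv")),
                    report$barriers[[br]])
    files <- c("window_samples.tsv", "pmf.tsv",
               paste0("mfep_", names(report$paths), ".tsv"))
    manifest <- lapply(files, function(f)
      list(file = f, hash = config_hash(readLines(fp(f), warn = FALSE))))
    names(manifest) <- files
  }
  report$manifest <- manifest
  structure(report, class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  accounting: %d windows x %g = %g production time-units\n",
              x$accounting$windows, x$accounting$production_length,
              x$accounting$total))
  if (isTRUE(x$insufficient_windows)) {
    cat("  insufficient windows: no landscape analysis performed\n")
    return(invisible(x))
  }
  cat(sprintf("  minima found: %d\n", nrow(x$minima)))
  if (!is.na(x$offset))
    cat(sprintf("  interface - active-site offset: %.2f kcal/mol\n",
                x$offset))
  if (!is.null(x$barriers))
    for (br in names(x$barriers))
      cat(sprintf("  %s branch: peak %.2f, barrier %.2f kcal/mol\n", br,
                  x$barriers[[br]]$peak, x$barriers[[br]]$barrier))
  if (length(x$path_errors))
    for (br in names(x$path_errors))
      cat(sprintf("  %s branch: path extraction failed (%s)\n", br,
                  x$path_errors[[br]]))
  cat(sprintf("  PMF 75%%-vs-100%% RMS: %.3f kcal/mol; exchange acceptance %.2f\n",
              x$pmf_rms_75, x$exchange_acceptance))
  invisible(x)
}

#' Run the biased-exit study
#'
#' Emulates the gate-region protocol: `n_runs` independent overdamped
#' Langevin runs started from identical coordinates in a binding well but
#' with different noise streams, each driven outward by the moving
#' flat-bottom restraint [moving_flatbottom_bias()] whose radius grows as
#' \eqn{r_0(t) = r_0(0) + c\,t}.  Alongside the exit trajectories, windowed
#' RMSF (window length `rmsf_window` time-units) averaged over runs and the
#' gate RMSD series are computed on a paired synthetic gate ensemble whose
#' gate sites destabilize in the later half of the run.
#'
#' @param schedule a [bias_schedule()] (k_bias and pull speed c).
#' @param n_runs number of independent runs.
#' @param run_length run length in time-units; must cover at least one RMSF
#'   window.
#' @param rmsf_window RMSF window length in time-units.
#' @param well_k stiffness of the binding well holding the ligand.
#' @param dt,friction,stride,kT sampler parameters.
#' @param gate_range,gate_amplification,n_sites gate-ensemble fixture
#'   parameters (see [make_gate_ensemble()]).
#' @param seed master seed.
#' @return object of class `exit_report`: list with `trajectories`, `r`
#'   (per-run exit-distance matrix), `r0` (restraint radius at the recorded
#'   times), `rmsf` (an [rmsf_windows()] table), `gate_rmsd` (per-run RMSD
#'   series over the gate sites), and the parameters.
#' @export
run_exit_study <- function(schedule = bias_schedule(), n_runs = 8L,
                           run_length = 90, rmsf_window = 20,
                           well_k = 0.05, dt = 1e-3, friction = 1,
                           stride = 100L, kT = thermal_energy(300, "K"),
                           gate_range = "96-106", gate_amplification = 2,
                           n_sites = 330L, seed = 1L) {
  stopifnot(inherits(schedule, "bias_schedule"))
  if (run_length < rmsf_window)
    stop("run length (", run_length, ") shorter than one RMSF window (",
         rmsf_window, ")")
  n_windows <- floor(run_length / rmsf_window)
  pot <- make_test_potential("harmonic",
                             list(k = well_k, center = c(0, 0), dim = 2L))
  bias <- moving_flatbottom_bias(schedule)
  n_steps <- round(run_length / dt)
  x0 <- c(schedule$r0_initial, 0)
  trajectories <- lapply(seq_len(n_runs), function(run)
    run_langevin(pot, list(bias), x0, dt = dt, friction = friction, kT = kT,
                 n_steps = n_steps, stride = stride,
                 seed = .stage_seed(seed, 10L + run)))
  r <- vapply(trajectories, function(tr)
    sqrt(rowSums(sweep(tr$x, 2L, schedule$reference)^2)),
    numeric(length(trajectories[[1L]]$times)))
  times <- trajectories[[1L]]$times
  frames_per_window <- round(rmsf_window / (dt * stride))
  ens <- make_gate_ensemble(n_sites = n_sites, gate_range = gate_range,
                            n_runs = n_runs,
                            frames_per_window = frames_per_window,
                            n_windows = n_windows,
                            gate_amplification = gate_amplification,
                            time_per_frame = dt * stride,
                            seed = .stage_seed(seed, 99L))
  rmsf <- rmsf_windows(ens, frames_per_window)
  gate_sel <- parse_residue_selection(gate_range)
  gate_rmsd <- lapply(ens, rmsd_series, reference_frame = 1L,
                      fit_selection = NULL, report_selection = gate_sel)
  structure(list(trajectories = trajectories, r = r, times = times,
                 r0 = bias$r0_at(times), rmsf = rmsf,
                 gate_rmsd = gate_rmsd,
                 params = list(schedule = unclass(schedule),
                               n_runs = n_runs, run_length = run_length,
                               rmsf_window = rmsf_window,
                               n_rmsf_windows = n_windows,
                               well_k = well_k, dt = dt, stride = stride,
                               kT = kT, seed = seed)),
            class = "exit_report")
}

#' @export
print.exit_report <- function(x, ...) {
  p <- x$params
  cat(sprintf("<exit_report> %d runs x %g time-units; %d RMSF windows of %g\n",
              p$n_runs, p$run_length, p$n_rmsf_windows, p$rmsf_window))
  cat(sprintf("  r0 moved %g -> %g; mean final r = %.2f\n",
              x$r0[1L], x$r0[length(x$r0)],
              mean(x$r[nrow(x$r), ])))
  invisible(x)
}
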