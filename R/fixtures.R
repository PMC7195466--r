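#' Seeded Michaelis-Menten rate-table fixtures
#'
#' Generates synthetic substrate-rate tables for a monomer/multimer enzyme
#' pair whose ground-truth parameters carry the kinetic fold-changes of the
#' substrate-bridged multimerization system:
#'
#' * `dao_mimetic` — monomer (Km = 10 uM, Vmax = 1) vs dimer (Km = 2 uM,
#'   Vmax = 22): the dimer's Vmax is 22-fold higher and its Km 5-fold lower.
#' * `ga2ox_mimetic` — monomer (Km = 10 uM, Vmax = 1) vs tetramer (Km = 1 uM,
#'   Vmax = 3.5): Km 10-fold lower, Vmax 3.5-fold higher.
#' * `custom` — supply `truth` as a named list of `list(Km=, Vmax=)` per
#'   species.
#'
#' Rates are \eqn{v = V_{max} S / (K_m + S)} times multiplicative lognormal
#' noise of the stated coefficient of variation (mean 1); concentrations are
#' log-spaced over 0.5-100 uM.  Truth parameters live in the attributes,
#' never in filenames.
#'
#' @param scheme `"dao_mimetic"`, `"ga2ox_mimetic"` or `"custom"`.
#' @param seed integer RNG seed (required).
#' @param n_conc number of distinct concentrations (>= 5).
#' @param replicates replicate measurements per concentration (>= 1).
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param truth for `scheme = "custom"`: named list of species truths.
#' @return named list of `kinetics_dataset` objects (data.frames with columns
#'   `concentration_M`, `rate`, `replicate` and attributes `species`,
#'   `truth`, `cv`, `seed`).
#' @examples
#' fx <- make_kinetics_fixture("dao_mimetic", seed = 1)
#' attr(fx$dimer, "truth")$Vmax / attr(fx$monomer, "truth")$Vmax  # 22
#' @export
make_kinetics_fixture <- function(scheme = c("dao_mimetic", "ga2ox_mimetic",
                                             "custom"),
                                  seed, n_conc = 8L, replicates = 3L,
                                  cv = 0.02, truth = NULL) {
  scheme <- match.arg(scheme)
  if (missing(seed)) stop("seed is required")
  if (cv < 0) stop("cv must be non-negative")
  if (replicates < 1) stop("replicates must be >= 1")
  if (n_conc < 5) stop("need at least 5 distinct concentrations")
  truth <- switch(scheme,
    dao_mimetic = list(monomer = list(Km = 10e-6, Vmax = 1),
                       dimer = list(Km = 2e-6, Vmax = 22)),
    ga2ox_mimetic = list(monomer = list(Km = 10e-6, Vmax = 1),
                         tetramer = list(Km = 1e-6, Vmax = 3.5)),
    custom = {
      if (is.null(truth)) stop("scheme 'custom' requires `truth`")
      truth
    })
  conc <- exp(seq(log(0.5e-6), log(100e-6), length.out = n_conc))
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + cv^2))
  out <- lapply(names(truth), function(sp) {
    tr <- truth[[sp]]
    df <- expand.grid(replicate = seq_len(replicates),
                      concentration_M = conc)[, 2:1]
    v <- tr$Vmax * df$concentration_M / (tr$Km + df$concentration_M)
    if (cv > 0)
      v <- v * stats::rlnorm(length(v), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    df$rate <- v
    df$species <- sp
    structure(df[, c("concentration_M", "rate", "replicate", "species")],
              species = sp, truth = tr, cv = cv, seed = as.integer(seed),
              class = c("kinetics_dataset", "data.frame"))
  })
  names(out) <- names(truth)
  out
}

#' @export
print.kinetics_dataset <- function(x, ...) {
  tr <- attr(x, "truth")
  cat(sprintf("<kinetics_dataset> %s: %d points (%d conc x %d reps), truth Km=%g M, Vmax=%g, cv=%g\n",
              attr(x, "species"), nrow(x),
              length(unique(x$concentration_M)),
              length(unique(x$replicate)), tr$Km, tr$Vmax, attr(x, "cv")))
  NextMethod()
}

#' Synthetic gate-motion coordinate ensembles
#'
#' Builds coordinate ensembles (frames x sites x 3) in which every site
#' fluctuates isotropically about a fixed reference structure with per-axis
#' standard deviation `sigma_base`, and the sites inside the gate range have
#' their fluctuation multiplied by `gate_amplification` in the later half of
#' the time windows — emulating the destabilisation of a gate loop as the
#' ligand exits the binding site.  Run-to-run variation comes only from the
#' seed; the reference structure is shared by all runs.
#'
#' @param n_sites number of sites (C-alpha stand-ins).
#' @param gate_range range string (e.g. `"96-106"`) parsed by
#'   [parse_residue_selection()].
#' @param n_runs number of independent runs.
#' @param frames_per_window frames in one analysis window.
#' @param n_windows number of windows per run (total frames =
#'   `frames_per_window * n_windows`).
#' @param sigma_base per-axis fluctuation s.d. (length units).
#' @param gate_amplification multiplier (>= 1) applied to gate-site
#'   fluctuations in windows after `n_windows / 2`.
#' @param time_per_frame time between stored frames.
#' @param seed integer RNG seed (required).
#' @return list of `coordinate_ensemble` objects (arrays with attributes
#'   `site_labels`, `time_per_frame`, `run`, `gate_sites`, `n_windows`,
#'   `frames_per_window`).
#' @export
make_gate_ensemble <- function(n_sites = 330L, gate_range = "96-106",
                               n_runs = 8L, frames_per_window = 50L,
                               n_windows = 4L, sigma_base = 0.5,
                               gate_amplification = 2,
                               time_per_frame = 0.1, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(gate_amplification >= 1, sigma_base >= 0, n_runs >= 1,
            frames_per_window >= 1, n_windows >= 1)
  gate <- parse_residue_selection(gate_range)$indices
  if (any(gate < 1L | gate > n_sites))
    stop("gate_range lies outside [1, ", n_sites, "]")
  # fixed reference: a gentle helix-like curve, identical for every run/seed
  s <- seq_len(n_sites)
  ref <- cbind(10 * cos(s / 10), 10 * sin(s / 10), 0.5 * s)
  n_frames <- frames_per_window * n_windows
  late <- rep(seq_len(n_windows) > n_windows / 2, each = frames_per_window)
  set.seed(as.integer(seed))
  lapply(seq_len(n_runs), function(run) {
    sd_mat <- matrix(sigma_base, n_frames, n_sites)
    sd_mat[late, gate] <- sigma_base * gate_amplification
    arr <- array(0, c(n_frames, n_sites, 3L))
    for (ax in 1:3)
      arr[, , ax] <- rep(ref[, ax], each = n_frames) +
        if (sigma_base > 0) stats::rnorm(n_frames * n_sites) * sd_mat else 0
    structure(arr, site_labels = s, time_per_frame = time_per_frame,
              run = run, gate_sites = gate, n_windows = n_windows,
              frames_per_window = frames_per_window,
              class = "coordinate_ensemble")
  })
}

#' @export
print.coordinate_ensemble <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<coordinate_ensemble> run %s: %d frames x %d sites x 3\n",
              attr(x, "run"), d[1L], d[2L]))
  invisible(x)
}
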