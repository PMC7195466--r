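#' Parse a residue-selection string
#'
#' Parses comma-separated residue indices and inclusive ranges written with a
#' hyphen or an en-dash (both occur in printed methods sections), expanding
#' and deduplicating.  The canonical selection of the modelled exit study —
#' the 61 C-alpha sites within 10 A of the bound ligand — is available as
#' [ligand_shell_selection()].
#'
#' @param text e.g. `"89-92, 95, 98-105"`.
#' @return object of class `residue_selection`: list with `indices` (sorted
#'   unique integers), `source` (the input text) and `count`.
#' @examples
#' parse_residue_selection("1-3")$count        # 3
#' parse_residue_selection("5,5,4-6")$indices  # 4 5 6
#' @export
parse_residue_selection <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- trimws(strsplit(text, ",", fixed = TRUE)[[1L]])
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) stop("empty selection")
  idx <- integer()
  for (tok in tokens) {
    parts <- strsplit(tok, "[-–]")[[1L]]
    parts <- trimws(parts)
    if (!all(grepl("^[0-9]+$", parts)) || !length(parts) %in% 1:2)
      stop("malformed selection token: '", tok, "'")
    a <- as.integer(parts[1L])
    b <- as.integer(parts[length(parts)])
    if (b < a) stop("descending range: '", tok, "'")
    idx <- c(idx, a:b)
  }
  idx <- sort(unique(idx))
  structure(list(indices = idx, source = text, count = length(idx)),
            class = "residue_selection")
}

#' Canonical selection string round-trip
#'
#' @param sel a `residue_selection`.
#' @return canonical range string (e.g. `"4-6, 9"`); parsing it reproduces
#'   the same indices.
#' @export
format_residue_selection <- function(sel) {
  idx <- sel$indices
  breaks <- c(0L, which(diff(idx) != 1L), length(idx))
  runs <- vapply(seq_len(length(breaks) - 1L), function(i) {
    a <- idx[breaks[i] + 1L]; b <- idx[breaks[i + 1L]]
    if (a == b) as.character(a) else paste0(a, "-", b)
  }, "")
  paste(runs, collapse = ", ")
}

#' @export
print.residue_selection <- function(x, ...) {
  cat(sprintf("<residue_selection> %d residues: %s\n", x$count,
              format_residue_selection(x)))
  invisible(x)
}

#' The 61-residue ligand-shell selection of the exit study
#'
#' The printed selection of C-alpha sites within 10 A of the bound ligand in
#' the modelled system: residues 89-92, 95, 98-105, 110-114, 176-181,
#' 200-210, 242, 243-245, 259-261, 274-278 and 308-321 (61 residues).
#'
#' @return a `residue_selection` of 61 residues.
#' @export
ligand_shell_selection <- function() {
  parse_residue_selection(paste0(
    "89-92, 95, 98-105, 110-114, 176-181, 200-210, 242, 243-245, ",
    "259-261, 274-278, 308-321"))
}

#' Kabsch superposition and RMSD of two frames
#'
#' Least-squares optimal rigid superposition of `frame_a` onto `frame_b`
#' (proper rotation enforced via the determinant sign correction in the SVD)
#' and the unweighted RMSD after superposition.
#'
#' @param frame_a,frame_b `n x 3` coordinate matrices with equal site counts
#'   (n >= 3, non-collinear).
#' @param selection optional `residue_selection` (or integer vector) of sites
#'   used both for the fit and the RMSD.
#' @return list with `rotation` (3 x 3), `translation` (length 3; the map is
#'   `a %*% rotation + translation`), and `rmsd`.
#' @export
kabsch_rmsd <- function(frame_a, frame_b, selection = NULL) {
  a <- as.matrix(frame_a); b <- as.matrix(frame_b)
  if (!is.null(selection)) {
    idx <- if (inherits(selection, "residue_selection"))
      selection$indices else as.integer(selection)
    a <- a[idx, , drop = FALSE]; b <- b[idx, , drop = FALSE]
  }
  if (nrow(a) != nrow(b)) stop("site counts differ")
  if (nrow(a) < 3L) stop("need at least 3 sites for superposition")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2L, ca); b0 <- sweep(b, 2L, cb)
  if (any(svd(a0)$d[2L] < 1e-10 * max(svd(a0)$d[1L], 1)))
    stop("degenerate (collinear) coordinate set")
  H <- crossprod(a0, b0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  rmsd <- sqrt(mean(rowSums((a0 %*% R - b0)^2)))
  list(rotation = R, translation = cb - drop(ca %*% R), rmsd = rmsd)
}

# superpose frame a onto b (fit over fit_idx), return transformed full frame
.superpose <- function(a, b, fit_idx) {
  k <- kabsch_rmsd(a, b, fit_idx)
  sweep(a %*% k$rotation, 2L, k$translation, `+`)
}

#' RMSD time series of an ensemble against a reference frame
#'
#' Each frame is superposed onto the reference using `fit_selection`
#' (typically the whole molecule) and the RMSD is reported over
#' `report_selection` (e.g. the gate residues), supporting the standard
#' fit-on-whole / report-on-region protocol.
#'
#' @param ensemble a `coordinate_ensemble` (frames x sites x 3 array).
#' @param reference_frame frame index used as reference (default 1).
#' @param fit_selection,report_selection `residue_selection` objects or
#'   integer vectors; default all sites.
#' @return data.frame with columns `frame`, `time`, `rmsd`.
#' @export
rmsd_series <- function(ensemble, reference_frame = 1L,
                        fit_selection = NULL, report_selection = NULL) {
  n_sites <- dim(ensemble)[2L]
  as_idx <- function(s) {
    if (is.null(s)) return(seq_len(n_sites))
    if (inherits(s, "residue_selection")) s$indices else as.integer(s)
  }
  fit_idx <- as_idx(fit_selection)
  rep_idx <- as_idx(report_selection)
  if (!length(fit_idx) || !length(rep_idx)) stop("empty selection")
  if (any(c(fit_idx, rep_idx) > n_sites)) stop("selection outside site range")
  ref <- ensemble[reference_frame, , ]
  n_frames <- dim(ensemble)[1L]
  tpf <- attr(ensemble, "time_per_frame") %||% 1
  rmsd <- vapply(seq_len(n_frames), function(f) {
    fr <- .superpose(ensemble[f, , ], ref, fit_idx)
    sqrt(mean(rowSums((fr[rep_idx, , drop = FALSE] -
                       ref[rep_idx, , drop = FALSE])^2)))
  }, 0)
  data.frame(frame = seq_len(n_frames), time = (seq_len(n_frames) - 1L) * tpf,
             rmsd = rmsd)
}

#' Windowed RMSF averaged over runs
#'
#' Root-mean-square fluctuation per site, computed independently for each
#' time window of `window_frames` frames: frames of a window are superposed
#' onto the window-mean structure (two fit/re-mean passes), and
#' \eqn{\mathrm{RMSF}_i = \sqrt{\langle |r_i - \langle r_i\rangle|^2
#' \rangle}}.  Per-window tables are averaged arithmetically across runs.  A
#' final partial window is dropped, not padded.
#'
#' @param ensembles list of `coordinate_ensemble` objects (the independent
#'   runs).
#' @param window_frames frames per window; every run must have at least one
#'   full window.
#' @return object of class `rmsf_table`: list with `per_run` (list of
#'   sites x windows matrices), `mean` (run-averaged sites x windows matrix),
#'   `window_frames`, `n_windows`.
#' @export
rmsf_windows <- function(ensembles, window_frames) {
  stopifnot(length(ensembles) >= 1L, window_frames >= 2L)
  n_frames <- dim(ensembles[[1L]])[1L]
  if (n_frames < window_frames)
    stop("window (", window_frames, " frames) longer than run (", n_frames,
         ")")
  n_windows <- n_frames %/% window_frames
  per_run <- lapply(ensembles, function(ens) {
    n_sites <- dim(ens)[2L]
    out <- matrix(NA_real_, n_sites, n_windows)
    for (w in seq_len(n_windows)) {
      rows <- ((w - 1L) * window_frames + 1L):(w * window_frames)
      frames <- lapply(rows, function(f) ens[f, , ])
      mean_str <- Reduce(`+`, frames) / length(frames)
      for (pass in 1:2) {
        frames <- lapply(frames, .superpose, b = mean_str,
                         fit_idx = seq_len(n_sites))
        mean_str <- Reduce(`+`, frames) / length(frames)
      }
      dev2 <- Reduce(`+`, lapply(frames, function(fr)
        rowSums((fr - mean_str)^2))) / length(frames)
      out[, w] <- sqrt(dev2)
    }
    out
  })
  structure(list(per_run = per_run,
                 mean = Reduce(`+`, per_run) / length(per_run),
                 window_frames = as.integer(window_frames),
                 n_windows = as.integer(n_windows)),
            class = "rmsf_table")
}

#' @export
print.rmsf_table <- function(x, ...) {
  cat(sprintf("<rmsf_table> %d sites x %d windows, averaged over %d runs\n",
              nrow(x$mean), x$n_windows, length(x$per_run)))
  invisible(x)
}
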