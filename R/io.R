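#' Artifact readers and writers
#'
#' All tabular artifacts are TSV with a commented header block (`# key: value`
#' lines carrying tool version, config hash, seed and unit conventions)
#' followed by a column header; structured metadata travels in a JSON sidecar
#' (`<file>.json`).  Numeric values are written with 17 significant digits so
#' write/read round-trips are exact.  Schema violations (missing columns,
#' truncated files) raise errors naming the offending column — never a silent
#' partial load.
#'
#' @name artifact_io
NULL

.tool_version <- function() {
  as.character(utils::packageVersion("ligload"))
}

# FNV-1a hash of a serialized R object, as 8 hex digits; identifies the
# configuration that produced an output
#' Configuration hash
#' @param x any R object (typically a config list).
#' @return 8-hex-digit character hash.
#' @export
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # XOR with the low byte (b < 256), in double arithmetic to stay unsigned
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # FNV prime multiplication mod 2^32; 16-bit split keeps doubles exact
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

.write_tsv_with_header <- function(df, path, header = list()) {
  header <- c(list(tool = "ligload", version = .tool_version()), header)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header))
    writeLines(sprintf("# %s: %s", k,
                       paste(format(header[[k]], digits = 17),
                             collapse = " ")), con)
  is_num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  out <- df
  out[is_num] <- lapply(df[is_num], function(x) sprintf("%.17g", x))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv_with_header <- function(path, required_cols) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  header <- list()
  for (l in lines[hdr]) {
    kv <- sub("^# ([^:]+): (.*)$", "\\1\t\\2", l)
    kv <- strsplit(kv, "\t", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) header[[kv[1L]]] <- kv[2L]
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  if (!length(body)) stop("file ", path, " has no table body")
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols))
    stop("file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  list(df = df, header = header)
}

#' Write / read a trajectory
#'
#' TSV columns `time`, `cv_1..cv_d`, `bias_energy`; JSON sidecar with the
#' seed and integrator parameters.  `read_trajectory(write_trajectory(x))`
#' returns an equal object.
#'
#' @param traj a `trajectory`.
#' @param path output TSV path.
#' @return `write_trajectory`: the path, invisibly.  `read_trajectory`: a
#'   `trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  d <- ncol(traj$x)
  df <- data.frame(time = traj$times, traj$x, bias_energy = traj$bias_energy)
  names(df)[2:(1 + d)] <- paste0("cv_", seq_len(d))
  .write_tsv_with_header(df, path, list(
    type = "trajectory", seed = traj$seed,
    units = "time arbitrary; lengths Angstrom; energies kcal/mol",
    config_hash = config_hash(traj$params)))
  jsonlite::write_json(c(traj$params, list(seed = traj$seed)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  got <- .read_tsv_with_header(path, c("time", "cv_1", "bias_energy"))
  params <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- length(grep("^cv_", names(got$df)))
  structure(
    list(times = got$df$time,
         x = as.matrix(got$df[paste0("cv_", seq_len(d))]),
         bias_energy = got$df$bias_energy,
         seed = as.integer(params$seed),
         params = params[setdiff(names(params), "seed")]),
    class = "trajectory")
}

#' Write / read umbrella-window samples
#'
#' TSV columns `window`, `replica`, `time`, `cv_*`, `bias_energy`; the
#' exchange log (if any) goes to `<path>.exchange.tsv` with columns `sweep`,
#' `edge_i`, `edge_j`, `accepted`.
#'
#' @param ws a `window_samples`.
#' @param path output TSV path.
#' @export
write_window_samples <- function(ws, path) {
  .write_tsv_with_header(ws$samples, path, list(
    type = "window_samples",
    bias_convention = ws$windows$convention,
    seed = ws$params$seed,
    config_hash = config_hash(ws$params)))
  if (!is.null(ws$exchange_log))
    .write_tsv_with_header(ws$exchange_log, paste0(path, ".exchange.tsv"),
                           list(type = "exchange_log"))
  jsonlite::write_json(
    list(params = ws$params, k = ws$windows$k,
         centers = ws$windows$centers, ids = ws$windows$ids,
         cyclic = ws$windows$cyclic),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_window_samples
#' @export
read_window_samples <- function(path) {
  got <- .read_tsv_with_header(path, c("window", "replica", "time", "cv_1",
                                       "bias_energy"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  centers <- matrix(unlist(meta$centers), nrow = length(meta$ids))
  windows <- structure(list(centers = centers, k = meta$k,
                            ids = as.integer(meta$ids),
                            neighbors = cbind(seq_along(meta$ids),
                                              c(seq_along(meta$ids)[-1L], 1L)),
                            cyclic = isTRUE(meta$cyclic),
                            convention = "V(x) = k * |x - center|^2, k in kcal/mol/A^2"),
                       class = "umbrella_windows")
  ex_path <- paste0(path, ".exchange.tsv")
  structure(list(samples = got$df,
                 exchange_log = if (file.exists(ex_path))
                   .read_tsv_with_header(ex_path, c("sweep", "edge_i",
                                                    "edge_j", "accepted"))$df
                 else NULL,
                 windows = windows, params = meta$params),
            class = "window_samples")
}

#' Write / read a PMF grid
#'
#' Row-major TSV matrix with a header carrying origin, spacing and kT;
#' unoccupied cells are written as `NA`.  Counts go to `<path>.counts.tsv`.
#' Values round-trip exactly (17 significant digits).
#'
#' @param pmf a `pmf_grid`.
#' @param path output TSV path.
#' @export
write_pmf <- function(pmf, path) {
  hdr <- list(type = "pmf_grid",
              origin = pmf$origin, spacing = pmf$spacing,
              nx = pmf$nx, ny = pmf$ny, kT = pmf$kT,
              units = "kcal/mol; minimum over occupied cells is 0",
              minima_convention = "minimum over 3x3 cell neighborhood")
  df <- as.data.frame(pmf$values)
  names(df) <- paste0("c", seq_len(pmf$ny))
  .write_tsv_with_header(df, path, hdr)
  dfc <- as.data.frame(pmf$counts)
  names(dfc) <- paste0("c", seq_len(pmf$ny))
  .write_tsv_with_header(dfc, paste0(path, ".counts.tsv"),
                         list(type = "pmf_counts"))
  invisible(path)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path) {
  got <- .read_tsv_with_header(path, "c1")
  h <- got$header
  num <- function(k) as.numeric(strsplit(h[[k]], " +")[[1L]])
  counts <- .read_tsv_with_header(paste0(path, ".counts.tsv"), "c1")$df
  vals <- as.matrix(got$df)
  dimnames(vals) <- NULL
  cmat <- as.matrix(counts)
  dimnames(cmat) <- NULL
  new_pmf_grid(num("origin"), num("spacing"), vals, cmat, num("kT"))
}

#' Write / read kinetics rate tables
#'
#' TSV columns `concentration_M`, `rate`, `replicate`, `species`; the truth
#' parameters and noise metadata go in the JSON sidecar.
#'
#' @param datasets a list of `kinetics_dataset` objects (as returned by
#'   [make_kinetics_fixture()]).
#' @param path output TSV path.
#' @export
write_kinetics <- function(datasets, path) {
  df <- do.call(rbind, lapply(datasets, as.data.frame))
  rownames(df) <- NULL
  .write_tsv_with_header(df, path, list(type = "kinetics",
                                        units = "concentration M; rate arbitrary"))
  jsonlite::write_json(
    lapply(datasets, function(d) list(species = attr(d, "species"),
                                      truth = attr(d, "truth"),
                                      cv = attr(d, "cv"),
                                      seed = attr(d, "seed"))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kinetics
#' @export
read_kinetics <- function(path) {
  got <- .read_tsv_with_header(path, c("concentration_M", "rate",
                                       "replicate", "species"))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  sp <- split(got$df, got$df$species)
  out <- lapply(names(sp), function(s) {
    d <- sp[[s]]
    rownames(d) <- NULL
    m <- meta[[s]]
    structure(d, species = s, truth = m$truth, cv = m$cv,
              seed = m$seed, class = c("kinetics_dataset", "data.frame"))
  })
  names(out) <- names(sp)
  out
}

#' Write a free-energy path and its barrier report
#'
#' Path as TSV (`index`, `x`, `y`, `F`), barrier report as JSON.
#'
#' @param path_obj an `fe_path`.
#' @param report a `barrier_report` (optional).
#' @param path output TSV path.
#' @export
write_fe_path <- function(path_obj, path, report = NULL) {
  .write_tsv_with_header(as.data.frame(path_obj), path, list(
    type = "fe_path", branch = attr(path_obj, "branch") %||% "unconstrained"))
  if (!is.null(report))
    jsonlite::write_json(unclass(report), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
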