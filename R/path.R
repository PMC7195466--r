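#' Cyclic guiding paths for umbrella sampling
#'
#' A `guiding_path` is an ordered set of points in CV space.  Cyclic paths
#' treat the last and first points as adjacent (the ring topology in which
#' windows numbered 0 and n-1 are connected).  Two points — by convention the
#' interface pose (id 0) and the active-site pose (id 24 on the default
#' 48-point loop) — are flagged fixed and never move during optimization.
#' Window/point ids are 0-based to match the field's numbering; R indices are
#' ids + 1.
#'
#' @param n number of guiding points (>= 4).
#' @param geometry `"circle"` (points uniformly spaced on a circle of radius
#'   `radius`) or `"explicit"` with `points` supplied.
#' @param radius circle radius for `geometry = "circle"`.
#' @param points explicit `n x d` matrix for `geometry = "explicit"`.
#' @param active_id,interface_id 0-based ids of the two fixed points.  On the
#'   circle the interface point is placed at angle pi and the active point at
#'   angle 0.
#' @param cyclic logical; default TRUE.
#' @return object of class `guiding_path`: list with `points` (n x d),
#'   `cyclic`, `fixed` (1-based indices), `iteration`.
#' @export
init_guiding_path <- function(n = 48L, geometry = c("circle", "explicit"),
                              radius = 2.0, points = NULL,
                              active_id = 24L, interface_id = 0L,
                              cyclic = TRUE) {
  geometry <- match.arg(geometry)
  n <- as.integer(n)
  if (n < 4L) stop("need at least 4 guiding points")
  if (active_id == interface_id) stop("fixed ids must be distinct")
  if (any(c(active_id, interface_id) < 0L) ||
      any(c(active_id, interface_id) >= n))
    stop("fixed ids out of range [0, ", n - 1L, "]")
  if (geometry == "circle") {
    # interface_id at angle pi, active_id at angle 0, uniform spacing.
    # angle(i) = pi - 2*pi*(i - interface_id)/n places interface at pi; the
    # active point lands at 0 only if the ids are half a ring apart, which is
    # checked.
    if ((active_id - interface_id) %% n != n %/% 2L)
      warning("fixed ids are not diametrically opposite; ",
              "active point will not sit at angle 0")
    theta <- pi - 2 * pi * ((seq_len(n) - 1L - interface_id) %% n) / n
    pts <- cbind(radius * cos(theta), radius * sin(theta))
  } else {
    pts <- as.matrix(points)
    if (nrow(pts) != n) stop("points must have ", n, " rows")
  }
  structure(list(points = pts, cyclic = cyclic,
                 fixed = sort(c(interface_id, active_id)) + 1L,
                 ids = seq_len(n) - 1L, iteration = 0L),
            class = "guiding_path")
}

#' @export
print.guiding_path <- function(x, ...) {
  cat(sprintf("<guiding_path> %d points (%s), fixed ids: %s, iteration %d\n",
              nrow(x$points), if (x$cyclic) "cyclic" else "open",
              paste(x$fixed - 1L, collapse = ", "), x$iteration))
  invisible(x)
}

# cumulative arc length of a polyline (rows of pts)
.arclength <- function(pts) {
  seg <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(seg))
}

# resample a polyline at m equally spaced arc-length positions, endpoints kept
.resample_polyline <- function(pts, m) {
  s <- .arclength(pts)
  total <- s[length(s)]
  if (total == 0) return(matrix(pts[1L, ], m, ncol(pts), byrow = TRUE))
  target <- seq(0, total, length.out = m)
  out <- matrix(NA_real_, m, ncol(pts))
  for (j in seq_len(ncol(pts)))
    out[, j] <- stats::approx(s, pts[, j], xout = target, ties = "ordered")$y
  out
}

#' Reparameterize a guiding path to equal arc length
#'
#' Redistributes the points along the current polyline so that consecutive
#' arc lengths are equal, with the fixed points pinned exactly.  On a cyclic
#' path the fixed points split the loop into segments that are
#' reparameterized independently (each to equal spacing).  Idempotent: a
#' path that is already equally spaced is returned unchanged up to floating
#' point round-off.
#'
#' @param path a `guiding_path`.
#' @return the reparameterized `guiding_path`.
#' @export
reparameterize_path <- function(path) {
  stopifnot(inherits(path, "guiding_path"))
  pts <- path$points
  n <- nrow(pts)
  fx <- path$fixed
  if (!path$cyclic) {
    anchors <- unique(c(1L, fx, n))
  } else {
    if (length(fx) == 0L) fx <- 1L
    anchors <- sort(unique(fx))
  }
  new_pts <- pts
  n_anchor <- length(anchors)
  for (a in seq_len(n_anchor)) {
    i0 <- anchors[a]
    i1 <- if (a < n_anchor) anchors[a + 1L] else
      if (path$cyclic) anchors[1L] else break
    idx <- if (i1 > i0) i0:i1 else c(i0:n, 1:i1)
    if (length(idx) < 3L) next
    new_pts[idx, ] <- .resample_polyline(pts[idx, , drop = FALSE],
                                         length(idx))
  }
  path$points <- new_pts
  path
}

#' Build umbrella windows from a guiding path
#'
#' One harmonic window per guiding point, with the restraint convention
#' \eqn{V_w(x) = k\,|x - c_w|^2} (no 1/2 factor; `k` in kcal/mol/A^2; the
#' convention is recorded on the result and in output headers).  Neighbor
#' topology is copied from the path: on a cyclic path the first and last
#' windows are neighbors.
#'
#' @param path a `guiding_path`.
#' @param k force constant(s), kcal/mol/A^2 (> 0); a scalar shared by all
#'   windows or one value per window.  2.39 for the string phase and 0.48
#'   for the production phase of the modelled protocol.
#' @return object of class `umbrella_windows`: list with `centers` (n x d),
#'   `k`, `ids` (0-based), `neighbors` (two-column matrix of 1-based index
#'   pairs), `cyclic`, `convention`.
#' @export
build_windows <- function(path, k = 0.48) {
  stopifnot(inherits(path, "guiding_path"), all(k > 0))
  n <- nrow(path$points)
  k <- rep_len(k, n)
  nb <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  if (!path$cyclic) nb <- nb[-n, , drop = FALSE]
  structure(list(centers = path$points, k = k, ids = path$ids,
                 neighbors = nb, cyclic = path$cyclic,
                 convention = "V(x) = k * |x - center|^2, k in kcal/mol/A^2"),
            class = "umbrella_windows")
}

#' @export
print.umbrella_windows <- function(x, ...) {
  cat(sprintf("<umbrella_windows> %d windows, k in [%g, %g] kcal/mol/A^2 (%s), %s\n",
              nrow(x$centers), min(x$k), max(x$k), x$convention,
              if (x$cyclic) "cyclic" else "open"))
  invisible(x)
}

# window bias energy of states (n x d) in their own windows / arbitrary pairs
.window_energy <- function(windows, x, which_window) {
  dx <- x - windows$centers[which_window, , drop = FALSE]
  rep_len(windows$k, nrow(windows$centers))[which_window] * rowSums(dx^2)
}
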