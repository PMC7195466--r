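#' Two-minimum cyclic loading landscape
#'
#' Builds the calibrated analytic stand-in for the free-energy surface of the
#' interface-to-active-site substrate loading process: a circular valley of
#' radius `R` carrying two minima (the active site at angle 0, the interface
#' at angle pi) connected by two mirror-symmetric angular branches, each
#' blocked by a Gaussian saddle.
#'
#' The functional form is
#' \deqn{F(x, y) = A(\rho - R)^2 + \frac{\Delta}{2}(1 - \cos\theta)
#'       + \frac{w}{2}(1 - \cos 2\theta)
#'       + h\,[g(\theta - \pi/2) + g(\theta + \pi/2)] + F_0}
#' with \eqn{(\rho, \theta)} polar coordinates and \eqn{g} a wrapped Gaussian
#' bump of angular width `sigma`.  The \eqn{\cos\theta} term alone is concave
#' at \eqn{\theta = \pi}, so the well-shaping \eqn{\cos 2\theta} term (which
#' vanishes exactly at both minima and therefore does not disturb their
#' calibrated depths) is required to make the interface pose a true local
#' minimum; any `well_stiffness` above \eqn{\Delta/4} does so, and the
#' default 2.0 keeps each branch single-peaked.  The bump height `h` is
#' calibrated by 1D
#' root-finding on the angular profile so that the maximum along each branch
#' sits exactly `saddle_height` above the global minimum, and the constant
#' \eqn{F_0} then shifts the active-site minimum to exactly 0.  Defaults
#' place the interface minimum at +2.5 kcal/mol and the saddles at
#' +4.2 kcal/mol, the depths and barrier of the modelled loading landscape.
#'
#' Both branches are identical by construction (mirror symmetry across the
#' axis through the minima); `bump_delta` adds an optional asymmetry to the
#' +pi/2 bump for studies that need distinguishable branches.
#'
#' @param ring_radius radius `R` of the circular valley (length units).
#' @param radial_stiffness `A`, kcal/mol per length^2; confines the valley.
#' @param minima_offset `Delta`, kcal/mol; interface minus active-site depth.
#' @param saddle_height `H`, kcal/mol; branch maximum above the global
#'   minimum.  Must exceed `minima_offset`.
#' @param bump_width `sigma`, radians; angular width of the saddle bumps.
#' @param well_stiffness `w`, kcal/mol; strength of the well-shaping
#'   \eqn{\cos 2\theta} term (must exceed `minima_offset / 4` for the
#'   interface pose to be a minimum).
#' @param bump_height optional; if supplied, skips calibration and uses this
#'   `h` directly.
#' @param bump_delta additive asymmetry on the +pi/2 bump (default 0).
#' @return A [new_potential()] with the calibration recorded in
#'   `metadata$params` (including the calibrated `bump_height`, the gauge
#'   shift, and the located saddle angles).
#' @examples
#' pot <- make_ga2ox_landscape()
#' energy_at(pot, c(pot$metadata$params$ring_radius, 0))   # ~0 (active site)
#' energy_at(pot, c(-pot$metadata$params$ring_radius, 0))  # ~2.5 (interface)
#' @export
make_ga2ox_landscape <- function(ring_radius = 2.0, radial_stiffness = 5.0,
                                 minima_offset = 2.5, saddle_height = 4.2,
                                 bump_width = 0.35, well_stiffness = 2.0,
                                 bump_height = NULL, bump_delta = 0) {
  R <- ring_radius; A <- radial_stiffness
  Delta <- minima_offset; H <- saddle_height; sigma <- bump_width
  w <- well_stiffness
  stopifnot(R > 0, A > 0, sigma > 0, Delta >= 0)
  if (w <= Delta / 4)
    stop("well_stiffness must exceed minima_offset/4 (", Delta / 4,
         ") for the interface pose to be a local minimum")

  g <- function(u) .wrapped_gaussian(u, sigma)
  gd <- function(u) .wrapped_gaussian_d(u, sigma)

  angular <- function(theta, h) {
    Delta * (1 - cos(theta)) / 2 + w * (1 - cos(2 * theta)) / 2 +
      h * ((1 + bump_delta) * g(theta - pi / 2) + g(theta + pi / 2))
  }

  if (is.null(bump_height)) {
    if (H <= Delta)
      stop("infeasible calibration: saddle_height (", H,
           ") must exceed minima_offset (", Delta,
           "); no bump height can place the branch maximum below the ",
           "interface minimum")
    # dense scan + root-finding on max(profile) - min(profile) = H
    th <- seq(-pi, pi, length.out = 4001L)
    relief <- function(h) {
      prof <- angular(th, h)
      max(prof) - min(prof) - H
    }
    if (relief(0) > 0)
      stop("infeasible calibration: the bump-free profile already exceeds ",
           "saddle_height ", H, "; lower well_stiffness or raise the target")
    hi <- 1
    while (relief(hi) < 0 && hi < 1e6) hi <- hi * 2
    if (relief(hi) < 0) stop("infeasible calibration: cannot reach ",
                             "saddle_height ", H)
    h <- stats::uniroot(relief, c(0, hi), tol = 1e-12)$root
  } else {
    h <- bump_height
  }

  # gauge: active-site minimum (near theta = 0) shifted to exactly 0;
  # the radial term is separable and vanishes on rho = R, so the global
  # minimum of F is the minimum of the angular profile.
  o_act <- stats::optimize(function(t) angular(t, h),
                           c(-pi / 2, pi / 2), tol = 1e-12)
  F0 <- -o_act$objective
  # interface minimum and branch saddles, for metadata
  o_int <- stats::optimize(function(t) angular(t, h),
                           c(pi / 2, 3 * pi / 2), tol = 1e-12)
  o_sad <- stats::optimize(function(t) -angular(t, h), c(0, pi), tol = 1e-12)

  energy <- function(x) {
    rho <- sqrt(x[, 1L]^2 + x[, 2L]^2)
    theta <- atan2(x[, 2L], x[, 1L])
    A * (rho - R)^2 + angular(theta, h) + F0
  }
  gradient <- function(x) {
    rho <- pmax(sqrt(x[, 1L]^2 + x[, 2L]^2), 1e-12)
    theta <- atan2(x[, 2L], x[, 1L])
    dU_drho <- 2 * A * (rho - R)
    dU_dth <- Delta * sin(theta) / 2 + w * sin(2 * theta) +
      h * ((1 + bump_delta) * gd(theta - pi / 2) + gd(theta + pi / 2))
    gx <- dU_drho * x[, 1L] / rho - dU_dth * x[, 2L] / rho^2
    gy <- dU_drho * x[, 2L] / rho + dU_dth * x[, 1L] / rho^2
    cbind(gx, gy, deparse.level = 0)
  }

  new_potential(2L, energy, gradient, name = "ga2ox_mimetic_landscape",
    params = list(ring_radius = R, radial_stiffness = A,
                  minima_offset = Delta, saddle_height = H,
                  bump_width = sigma, well_stiffness = w, bump_height = h,
                  bump_delta = bump_delta, gauge_shift = F0,
                  active_angle = o_act$minimum,
                  interface_angle = .wrap_angle(o_int$minimum),
                  saddle_angle = o_sad$minimum),
    domain_bound = 50 * R)
}

.wrap_angle <- function(t) atan2(sin(t), cos(t))

# wrapped Gaussian bump of unit height, periodic on [-pi, pi)
.wrapped_gaussian <- function(u, sigma, kmax = 3L) {
  out <- 0
  for (k in -kmax:kmax) out <- out + exp(-(u + 2 * pi * k)^2 / (2 * sigma^2))
  out
}
.wrapped_gaussian_d <- function(u, sigma, kmax = 3L) {
  out <- 0
  for (k in -kmax:kmax) {
    v <- u + 2 * pi * k
    out <- out - v / sigma^2 * exp(-v^2 / (2 * sigma^2))
  }
  out
}

#' Angular free-energy profile of a cyclic landscape
#'
#' Convenience view of a 2D potential along its valley circle `rho = R`:
#' energies at `n` equally spaced angles.  Used by the calibration tests and
#' for plotting 1D profiles.
#'
#' @param potential a 2D [new_potential()].
#' @param radius circle radius (defaults to the potential's `ring_radius`).
#' @param n number of angles.
#' @return data.frame with columns `theta`, `energy`.
#' @export
angular_profile <- function(potential, radius = NULL, n = 721L) {
  stopifnot(potential$dimensionality == 2L)
  radius <- radius %||% potential$metadata$params$ring_radius
  if (is.null(radius)) stop("radius required for a non-ring potential")
  theta <- seq(-pi, pi, length.out = n)
  xy <- cbind(radius * cos(theta), radius * sin(theta))
  data.frame(theta = theta, energy = potential$energy(xy))
}
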