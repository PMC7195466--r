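#' Analytic potential objects
#'
#' A `potential` is an analytic energy surface over a low-dimensional
#' collective-variable (CV) space.  It bundles vectorised energy and gradient
#' closures with descriptive metadata, and is the substrate for the Langevin
#' sampler, the umbrella-sampling machinery and the free-energy estimators.
#'
#' Energies are in kcal/mol and lengths nominally in Angstrom throughout; the
#' surfaces themselves are unitless constructions, the labels merely keep the
#' printed constants of the modelled system usable without conversion.
#'
#' @param dimensionality integer, number of CV dimensions (1, 2 or 3).
#' @param energy function taking an `n x d` matrix of points and returning a
#'   length-`n` numeric vector of energies (kcal/mol).
#' @param gradient function taking an `n x d` matrix and returning an `n x d`
#'   matrix of gradients (kcal/mol per length unit).
#' @param name character scalar naming the potential.
#' @param params named list of the parameters the closures were built from.
#' @param domain_bound positive scalar; `|x|` beyond this is considered
#'   divergent by the sampler.
#'
#' @return An object of class `potential`.
#' @seealso [energy_at()], [gradient_at()], [make_test_potential()],
#'   [make_ga2ox_landscape()]
#' @export
new_potential <- function(dimensionality, energy, gradient, name,
                          params = list(), domain_bound = 1e3) {
  stopifnot(dimensionality %in% c(1L, 2L, 3L),
            is.function(energy), is.function(gradient))
  structure(
    list(dimensionality = as.integer(dimensionality),
         energy = energy, gradient = gradient,
         metadata = list(name = name, params = params),
         domain_bound = domain_bound),
    class = "potential")
}

#' @export
print.potential <- function(x, ...) {
  cat("<potential> ", x$metadata$name,
      " (", x$dimensionality, "D)\n", sep = "")
  p <- x$metadata$params
  if (length(p))
    cat("  params:", paste(names(p), vapply(p, function(v)
      paste(signif(unlist(v), 6), collapse = ","), ""),
      sep = "=", collapse = "  "), "\n")
  invisible(x)
}

.as_points <- function(x, d) {
  if (is.null(dim(x))) {
    if (length(x) == d) x <- matrix(x, nrow = 1L)
    else if (d == 1L) x <- matrix(x, ncol = 1L)
    else stop("point has length ", length(x), ", expected ", d)
  }
  x <- as.matrix(x)
  if (ncol(x) != d) stop("points have ", ncol(x), " columns, expected ", d)
  storage.mode(x) <- "double"
  x
}

#' Evaluate a potential
#'
#' @param potential a [new_potential()] object.
#' @param x a point (length-`d` vector) or an `n x d` matrix of points.
#' @return `energy_at`: numeric vector of energies (kcal/mol);
#'   `gradient_at`: an `n x d` gradient matrix (a plain vector for a single
#'   point).
#' @export
energy_at <- function(potential, x) {
  stopifnot(inherits(potential, "potential"))
  potential$energy(.as_points(x, potential$dimensionality))
}

#' @rdname energy_at
#' @export
gradient_at <- function(potential, x) {
  stopifnot(inherits(potential, "potential"))
  g <- potential$gradient(.as_points(x, potential$dimensionality))
  if (is.null(dim(x)) && length(x) == potential$dimensionality) drop(g) else g
}

# C2 quintic smoothstep: 0 for t<=0, 1 for t>=1
.smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^3 * (10 + t * (-15 + 6 * t))
}
.smoothstep_d <- function(t) {
  ifelse(t <= 0 | t >= 1, 0, 30 * t^2 * (1 - t)^2)
}

#' Generic analytic test potentials
#'
#' Closed-form surfaces used as oracle substrates for the sampler and the
#' free-energy estimators.
#'
#' * `harmonic`: \eqn{U = \sum_i \tfrac12 k_i (x_i - c_i)^2}; params `k`
#'   (scalar or per-dimension), `center`, `dim`.
#' * `flat`: identically zero; params `dim`.
#' * `double_well_1d`: two wells of identical shape at \eqn{x=\pm 1} offset by
#'   `dG`, \eqn{U = b (x^2-1)^2 + dG\, s(x)} with \eqn{s} a quintic smoothstep
#'   across `[-w, w]`; because the wells are congruent, the well free-energy
#'   difference equals `dG` at any temperature at which the barrier-top
#'   contribution is negligible.  Params `dG`, `barrier` (= b), `width`
#'   (default 0.3).
#' * `ring_valley`: \eqn{U = A(\rho - R)^2}, a circular trough of radius `R`
#'   whose valley floor is known analytically; params `A`, `R`.
#'
#' @param kind one of `"harmonic"`, `"flat"`, `"double_well_1d"`,
#'   `"ring_valley"`.
#' @param params named list of parameters, see Details.
#' @return A [new_potential()] object.
#' @export
make_test_potential <- function(kind = c("harmonic", "flat", "double_well_1d",
                                         "ring_valley"),
                                params = list()) {
  kind <- match.arg(kind)
  switch(kind,
    harmonic = {
      d <- as.integer(params$dim %||% 2L)
      k <- params$k %||% 1
      if (any(k <= 0)) stop("harmonic stiffness k must be positive")
      k <- rep_len(k, d)
      ctr <- rep_len(params$center %||% 0, d)
      new_potential(d,
        energy = function(x) {
          dx <- sweep(x, 2L, ctr)
          0.5 * drop(dx^2 %*% k)
        },
        gradient = function(x) sweep(sweep(x, 2L, ctr), 2L, k, `*`),
        name = "harmonic", params = list(k = k, center = ctr))
    },
    flat = {
      d <- as.integer(params$dim %||% 2L)
      new_potential(d,
        energy = function(x) rep(0, nrow(x)),
        gradient = function(x) x * 0,
        name = "flat", params = list())
    },
    double_well_1d = {
      dG <- params$dG %||% 1
      b <- params$barrier %||% 3
      w <- params$width %||% 0.3
      if (b <= 0) stop("barrier must be positive")
      new_potential(1L,
        energy = function(x) {
          x <- drop(x)
          b * (x^2 - 1)^2 + dG * .smoothstep((x + w) / (2 * w))
        },
        gradient = function(x) {
          xv <- drop(x)
          g <- 4 * b * xv * (xv^2 - 1) +
            dG * .smoothstep_d((xv + w) / (2 * w)) / (2 * w)
          matrix(g, ncol = 1L)
        },
        name = "double_well_1d", params = list(dG = dG, barrier = b, width = w))
    },
    ring_valley = {
      A <- params$A %||% 5
      R <- params$R %||% 2
      if (A <= 0 || R <= 0) stop("A and R must be positive")
      new_potential(2L,
        energy = function(x) {
          rho <- sqrt(x[, 1L]^2 + x[, 2L]^2)
          A * (rho - R)^2
        },
        gradient = function(x) {
          rho <- pmax(sqrt(x[, 1L]^2 + x[, 2L]^2), 1e-12)
          (2 * A * (rho - R) / rho) * x
        },
        name = "ring_valley", params = list(A = A, R = R))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact Boltzmann sampling by rejection
#'
#' Draws independent samples from \eqn{p(x) \propto \exp(-U(x)/kT)} on a
#' rectangular domain by uniform-proposal rejection against the domain minimum
#' of `U`.  Exact up to the domain truncation; used as the independent sampling
#' oracle against which dynamical samplers and estimators are validated.
#'
#' @param potential a [new_potential()] object.
#' @param kT thermal energy, kcal/mol.
#' @param n number of samples.
#' @param lower,upper numeric vectors, the rectangular domain.
#' @param seed integer RNG seed (required: fixtures must be reproducible).
#' @return `n x d` matrix of samples.
#' @export
sample_boltzmann <- function(potential, kT, n, lower, upper, seed) {
  stopifnot(inherits(potential, "potential"), kT > 0, n >= 1)
  d <- potential$dimensionality
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  set.seed(as.integer(seed))
  # domain minimum via coarse scan (the acceptance bound)
  grid <- as.matrix(do.call(expand.grid, lapply(seq_len(d), function(i)
    seq(lower[i], upper[i], length.out = if (d >= 3) 25 else 120))))
  u_min <- min(potential$energy(grid))
  out <- matrix(NA_real_, 0L, d)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 1000L)
    prop <- vapply(seq_len(d), function(i) stats::runif(m, lower[i], upper[i]),
                   numeric(m))
    prop <- matrix(prop, ncol = d)
    acc <- stats::runif(m) < exp(-(potential$energy(prop) - u_min) / kT)
    out <- rbind(out, prop[acc, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}
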