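#' Bias potentials
#'
#' Composable time-dependent bias potentials for the Langevin sampler.  A
#' `bias` object carries vectorised spatial closures `energy(x, t)` and
#' `gradient(x, t)` (`x` an `n x d` matrix) plus its defining parameters.
#'
#' @name bias
NULL

new_bias <- function(energy, gradient, name, params = list()) {
  structure(list(energy = energy, gradient = gradient,
                 metadata = list(name = name, params = params)),
            class = "bias")
}

#' @export
print.bias <- function(x, ...) {
  cat("<bias>", x$metadata$name, "\n")
  invisible(x)
}

#' Harmonic umbrella restraint
#'
#' \eqn{V(x) = k\,|x - c|^2} — note the convention: no 1/2 factor, `k` in
#' kcal/mol/A^2.  This is the window restraint of the umbrella-sampling
#' machinery; the convention is stated in every output header.
#'
#' @param center numeric d-vector, the window center.
#' @param k force constant, kcal/mol/A^2 (> 0).
#' @return a `bias` object.
#' @export
harmonic_bias <- function(center, k) {
  stopifnot(k > 0)
  center <- as.numeric(center)
  new_bias(
    energy = function(x, t = 0) {
      dx <- sweep(x, 2L, center)
      k * rowSums(dx^2)
    },
    gradient = function(x, t = 0) 2 * k * sweep(x, 2L, center),
    name = "harmonic", params = list(center = center, k = k))
}

#' Bias schedule for the moving exit restraint
#'
#' Parameters of the time-dependent flat-bottom restraint used to drive a
#' ligand out of a binding well: \eqn{r_0(t) = r_0(0) + c\,t}, exactly linear
#' in `t`.
#'
#' @param k_bias restraint constant, kcal/mol/A^2 (>= 0).  The modelled
#'   protocol used 10 kJ/mol/A^2 (= 2.39 kcal/mol/A^2); the source's printed
#'   unit string `"10 kJ A-2"` omits the /mol and is preserved verbatim in
#'   the metadata rather than silently corrected.
#' @param pull_speed `c`, length per time unit (0.1 by default).
#' @param r0_initial initial restraint radius `r_0(0)`.
#' @param reference numeric d-vector; `r` is measured from this point (the
#'   stand-in for the receptor-site centre of mass).
#' @return object of class `bias_schedule`.
#' @export
bias_schedule <- function(k_bias = 10 / 4.184,
                          pull_speed = 0.1, r0_initial = 0,
                          reference = c(0, 0)) {
  stopifnot(k_bias >= 0)
  structure(list(k_bias = k_bias, pull_speed = pull_speed,
                 r0_initial = r0_initial, reference = as.numeric(reference),
                 source_unit_string = "10 kJ A-2 (as printed; read as kJ/mol/A^2)"),
            class = "bias_schedule")
}

#' @export
print.bias_schedule <- function(x, ...) {
  cat(sprintf("<bias_schedule> k_bias=%g kcal/mol/A^2, c=%g /time, r0(0)=%g\n",
              x$k_bias, x$pull_speed, x$r0_initial))
  invisible(x)
}

#' Moving flat-bottom exit restraint
#'
#' One-sided restraint \eqn{V_{bias} = k_{bias}\,(\min(r - r_0(t), 0))^2}
#' with \eqn{r_0(t) = r_0(0) + c\,t}: zero whenever the exit distance `r`
#' already exceeds the moving radius, quadratic inside it.  Continuous (with
#' continuous gradient) at `r = r_0(t)`.
#'
#' The returned object exposes the spatial closures used by the sampler and,
#' additionally, `energy_r(r, t)` evaluating the restraint directly on the
#' scalar exit distance.
#'
#' @param schedule a [bias_schedule()].
#' @return a `bias` object with an extra `energy_r(r, t)` element.
#' @examples
#' b <- moving_flatbottom_bias(bias_schedule(k_bias = 10, pull_speed = 0))
#' b$energy_r(1.5, 0)  # 0: outside the wall
#' b$energy_r(-Inf, 0) # would be Inf; at r0 - 1 it is k_bias
#' @export
moving_flatbottom_bias <- function(schedule) {
  stopifnot(inherits(schedule, "bias_schedule"))
  k <- schedule$k_bias; cc <- schedule$pull_speed
  r00 <- schedule$r0_initial; ref <- schedule$reference
  r0_at <- function(t) r00 + cc * t
  energy_r <- function(r, t) k * pmin(r - r0_at(t), 0)^2
  b <- new_bias(
    energy = function(x, t = 0) {
      dx <- sweep(x, 2L, ref)
      r <- sqrt(rowSums(dx^2))
      energy_r(r, t)
    },
    gradient = function(x, t = 0) {
      dx <- sweep(x, 2L, ref)
      r <- pmax(sqrt(rowSums(dx^2)), 1e-12)
      (2 * k * pmin(r - r0_at(t), 0) / r) * dx
    },
    name = "moving_flatbottom",
    params = list(k_bias = k, pull_speed = cc, r0_initial = r00,
                  reference = ref))
  b$energy_r <- energy_r
  b$r0_at <- r0_at
  b
}
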