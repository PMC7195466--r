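#' Lineweaver-Burk fit of Michaelis-Menten kinetics
#'
#' Unweighted ordinary least squares on the double-reciprocal transform
#' \eqn{1/v = (K_m/V_{max})\,(1/S) + 1/V_{max}} of the replicate means (the
#' mean rate at each concentration): slope = Km/Vmax, intercept = 1/Vmax.
#' Noiseless data are recovered exactly; a non-positive fitted intercept
#' (which would imply a negative Vmax) is an error.
#'
#' @param dataset a `kinetics_dataset` (data.frame with `concentration_M`,
#'   `rate`, `replicate`).
#' @return object of class `mm_fit`: list with `Km` (molar), `Vmax`,
#'   standard errors (delta method from the regression), `method = "LB"`,
#'   `residuals` (on the reciprocal scale) and `species`.
#' @export
fit_lineweaver_burk <- function(dataset) {
  conc <- dataset$concentration_M
  if (length(unique(conc)) < 3L) stop("need >= 3 distinct concentrations")
  if (any(dataset$rate <= 0))
    stop("all rates must be positive for the reciprocal transform")
  means <- tapply(dataset$rate, conc, mean)
  S <- as.numeric(names(means))
  v <- as.numeric(means)
  if (any(v <= 0))
    stop("all replicate-mean rates must be positive for the reciprocal ",
         "transform")
  fit <- stats::lm(y ~ x, data = data.frame(x = 1 / S, y = 1 / v))
  b0 <- stats::coef(fit)[[1L]]  # 1/Vmax
  b1 <- stats::coef(fit)[[2L]]  # Km/Vmax
  if (b0 <= 0)
    stop("Lineweaver-Burk intercept is non-positive; Vmax undefined")
  # noiseless tables fit exactly; R warns that the summary is unreliable,
  # which is expected and harmless for the standard errors reported here
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  Vmax <- 1 / b0
  Km <- b1 / b0
  structure(list(Km = Km, Vmax = Vmax,
                 Km_se = abs(Km) * sqrt((se[2L] / b1)^2 + (se[1L] / b0)^2),
                 Vmax_se = Vmax^2 * se[1L],
                 method = "LB", residuals = stats::residuals(fit),
                 species = attr(dataset, "species")),
            class = "mm_fit")
}

#' Direct nonlinear least-squares Michaelis-Menten fit
#'
#' Oracle cross-check for the Lineweaver-Burk route: fits
#' \eqn{v = V_{max} S/(K_m + S)} to the pooled points by nonlinear least
#' squares, initialized from the Lineweaver-Burk estimates.
#'
#' @param dataset a `kinetics_dataset`.
#' @return an `mm_fit` with `method = "NLS"`.
#' @export
fit_mm_nls <- function(dataset) {
  start <- tryCatch({
    lb <- fit_lineweaver_burk(dataset)
    list(Km = lb$Km, Vmax = lb$Vmax)
  }, error = function(e)
    list(Km = stats::median(dataset$concentration_M),
         Vmax = max(dataset$rate)))
  fit <- stats::nls(rate ~ Vmax * concentration_M / (Km + concentration_M),
                    data = dataset, start = start,
                    control = stats::nls.control(maxiter = 200L,
                                                 scaleOffset = 1,
                                                 warnOnly = FALSE))
  co <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(Km = co[["Km"]], Vmax = co[["Vmax"]],
                 Km_se = se[["Km"]], Vmax_se = se[["Vmax"]],
                 method = "NLS", residuals = stats::residuals(fit),
                 species = attr(dataset, "species")),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit:%s> %s: Km = %.3g M (se %.2g), Vmax = %.4g (se %.2g)\n",
              x$method, x$species %||% "?", x$Km, x$Km_se, x$Vmax, x$Vmax_se))
  invisible(x)
}

#' Monomer-versus-multimer kinetic comparison
#'
#' Fold-changes computed exactly from two fits: Km fold = monomer Km /
#' multimer Km (how much tighter the multimer binds), Vmax fold = multimer
#' Vmax / monomer Vmax (how much faster it turns over).
#'
#' @param fit_monomer,fit_multimer `mm_fit` objects.
#' @return object of class `oligomer_comparison`: list with `Km_fold`,
#'   `Vmax_fold` and the species labels.
#' @export
compare_oligomers <- function(fit_monomer, fit_multimer) {
  stopifnot(inherits(fit_monomer, "mm_fit"), inherits(fit_multimer, "mm_fit"))
  structure(list(Km_fold = fit_monomer$Km / fit_multimer$Km,
                 Vmax_fold = fit_multimer$Vmax / fit_monomer$Vmax,
                 monomer = fit_monomer$species,
                 multimer = fit_multimer$species),
            class = "oligomer_comparison")
}

#' @export
print.oligomer_comparison <- function(x, ...) {
  cat(sprintf("<oligomer_comparison> %s vs %s: Km %.3g-fold lower, Vmax %.3g-fold higher in the multimer\n",
              x$monomer %||% "monomer", x$multimer %||% "multimer",
              x$Km_fold, x$Vmax_fold))
  invisible(x)
}

#' Ratio of two reaction rates
#'
#' @param rate_a,rate_b rates in the same units (`rate_b` > 0).
#' @return `rate_a / rate_b`.
#' @examples
#' compare_rates(54.48, 244)  # ~0.22: about a quarter
#' @export
compare_rates <- function(rate_a, rate_b) {
  if (any(rate_b == 0)) stop("division by zero rate")
  rate_a / rate_b
}

#' Multimer fraction as a function of substrate concentration
#'
#' An invented Hill-type dose-response stand-in for substrate-driven
#' multimerization: \eqn{f(S) = S^{n}/(K^{n} + S^{n})}, monotone
#' non-decreasing, 0 at S = 0 and 1/2 at S = K.  Defaults are calibrated
#' qualitatively so activation starts below 1e-6 M and saturates near
#' 1e-4 M.  This functional form is a modelling choice of this package, not
#' a measured law.
#'
#' @param S substrate concentration, molar (>= 0).
#' @param K_half half-saturation concentration, molar.
#' @param n_H Hill coefficient.
#' @return multimer fraction in `[0, 1]`.
#' @export
multimer_dose_response <- function(S, K_half = 5e-6, n_H = 1.5) {
  stopifnot(all(S >= 0), K_half > 0, n_H > 0)
  Sn <- S^n_H
  Sn / (K_half^n_H + Sn)
}

#' Multimerization time course
#'
#' Invented first-order relaxation stand-in for the slow activation kinetics
#' observed on incubation with substrate:
#' \eqn{m(t) = m_\infty (1 - e^{-t/\tau})}, 0 at t = 0 and monotone in t.
#' With the default time constant of 6 h, most of the activation develops
#' after several hours.  A modelling choice of this package, not a measured
#' law.
#'
#' @param t time, hours (>= 0).
#' @param tau relaxation time constant, hours (> 0).
#' @param m_inf asymptotic multimer fraction.
#' @return multimer fraction at `t`.
#' @export
activation_time_course <- function(t, tau = 6, m_inf = 1) {
  stopifnot(all(t >= 0), tau > 0)
  m_inf * (1 - exp(-t / tau))
}

#' Effective activity of a monomer/multimer mixture
#'
#' \eqn{v_{eff}(S) = (1 - f(S))\,v_{mono}(S) + f(S)\,v_{multi}(S)} with
#' \eqn{f} the [multimer_dose_response()]: the population-weighted
#' Michaelis-Menten activity of a self-activating enzyme pool.
#'
#' @param S substrate concentration, molar.
#' @param truth_monomer,truth_multimer lists with `Km`, `Vmax`.
#' @param K_half,n_H dose-response parameters.
#' @return effective rate at each `S`.
#' @export
effective_activity <- function(S, truth_monomer, truth_multimer,
                               K_half = 5e-6, n_H = 1.5) {
  f <- multimer_dose_response(S, K_half, n_H)
  v <- function(tr) tr$Vmax * S / (tr$Km + S)
  (1 - f) * v(truth_monomer) + f * v(truth_multimer)
}
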