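#' Thermodynamic and unit utilities
#'
#' @name units
NULL

# Boltzmann constant in kcal/mol/K
.KB_KCAL <- 1.9872041e-3
.KJ_PER_KCAL <- 4.184

#' Thermal energy kT
#'
#' @param temperature numeric temperature.
#' @param unit `"K"` (kelvin) or `"C"` (celsius).  The unit is always
#'   explicit, never guessed.
#' @return kT in kcal/mol (k_B = 1.9872041e-3 kcal/mol/K).
#' @examples
#' thermal_energy(25, "C")  # 0.59 kcal/mol, the room-temperature fluctuation
#' thermal_energy(300, "K") # 0.596 kcal/mol, the simulation temperature
#' @export
thermal_energy <- function(temperature, unit = c("K", "C")) {
  unit <- match.arg(unit)
  T_K <- if (unit == "C") temperature + 273.15 else temperature
  if (any(T_K <= 0)) stop("temperature must be above 0 K")
  .KB_KCAL * T_K
}

#' Convert harmonic force constants between unit systems
#'
#' Exact conversion between the two unit systems force constants are commonly
#' printed in, using 1 kcal = 4.184 kJ and 1 nm = 10 Angstrom.  Round-trips
#' are exact.
#'
#' @param value numeric force constant(s).
#' @param from,to unit strings, one of `"kJ/mol/nm^2"`, `"kcal/mol/A^2"`.
#' @return converted value.
#' @examples
#' convert_force_constant(1000, "kJ/mol/nm^2", "kcal/mol/A^2") # 2.39
#' convert_force_constant(200,  "kJ/mol/nm^2", "kcal/mol/A^2") # 0.48
#' @export
convert_force_constant <- function(value, from, to) {
  units <- c("kJ/mol/nm^2" = 1, "kcal/mol/A^2" = .KJ_PER_KCAL * 100)
  if (!from %in% names(units)) stop("unknown unit: ", from)
  if (!to %in% names(units)) stop("unknown unit: ", to)
  value * units[[from]] / units[[to]]
}
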