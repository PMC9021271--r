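#' Boltzmann constant in eV per kelvin
#'
#' @keywords internal
BOLTZMANN_EV <- 8.618e-5

#' Reference temperature (kelvin) at which standardised temperatures are zero
#'
#' 283.15 K (10 degrees C), the conventional reference for cold-stream
#' invertebrate work.
#'
#' @keywords internal
T_REF_K <- 283.15

#' Convert degrees Celsius to kelvin
#'
#' @param temp_C temperature(s) in degrees Celsius.
#' @return temperature(s) in kelvin.
#' @export
celsius_to_kelvin <- function(temp_C) temp_C + 273.15

#' Standardised Arrhenius temperature
#'
#' Maps an absolute temperature T to `(T - T0) / (k * T * T0)` with units of
#' inverse electronvolts, so that the activation energy is the slope of log
#' rate against this quantity and the rate intercept is anchored at `T0`.
#' The value is exactly zero at `T = T0` and strictly increasing in T.
#'
#' @param temp_K temperature(s) in kelvin; must be positive.
#' @param T0 reference temperature in kelvin (default 283.15).
#' @param k Boltzmann constant in eV K^-1 (default 8.618e-5).
#' @return standardised temperature(s), eV^-1.
#' @examples
#' arrhenius_temp(283.15) # 0
#' arrhenius_temp(celsius_to_kelvin(20)) # about 1.4
#' @export
arrhenius_temp <- function(temp_K, T0 = T_REF_K, k = BOLTZMANN_EV) {
  if (any(!is.finite(temp_K)) || any(temp_K <= 0)) {
    stop("temperatures must be positive and finite (kelvin)")
  }
  stopifnot(T0 > 0, k > 0)
  (temp_K - T0) / (k * temp_K * T0)
}

#' Metabolic-rate coefficient set
#'
#' Bundles the coefficients of the log-linear metabolic rate model
#' `ln I = ln_I0 + b ln M + E_A T_A + E_C T_C + b_C ln M T_C + E_AC T_A T_C`,
#' where `T_A`/`T_C` are standardised acute and chronic Arrhenius
#' temperatures. With `plasticity = FALSE` the three chronic-temperature
#' (plasticity) terms are forced to exactly zero and the model reduces to the
#' classical Boltzmann--Arrhenius form.
#'
#' @param ln_I0 log rate intercept (log J h^-1) at 1 mg and reference
#'   temperatures.
#' @param b allometric scaling exponent (dimensionless).
#' @param E_A acute activation energy (eV).
#' @param E_C chronic-temperature main effect (eV).
#' @param b_C mass x chronic-temperature interaction (per log-mg per eV^-1).
#' @param E_AC acute x chronic temperature interaction (eV^2 scale as fitted).
#' @param plasticity logical; whether the chronic-temperature terms are
#'   active. When `FALSE`, `E_C`, `b_C` and `E_AC` must be zero (defaulted).
#' @return an object of class `metabolic_coefficients`.
#' @seealso [default_coefficients()], [predict_ln_rate()]
#' @export
metabolic_coefficients <- function(ln_I0, b, E_A, E_C = 0, b_C = 0, E_AC = 0,
                                   plasticity = !(E_C == 0 && b_C == 0 && E_AC == 0)) {
  vals <- c(ln_I0 = ln_I0, b = b, E_A = E_A, E_C = E_C, b_C = b_C, E_AC = E_AC)
  if (any(!is.finite(vals))) stop("all coefficients must be finite")
  if (!plasticity && any(vals[c("E_C", "b_C", "E_AC")] != 0)) {
    stop("with plasticity = FALSE the terms E_C, b_C and E_AC must be exactly zero")
  }
  structure(c(as.list(vals), list(plasticity = isTRUE(plasticity))),
            class = "metabolic_coefficients")
}

#' @exportS3Method base::print
print.metabolic_coefficients <- function(x, ...) {
  cat(sprintf("Metabolic coefficients (%s plasticity)\n",
              if (x$plasticity) "with" else "without"))
  v <- unlist(x[c("ln_I0", "b", "E_A", "E_C", "b_C", "E_AC")])
  print(round(v, 4))
  invisible(x)
}

#' Packaged default coefficient sets
#'
#' Returns one of the two coefficient sets shipped with the package, estimated
#' in a published field study of metabolic plasticity in geothermal stream
#' invertebrates: `"plasticity"` is the AIC-optimal mixed model including
#' chronic-temperature terms, `"no_plasticity"` the classical alternative with
#' only mass and acute temperature. Values are used at their printed
#' precision; users fitting their own data should export coefficients from
#' [select_fixed_structure()] instead.
#'
#' @param model `"plasticity"` or `"no_plasticity"`.
#' @return a [metabolic_coefficients()] object.
#' @export
default_coefficients <- function(model = c("plasticity", "no_plasticity")) {
  model <- match.arg(model)
  file <- system.file("extdata",
                      paste0("coefficients_", model, ".json"),
                      package = "plastflux", mustWork = TRUE)
  read_coefficients(file)
}

#' Read / write a coefficient set as JSON
#'
#' The JSON layout is a flat object with fields `ln_I0`, `b`, `E_A`, `E_C`,
#' `b_C`, `E_AC` and `plasticity_enabled`.
#'
#' @param path file path.
#' @return `read_coefficients` returns a [metabolic_coefficients()] object;
#'   `write_coefficients` returns `path` invisibly.
#' @export
read_coefficients <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("ln_I0", "b", "E_A", "E_C", "b_C", "E_AC", "plasticity_enabled")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("coefficient file ", path, " lacks fields: ", paste(missing, collapse = ", "))
  }
  metabolic_coefficients(x$ln_I0, x$b, x$E_A, x$E_C, x$b_C, x$E_AC,
                         plasticity = isTRUE(x$plasticity_enabled))
}

#' @rdname read_coefficients
#' @param coeffs a [metabolic_coefficients()] object.
#' @export
write_coefficients <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "metabolic_coefficients"))
  out <- list(ln_I0 = coeffs$ln_I0, b = coeffs$b, E_A = coeffs$E_A,
              E_C = coeffs$E_C, b_C = coeffs$b_C, E_AC = coeffs$E_AC,
              plasticity_enabled = coeffs$plasticity)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Predicted log metabolic rate
#'
#' Evaluates the log-linear rate model at given log body mass and standardised
#' acute/chronic temperatures. Inputs are recycled to a common length.
#'
#' @param coeffs a [metabolic_coefficients()] object.
#' @param ln_mass natural log of dry body mass (mg).
#' @param TA standardised acute temperature, from [arrhenius_temp()].
#' @param TC standardised chronic temperature (ignored by construction when
#'   the coefficient set has no plasticity terms).
#' @return predicted ln rate (log J h^-1).
#' @export
predict_ln_rate <- function(coeffs, ln_mass, TA, TC = 0) {
  stopifnot(inherits(coeffs, "metabolic_coefficients"))
  if (any(!is.finite(ln_mass)) || any(!is.finite(TA)) || any(!is.finite(TC))) {
    stop("ln_mass, TA and TC must be finite")
  }
  coeffs$ln_I0 + coeffs$b * ln_mass + coeffs$E_A * TA + coeffs$E_C * TC +
    coeffs$b_C * ln_mass * TC + coeffs$E_AC * TA * TC
}

#' Effective allometric scaling exponent at a chronic temperature
#'
#' The mass-slope of the rate model at standardised chronic temperature `TC`,
#' `b + b_C * TC`. With a negative mass x chronic interaction the exponent
#' declines with chronic warming (small organisms elevate their metabolism
#' more than large ones after long-term exposure).
#'
#' @inheritParams predict_ln_rate
#' @return effective exponent(s).
#' @export
effective_scaling_exponent <- function(coeffs, TC) {
  stopifnot(inherits(coeffs, "metabolic_coefficients"))
  coeffs$b + coeffs$b_C * TC
}

#' Effective activation energy at a chronic temperature
#'
#' The acute-temperature slope of the rate model at standardised chronic
#' temperature `TC`, `E_A + E_AC * TC`. A positive acute x chronic interaction
#' means chronically warmed organisms are more thermally sensitive.
#'
#' @inheritParams predict_ln_rate
#' @return effective activation energy(ies), eV.
#' @export
effective_activation_energy <- function(coeffs, TC) {
  stopifnot(inherits(coeffs, "metabolic_coefficients"))
  coeffs$E_A + coeffs$E_AC * TC
}

#' Convert an oxygen-consumption rate to energetic equivalents
#'
#' Chains the standard constants: molar mass of O2 31.9988 g mol^-1, gas
#' density 1.429 g L^-1, and the oxycalorific equivalent 20.1 J per ml O2.
#' The conversion is linear: 1 umol O2 h^-1 is about 0.45 J h^-1.
#'
#' @param rate_umol_h oxygen consumption in umol O2 h^-1 (non-negative).
#' @return metabolic rate in J h^-1.
#' @export
o2_rate_to_joules <- function(rate_umol_h) {
  if (any(!is.finite(rate_umol_h)) || any(rate_umol_h < 0)) {
    stop("oxygen consumption rate must be non-negative and finite")
  }
  grams <- rate_umol_h * 31.9988e-6     # g O2 per hour
  ml <- grams / 1.429 * 1000            # ml O2 per hour (density 1.429 g/L)
  ml * 20.1                             # J per hour
}
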