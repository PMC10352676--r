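# Arrhenius temperature normalization of photosynthetic capacity.
#
# A rate measured at leaf temperature Tk is mapped to its 25 degC equivalent
# through the exponential temperature response
#
#   f(Tk) = k25 * exp(c - dHa / (R * Tk))
#
# where c is a dimensionless scaling constant, dHa the activation energy
# (kJ mol^-1) and R the molar gas constant (0.008314 kJ mol^-1 K^-1). The
# constant c is calibrated so that exp(c - dHa/(R * 298.15)) = 1, making the
# transform an identity at 25 degC.

#' Arrhenius temperature-response parameters
#'
#' Bundles the scaling constant and activation energy of the exponential
#' temperature response used to normalize photosynthetic capacities between
#' leaf temperature and 25 degrees C.
#'
#' @param c Dimensionless scaling constant.
#' @param delta_ha Activation energy, kJ mol^-1. Must be positive.
#' @return An object of class `"arrhenius_params"`.
#' @seealso [arrhenius_preset()] for the standard Vcmax and Jmax constants.
#' @export
#' @examples
#' arrhenius_params(c = 26.355, delta_ha = 65.33)
arrhenius_params <- function(c, delta_ha) {
  stop_positive(delta_ha, "delta_ha")
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c)) {
    stop("`c` must be a finite number", call. = FALSE)
  }
  structure(list(c = c, delta_ha = delta_ha, r_gas = R_GAS),
            class = "arrhenius_params")
}

#' Standard temperature-response constants for Vcmax and Jmax
#'
#' The scaling constant `c` and activation energy `delta_ha` (kJ mol^-1)
#' conventionally used to normalize the maximum carboxylation rate
#' (c = 26.355, dHa = 65.33) and the maximum electron-transport rate
#' (c = 17.710, dHa = 43.90) to 25 degrees C. Both pairs satisfy
#' `exp(c - dHa/(R * 298.15)) = 1` to better than 1e-3, so normalization is an
#' identity for curves measured at 25 degrees C.
#'
#' @param which `"vcmax"` or `"jmax"`.
#' @return An `"arrhenius_params"` object.
#' @export
#' @examples
#' arrhenius_factor(298.15, arrhenius_preset("vcmax"))  # ~1
arrhenius_preset <- function(which = c("vcmax", "jmax")) {
  which <- match.arg(which)
  switch(which,
    vcmax = arrhenius_params(c = 26.355, delta_ha = 65.33),
    jmax  = arrhenius_params(c = 17.710, delta_ha = 43.90)
  )
}

#' Arrhenius factor f(Tk)/k25
#'
#' Ratio of a capacity at leaf temperature `tk` to its value at 25 degrees C,
#' `exp(c - delta_ha / (R * tk))`. Strictly positive and strictly increasing
#' in `tk`.
#'
#' @param tk Leaf temperature, K. Must lie within \[273, 323\].
#' @param params An [arrhenius_params()] object.
#' @return Dimensionless numeric vector, same length as `tk`.
#' @export
#' @examples
#' arrhenius_factor(303.15, arrhenius_preset("vcmax"))
arrhenius_factor <- function(tk, params = arrhenius_preset("vcmax")) {
  check_tk(tk)
  stopifnot(inherits(params, "arrhenius_params"))
  exp(params$c - params$delta_ha / (params$r_gas * tk))
}

#' Normalize a rate measured at leaf temperature to 25 degrees C
#'
#' @param k_obs Rate observed at `tk` (e.g. Vcmax), umol m^-2 s^-1. Positive.
#' @param tk Leaf temperature of the observation, K.
#' @param params An [arrhenius_params()] object.
#' @return The rate at 25 degrees C, same units as `k_obs`.
#' @export
#' @examples
#' normalize_to_25(100, 303.15, arrhenius_preset("vcmax"))
normalize_to_25 <- function(k_obs, tk, params = arrhenius_preset("vcmax")) {
  stop_positive(k_obs, "k_obs")
  k_obs / arrhenius_factor(tk, params)
}

#' Project a 25-degree rate to another leaf temperature
#'
#' Inverse of [normalize_to_25()]; used by the synthetic-curve generator to
#' express ground-truth 25 degC capacities at the cuvette temperature.
#'
#' @param k25 Rate at 25 degrees C. Positive.
#' @inheritParams normalize_to_25
#' @return The rate at `tk`.
#' @export
project_from_25 <- function(k25, tk, params = arrhenius_preset("vcmax")) {
  stop_positive(k25, "k25")
  k25 * arrhenius_factor(tk, params)
}
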