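# Rubisco kinetic constants and their temperature dependence.

# Bernacchi et al. (2001) in-vivo parameterization: values at 25 degC and
# activation energies (kJ mol^-1). The de-facto standard consumed by A/Ci
# fitting tools; exposed as a constructor so alternative sets can be swapped.
.BERNACCHI <- list(
  kc25 = 404.9,  ea_kc = 79.43,   # umol mol^-1
  ko25 = 278.4,  ea_ko = 36.38,   # mmol mol^-1
  gamma_star25 = 42.75, ea_gamma_star = 37.83,  # umol mol^-1
  o = 210                          # mmol mol^-1, ambient O2
)

#' Rubisco kinetic constants
#'
#' Container for the Michaelis constants of Rubisco for CO2 (`kc`, umol mol^-1)
#' and O2 (`ko`, mmol mol^-1), the photorespiratory CO2 compensation point
#' (`gamma_star`, umol mol^-1) and the oxygen concentration (`o`, mmol mol^-1),
#' all valid at leaf temperature `tleaf_k`.
#'
#' @param kc,ko,gamma_star,o Positive kinetic constants (units above).
#' @param tleaf_k Leaf temperature the constants refer to, K.
#' @return An object of class `"kinetic_constants"`.
#' @seealso [bernacchi_kinetics()]
#' @export
kinetic_constants <- function(kc, ko, gamma_star, o = 210, tleaf_k = 298.15) {
  stop_positive(kc, "kc"); stop_positive(ko, "ko")
  stop_positive(gamma_star, "gamma_star"); stop_positive(o, "o")
  check_tk(tleaf_k)
  if (gamma_star >= kc) {
    stop("`gamma_star` must be smaller than `kc`", call. = FALSE)
  }
  structure(list(kc = kc, ko = ko, gamma_star = gamma_star, o = o,
                 tleaf_k = tleaf_k),
            class = "kinetic_constants")
}

#' Bernacchi in-vivo Rubisco kinetics at a given leaf temperature
#'
#' Returns Kc, Ko and Gamma* scaled from their 25 degC values with the
#' Bernacchi et al. (2001) activation energies:
#' `k(T) = k25 * exp(Ea * (T - 298.15) / (298.15 * R * T))`.
#'
#' @param tleaf_k Leaf temperature, K (default 298.15 = 25 degC).
#' @param o Oxygen concentration, mmol mol^-1.
#' @return A [kinetic_constants()] object at `tleaf_k`.
#' @export
#' @examples
#' bernacchi_kinetics()          # 25 degC: Kc = 404.9, Ko = 278.4, Gamma* = 42.75
#' bernacchi_kinetics(303.15)    # 30 degC
bernacchi_kinetics <- function(tleaf_k = 298.15, o = 210) {
  check_tk(tleaf_k)
  scale <- function(k25, ea) {
    k25 * exp(ea * (tleaf_k - T_REF) / (T_REF * R_GAS * tleaf_k))
  }
  b <- .BERNACCHI
  kinetic_constants(
    kc = scale(b$kc25, b$ea_kc),
    ko = scale(b$ko25, b$ea_ko),
    gamma_star = scale(b$gamma_star25, b$ea_gamma_star),
    o = o, tleaf_k = tleaf_k
  )
}

#' @export
print.kinetic_constants <- function(x, ...) {
  cat(sprintf(
    "Rubisco kinetics at %.2f K: Kc = %.1f umol/mol, Ko = %.1f mmol/mol, Gamma* = %.2f umol/mol, O = %.0f mmol/mol\n",
    x$tleaf_k, x$kc, x$ko, x$gamma_star, x$o))
  invisible(x)
}
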