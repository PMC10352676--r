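# Forward Farquhar-von Caemmerer-Berry model for C3 leaves.
#
# Net assimilation is the minimum of the Rubisco-limited rate
#   Ac = Vcmax * (Ci - Gamma*) / (Ci + Kc * (1 + O/Ko))
# and the RuBP-regeneration-limited rate
#   Aj = J * (Ci - Gamma*) / (4*Ci + 8*Gamma*)
# minus day respiration Rd. At saturating light J = Jmax.

#' FvCB net assimilation at given intercellular CO2
#'
#' Computes net CO2 assimilation `A = min(Ac, Aj) - Rd` for a C3 leaf.
#' Curves are assumed measured at saturating light, so the electron-transport
#' rate equals `jmax`; pass a light-limited `J` from [electron_transport()]
#' in its place for non-saturating conditions. TPU limitation is not modeled.
#'
#' @param vcmax Maximum carboxylation rate at the leaf temperature of
#'   `kinetics`, umol m^-2 s^-1.
#' @param jmax Maximum (or realized) electron-transport rate, umol m^-2 s^-1.
#' @param rd Day respiration, umol m^-2 s^-1 (non-negative).
#' @param ci Intercellular CO2 concentration(s), umol mol^-1. Must be > 0.
#' @param kinetics A [kinetic_constants()] object at the leaf temperature.
#' @return Net assimilation, umol m^-2 s^-1, vectorized over `ci`.
#' @export
#' @examples
#' fvcb_forward(100, 160, 1.5, ci = c(100, 250, 600))
fvcb_forward <- function(vcmax, jmax, rd, ci,
                         kinetics = bernacchi_kinetics()) {
  stop_positive(vcmax, "vcmax"); stop_positive(jmax, "jmax")
  if (!is.numeric(rd) || any(rd < 0)) stop("`rd` must be non-negative", call. = FALSE)
  if (!is.numeric(ci) || any(!is.finite(ci)) || any(ci <= 0)) {
    stop("`ci` must be positive and finite", call. = FALSE)
  }
  stopifnot(inherits(kinetics, "kinetic_constants"))
  km <- kinetics$kc * (1 + kinetics$o / kinetics$ko)
  ac <- vcmax * (ci - kinetics$gamma_star) / (ci + km)
  aj <- jmax * (ci - kinetics$gamma_star) / (4 * ci + 8 * kinetics$gamma_star)
  pmin(ac, aj) - rd
}

#' Light dependence of electron transport (non-rectangular hyperbola)
#'
#' `J` is the smaller root of
#' `theta * J^2 - (alpha * Q + Jmax) * J + alpha * Q * Jmax = 0`.
#' Provided for completeness; the curve protocol here uses saturating light
#' (PPFD 1500 umol m^-2 s^-1), under which `J` is effectively `jmax` and the
#' forward model uses `jmax` directly by default.
#'
#' @param ppfd Photosynthetic photon flux density, umol m^-2 s^-1.
#' @param jmax Maximum electron-transport rate, umol m^-2 s^-1.
#' @param theta Curvature (0, 1\]; default 0.7.
#' @param alpha Initial quantum yield of electron transport, default 0.24.
#' @return Electron-transport rate J, umol m^-2 s^-1.
#' @export
electron_transport <- function(ppfd, jmax, theta = 0.7, alpha = 0.24) {
  stop_positive(jmax, "jmax")
  if (any(ppfd < 0)) stop("`ppfd` must be non-negative", call. = FALSE)
  b <- alpha * ppfd + jmax
  (b - sqrt(b^2 - 4 * theta * alpha * ppfd * jmax)) / (2 * theta)
}
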