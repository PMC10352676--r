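# Leaf pigments, structural traits and nitrogen partitioning.

#' Constants for photosynthetic nitrogen partitioning
#'
#' Fixed constants of the nitrogen-allocation equations: the specific activity
#' of Rubisco `v_cr` (20.5 umol CO2 (g Rubisco)^-1 s^-1 at 25 degC), the
#' electron-transport capacity per unit cytochrome f `j_mc` (156 umol
#' electrons (umol cyt f)^-1 s^-1 at 25 degC), the chlorophyll binding
#' coefficient of light-harvesting complexes `c_b` (2.15 mmol Chl (g N)^-1),
#' the nitrogen-to-Rubisco mass factor 6.25 (g Rubisco (g N)^-1) and the
#' bioenergetics factor 8.06 (umol cyt f (g N)^-1). `chl_molar_mass` (901
#' g mol^-1, an a:b ~ 3:1 average of 893.5 and 907.5) converts area-based
#' chlorophyll to the molar per-dry-mass basis the light-harvesting equation
#' needs.
#'
#' @param v_cr,j_mc,c_b,rubisco_n_factor,bioenergetics_factor,chl_molar_mass
#'   Override individual constants (rarely needed; the 6.25 and 8.06 factors
#'   are part of the equations themselves).
#' @return A named list of class `"allocation_constants"`.
#' @export
allocation_constants <- function(v_cr = 20.5, j_mc = 156, c_b = 2.15,
                                 rubisco_n_factor = 6.25,
                                 bioenergetics_factor = 8.06,
                                 chl_molar_mass = 901) {
  out <- list(v_cr = v_cr, j_mc = j_mc, c_b = c_b,
              rubisco_n_factor = rubisco_n_factor,
              bioenergetics_factor = bioenergetics_factor,
              chl_molar_mass = chl_molar_mass)
  for (nm in names(out)) stop_positive(out[[nm]], nm)
  structure(out, class = "allocation_constants")
}

# 95%-ethanol spectrophotometric coefficient set for absorbances read at
# 665, 649 and 470 nm (concentrations in ug mL^-1):
#   Chl a = 13.95 A665 - 6.88 A649
#   Chl b = 24.96 A649 - 7.32 A665
#   Car   = (1000 A470 - 2.05 Chl a - 114.8 Chl b) / 245
# This set is the single source of truth for the pigment oracle used in the
# tests; alternative sets can be supplied via `coefficients`.
.PIGMENT_COEF_ETHANOL95 <- list(
  chl_a = c(a665 = 13.95, a649 = -6.88),
  chl_b = c(a665 = -7.32, a649 = 24.96),
  car   = c(a470 = 1000, chl_a = -2.05, chl_b = -114.8, denom = 245)
)

#' Leaf pigment contents from spectrophotometric absorbances
#'
#' Converts 95%-ethanol extract absorbances at 665, 649 and 470 nm into
#' chlorophyll a, b, total chlorophyll and carotenoid concentrations
#' (ug mL^-1), then scales by extract volume, dilution and leaf area to
#' area-based contents (ug cm^-2). Negative computed concentrations are
#' below-detection artifacts; they are clipped to zero with a warning and
#' the number of clipped values is recorded in the `"n_clipped"` attribute.
#'
#' @param a665,a649,a470 Absorbances (dimensionless, >= 0); vectorized.
#' @param volume_ml Extract volume, mL.
#' @param leaf_area_cm2 Leaf area extracted, cm^2.
#' @param dilution Dilution factor applied before reading, default 1.
#' @param coefficients Coefficient set; default the 95%-ethanol set above.
#' @return Data frame with `chl_a_ug_ml`, `chl_b_ug_ml`, `car_ug_ml`,
#'   `chl_area_ug_cm2`, `car_area_ug_cm2`.
#' @export
#' @examples
#' pigments_from_absorbance(0.50, 0.20, 0.30, volume_ml = 10, leaf_area_cm2 = 5)
pigments_from_absorbance <- function(a665, a649, a470, volume_ml,
                                     leaf_area_cm2, dilution = 1,
                                     coefficients = .PIGMENT_COEF_ETHANOL95) {
  if (any(c(a665, a649, a470) < 0)) stop("absorbances must be >= 0", call. = FALSE)
  stop_positive(volume_ml, "volume_ml")
  stop_positive(leaf_area_cm2, "leaf_area_cm2")
  stop_positive(dilution, "dilution")

  k <- coefficients
  chl_a <- k$chl_a[["a665"]] * a665 + k$chl_a[["a649"]] * a649
  chl_b <- k$chl_b[["a665"]] * a665 + k$chl_b[["a649"]] * a649
  car <- (k$car[["a470"]] * a470 + k$car[["chl_a"]] * chl_a +
            k$car[["chl_b"]] * chl_b) / k$car[["denom"]]

  n_clipped <- sum(chl_a < 0) + sum(chl_b < 0) + sum(car < 0)
  if (n_clipped > 0) {
    warning(sprintf("%d pigment concentration(s) below detection; clipped to 0",
                    n_clipped), call. = FALSE)
    chl_a <- pmax(chl_a, 0); chl_b <- pmax(chl_b, 0); car <- pmax(car, 0)
  }

  per_area <- volume_ml * dilution / leaf_area_cm2  # ug/mL -> ug/cm^2
  out <- data.frame(
    chl_a_ug_ml = chl_a, chl_b_ug_ml = chl_b, car_ug_ml = car,
    chl_area_ug_cm2 = (chl_a + chl_b) * per_area,
    car_area_ug_cm2 = car * per_area
  )
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Structural leaf traits from dry mass, area and mass-based nitrogen
#'
#' @param dry_mass_g Leaf dry mass, g.
#' @param leaf_area_cm2 Leaf area, cm^2.
#' @param n_mass_g_g Nitrogen content per dry mass, g g^-1.
#' @return Data frame with `sla_cm2_g` (specific leaf area), `m_a_g_m2`
#'   (dry mass per area; `sla * m_a = 1e4` in these units), `n_area_g_m2`
#'   and `n_area_ug_cm2` (1 g m^-2 = 100 ug cm^-2).
#' @export
#' @examples
#' structural_traits(0.05, 10, 0.04)  # M_A = 50 g m^-2, N_area = 2 g m^-2
structural_traits <- function(dry_mass_g, leaf_area_cm2, n_mass_g_g) {
  stop_positive(dry_mass_g, "dry_mass_g")
  stop_positive(leaf_area_cm2, "leaf_area_cm2")
  stop_positive(n_mass_g_g, "n_mass_g_g")
  sla <- leaf_area_cm2 / dry_mass_g            # cm^2 g^-1
  m_a <- 1e4 * dry_mass_g / leaf_area_cm2      # g m^-2
  n_area <- m_a * n_mass_g_g                   # g m^-2
  data.frame(sla_cm2_g = sla, m_a_g_m2 = m_a,
             n_area_g_m2 = n_area, n_area_ug_cm2 = 100 * n_area)
}

#' Fractions of leaf nitrogen in photosynthetic pools
#'
#' Partitions leaf nitrogen into the fraction bound in active Rubisco
#' (`p_r`), in bioenergetics (cytochrome f) pools (`p_b`) and in
#' light-harvesting chlorophyll-protein complexes (`p_l`):
#'
#' \deqn{P_R = Vcmax / (6.25 \cdot V_{cr} \cdot M_A \cdot N_{mass})}
#' \deqn{P_B = Jmax / (8.06 \cdot J_{mc} \cdot M_A \cdot N_{mass})}
#' \deqn{P_L = C_c / (C_B \cdot N_{mass})}
#'
#' where \eqn{C_c} is chlorophyll per dry mass in mmol g^-1, derived here from
#' area-based chlorophyll via \eqn{M_A} and the mean chlorophyll molar mass.
#' Because \eqn{V_{cr}} and \eqn{J_{mc}} are 25 degC activities, pass
#' 25 degC-normalized rates (the default throughout the pipeline); rates at
#' leaf temperature may be used deliberately when temperatures are near 25 degC.
#'
#' @param vcmax,jmax Carboxylation / electron-transport capacity,
#'   umol m^-2 s^-1 (normally `vcmax25`, `jmax25`).
#' @param chl_area_ug_cm2 Leaf chlorophyll content, ug cm^-2.
#' @param m_a_g_m2 Leaf dry mass per area, g m^-2.
#' @param n_mass_g_g Nitrogen per dry mass, g g^-1.
#' @param leaf_id Optional identifier(s) used in warnings.
#' @param constants An [allocation_constants()] object.
#' @return Data frame with `p_r`, `p_b`, `p_l` (dimensionless fractions) and
#'   `cc_mmol_g` (chlorophyll per dry mass). Fractions outside (0, 1) signal
#'   implausible inputs and raise a warning naming the leaf, not an error.
#' @export
#' @examples
#' allocation_fractions(100, 160, chl_area_ug_cm2 = 72,
#'                      m_a_g_m2 = 100, n_mass_g_g = 0.04)
allocation_fractions <- function(vcmax, jmax, chl_area_ug_cm2, m_a_g_m2,
                                 n_mass_g_g, leaf_id = NULL,
                                 constants = allocation_constants()) {
  stop_positive(vcmax, "vcmax"); stop_positive(jmax, "jmax")
  stop_positive(chl_area_ug_cm2, "chl_area_ug_cm2")
  stop_positive(m_a_g_m2, "m_a_g_m2"); stop_positive(n_mass_g_g, "n_mass_g_g")
  k <- constants
  # ug cm^-2 -> g m^-2 (x0.01) -> g (g dry mass)^-1 (/M_A) -> mmol g^-1
  cc <- 0.01 * chl_area_ug_cm2 / m_a_g_m2 / k$chl_molar_mass * 1000
  p_r <- vcmax / (k$rubisco_n_factor * k$v_cr * m_a_g_m2 * n_mass_g_g)
  p_b <- jmax / (k$bioenergetics_factor * k$j_mc * m_a_g_m2 * n_mass_g_g)
  p_l <- cc / (k$c_b * n_mass_g_g)
  bad <- which(p_r <= 0 | p_r >= 1 | p_b <= 0 | p_b >= 1 | p_l <= 0 | p_l >= 1)
  if (length(bad) > 0) {
    ids <- if (is.null(leaf_id)) paste("row", bad) else leaf_id[bad]
    warning(sprintf("allocation fraction outside (0, 1) for: %s",
                    paste(ids, collapse = ", ")), call. = FALSE)
  }
  data.frame(p_r = p_r, p_b = p_b, p_l = p_l, cc_mmol_g = cc)
}

#' Per-DOY chlorophyll-to-nitrogen ratio series
#'
#' Mean of the leaf-level `chl_area / n_area` ratio per day of year, both
#' contents in ug cm^-2. The ratio tracks the share of leaf nitrogen invested
#' in chlorophyll-bearing complexes; in winter wheat it rises early in the
#' season and plateaus near 0.36.
#'
#' @param samples Data frame with columns `doy`, `chl_area_ug_cm2`,
#'   `n_area_ug_cm2`.
#' @return Data frame with `doy`, `chl_to_n`, `n_leaves`.
#' @export
chl_to_n_ratio <- function(samples) {
  stopifnot(is.data.frame(samples), nrow(samples) > 0,
            all(c("doy", "chl_area_ug_cm2", "n_area_ug_cm2") %in% names(samples)))
  if (any(samples$n_area_ug_cm2 == 0)) {
    stop("n_area is zero for at least one leaf; ratio undefined", call. = FALSE)
  }
  ratio <- samples$chl_area_ug_cm2 / samples$n_area_ug_cm2
  agg <- stats::aggregate(ratio, by = list(doy = samples$doy), FUN = mean)
  cnt <- stats::aggregate(ratio, by = list(doy = samples$doy), FUN = length)
  data.frame(doy = agg$doy, chl_to_n = agg$x, n_leaves = cnt$x)
}
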