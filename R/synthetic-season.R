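# Synthetic leaf-trait season with known ground truth.
#
# Every trait mean follows a single-peaked piecewise-linear trajectory
# (baseline at the first DOY, peak at the flowering peak DOY, end at the last
# DOY); SLA declines monotonically. Leaf-level values add multiplicative
# lognormal noise at a per-trait coefficient of variation, partially coupled
# across traits through one shared "leaf vigor" factor z: on the log scale
# each trait deviates by rho * z + sqrt(1 - rho^2) * eps. Vcmax25 carries
# rho = 1, so rho of another trait is (approximately) the within-day noise
# correlation between that trait and Vcmax25. Chlorophyll is generated from
# the nitrogen trajectory through a Chl/N ratio curve that rises early and
# plateaus from DOY 105 on, reproducing the observed stable nitrogen
# investment in chlorophyll.

#' Trait-trajectory configuration for the season generator
#'
#' @param traits Named list of per-trait anchors. Each element has `baseline`
#'   (value at the first DOY), `peak` (value at `peak_doy`; `NA` for a
#'   monotone trait such as SLA), `end` (value at the last DOY), `cv`
#'   (within-DOY coefficient of variation, >= 0) and `coupling` (correlation
#'   of the trait's log-noise with the shared leaf-vigor factor, in \[-1, 1\]).
#'   Defaults (units: capacities umol m^-2 s^-1, contents ug cm^-2, SLA
#'   cm^2 g^-1) anchor Vcmax25 at 82.38 / 133.46 / 46.02 and the other traits
#'   at values consistent with the reported seasonal percent changes; the
#'   CV/coupling defaults are calibrated so the season-level correlations of
#'   Vcmax25 with Chl, Car and N are about 0.83, 0.68 and 0.60.
#' @param peak_doy DOY of the flowering peak, default 126.
#' @param chl_mode `"ratio"` (default): the chlorophyll mean at DOY d is
#'   `ratio(d) * N_mean(d)` with `ratio` interpolating `chl_ratio_start` at
#'   the first knot DOY through `chl_to_n_plateau` from DOY 105 onward.
#'   `"anchors"`: chlorophyll uses its own `traits$chl_area` anchors like any
#'   other trait.
#' @param chl_to_n_plateau Plateau of the Chl/N ratio (both ug cm^-2),
#'   default 0.36.
#' @param chl_ratio_knots Data frame `doy`, `ratio` of pre-plateau knots;
#'   default ratio 0.23 at DOY 92 and 0.32 at DOY 96.
#' @param rd_fraction Ground-truth Rd25 as a fraction of Vcmax25, default 0.015.
#' @param jmax_ratio_bounds Allowed Jmax25/Vcmax25 range; leaf values are
#'   clamped inside it. Default `c(1.2, 2.2)`.
#' @param tleaf_k Cuvette leaf temperature, K (default 298.15; the protocol
#'   controls the cuvette at 25 degC).
#' @param rng_seed Master seed; per-leaf streams are derived by stable
#'   hashing of (seed, leaf_id), so a season is reproducible leaf by leaf.
#' @return A list of class `"trait_config"`.
#' @export
trait_config <- function(traits = NULL,
                         peak_doy = 126,
                         chl_mode = c("ratio", "anchors"),
                         chl_to_n_plateau = 0.36,
                         chl_ratio_knots = data.frame(doy = c(92, 96),
                                                      ratio = c(0.23, 0.32)),
                         rd_fraction = 0.015,
                         jmax_ratio_bounds = c(1.2, 2.2),
                         tleaf_k = 298.15,
                         rng_seed = 1L) {
  defaults <- list(
    vcmax25  = list(baseline = 82.38, peak = 133.46, end = 46.02,
                    cv = 0.12, coupling = 1.00),
    jmax25   = list(baseline = 137.6, peak = 222.9, end = 76.9,
                    cv = 0.10, coupling = 0.90),
    n_area   = list(baseline = 200, peak = 252, end = 137.7,
                    cv = 0.23, coupling = 0.22),
    chl_area = list(baseline = 46, peak = 90.7, end = 49.6,
                    cv = 0.18, coupling = 0.85),
    car_area = list(baseline = 12, peak = 17.8, end = 13.4,
                    cv = 0.11, coupling = 0.70),
    sla      = list(baseline = 230, peak = NA, end = 170,
                    cv = 0.10, coupling = 0.05)
  )
  if (!is.null(traits)) {
    for (nm in names(traits)) {
      if (!nm %in% names(defaults)) stop(sprintf("unknown trait '%s'", nm), call. = FALSE)
      defaults[[nm]] <- utils::modifyList(defaults[[nm]], traits[[nm]])
    }
  }
  for (nm in names(defaults)) {
    tr <- defaults[[nm]]
    vals <- c(tr$baseline, tr$end, if (!is.na(tr$peak)) tr$peak)
    if (any(vals <= 0)) stop(sprintf("trait '%s' has non-positive anchors", nm), call. = FALSE)
    if (tr$cv < 0) stop(sprintf("trait '%s' has negative CV", nm), call. = FALSE)
    if (abs(tr$coupling) > 1) stop(sprintf("trait '%s' coupling outside [-1, 1]", nm), call. = FALSE)
  }
  stop_positive(chl_to_n_plateau, "chl_to_n_plateau")
  stop_positive(rd_fraction, "rd_fraction")
  check_tk(tleaf_k)
  structure(list(traits = defaults, peak_doy = peak_doy,
                 chl_mode = match.arg(chl_mode),
                 chl_to_n_plateau = chl_to_n_plateau,
                 chl_ratio_knots = chl_ratio_knots,
                 rd_fraction = rd_fraction,
                 jmax_ratio_bounds = jmax_ratio_bounds,
                 tleaf_k = tleaf_k,
                 rng_seed = as.integer(rng_seed)),
            class = "trait_config")
}

#' Trend-free configuration for coupling-ordering experiments
#'
#' In a seasonal configuration every trait shares the phenological trend, so
#' season-level correlations mix trajectory amplitude with leaf-level
#' coupling and the coupling ordering is confounded. This probe holds every
#' trait mean flat at its flowering-stage level and drives all leaf-to-leaf
#' variation through the shared vigor factor, so the correlation of each
#' trait with Vcmax25 equals its coupling by construction. Used to verify
#' that an imposed coupling ordering (default Chl 0.95 > Car 0.80 > N 0.60 >
#' SLA 0.00) propagates through curve fitting into the regression-R2 and
#' random-forest importance rankings.
#'
#' @param couplings Named vector of couplings for `chl_area`, `car_area`,
#'   `n_area`, `sla`.
#' @param cv Common within-season coefficient of variation, default 0.35.
#' @param rng_seed Master seed.
#' @return A [trait_config()] object with flat trajectories.
#' @export
coupling_probe_config <- function(couplings = c(chl_area = 0.95,
                                                car_area = 0.80,
                                                n_area = 0.60, sla = 0.00),
                                  cv = 0.35, rng_seed = 1L) {
  flat <- function(v, rho, cvv = cv) {
    list(baseline = v, peak = v, end = v, cv = cvv, coupling = rho)
  }
  trait_config(traits = list(
    vcmax25 = flat(100, 1.0),
    jmax25 = flat(167, 0.9, 0.2),
    chl_area = flat(80, couplings[["chl_area"]]),
    car_area = flat(16, couplings[["car_area"]]),
    n_area = flat(230, couplings[["n_area"]]),
    sla = list(baseline = 200, peak = NA, end = 200, cv = cv,
               coupling = couplings[["sla"]])
  ), chl_mode = "anchors", rng_seed = rng_seed)
}

# Single-peaked (or monotone, when peak is NA) piecewise-linear trajectory.
trait_trajectory <- function(doy, anchors, first_doy, peak_doy, last_doy) {
  if (is.na(anchors$peak)) {
    xs <- c(first_doy, last_doy); ys <- c(anchors$baseline, anchors$end)
  } else {
    if (peak_doy <= first_doy || peak_doy >= last_doy) {
      stop("`peak_doy` must lie strictly inside the season", call. = FALSE)
    }
    xs <- c(first_doy, peak_doy, last_doy)
    ys <- c(anchors$baseline, anchors$peak, anchors$end)
  }
  stats::approx(xs, ys, xout = doy, rule = 2)$y
}

chl_ratio_curve <- function(doy, cfg) {
  kn <- cfg$chl_ratio_knots
  xs <- c(kn$doy, 105)
  ys <- c(kn$ratio, cfg$chl_to_n_plateau)
  ord <- order(xs)
  stats::approx(xs[ord], ys[ord], xout = pmin(doy, 105), rule = 2)$y
}

# Mean-one lognormal multiplier with exact coefficient of variation `cv`,
# driven by the standard-normal deviate u.
log_noise <- function(u, cv) {
  if (cv == 0) return(rep(1, length(u)))
  sigma <- sqrt(log(1 + cv^2))
  exp(sigma * u - sigma^2 / 2)
}

#' Simulate one field season of leaf-trait ground truths
#'
#' Draws one leaf record per design slot with known Vcmax25, Jmax25, Rd25,
#' N_area, Chl_area, Car_area and SLA; see the file-level description for the
#' trajectory and noise model. Deterministic given `cfg$rng_seed`, and
#' independent of the caller's RNG state.
#'
#' @param design A [season_design()] data frame.
#' @param cfg A [trait_config()] object.
#' @return Data frame with one row per leaf: `leaf_id`, `doy`, `stage`,
#'   `vcmax25`, `jmax25`, `rd25` (umol m^-2 s^-1), `n_area_ug_cm2`,
#'   `chl_area_ug_cm2`, `car_area_ug_cm2` (ug cm^-2), `sla_cm2_g`,
#'   `m_a_g_m2`, `n_mass_g_g`, `tleaf_k`.
#' @export
#' @examples
#' season <- simulate_season(build_default_design(), trait_config(rng_seed = 7))
#' nrow(season)  # 29
simulate_season <- function(design = build_default_design(),
                            cfg = trait_config()) {
  stopifnot(inherits(design, "season_design"), inherits(cfg, "trait_config"))
  first_doy <- min(design$doy); last_doy <- max(design$doy)
  trait_names <- names(cfg$traits)

  rows <- vector("list", sum(design$n))
  k <- 0L
  with_preserved_seed({
    for (i in seq_len(nrow(design))) {
      doy <- design$doy[i]
      means <- vapply(trait_names, function(nm) {
        trait_trajectory(doy, cfg$traits[[nm]], first_doy, cfg$peak_doy, last_doy)
      }, numeric(1))
      if (cfg$chl_mode == "ratio") {
        means[["chl_area"]] <- chl_ratio_curve(doy, cfg) * means[["n_area"]]
      }
      for (j in seq_len(design$n[i])) {
        leaf_id <- sprintf("D%03d_L%d", doy, j)
        set.seed(hash_seed(cfg$rng_seed, leaf_id, "traits"))
        z <- stats::rnorm(1)
        vals <- vapply(trait_names, function(nm) {
          tr <- cfg$traits[[nm]]
          u <- tr$coupling * z + sqrt(1 - tr$coupling^2) * stats::rnorm(1)
          means[[nm]] * log_noise(u, tr$cv)
        }, numeric(1))
        # keep the Jmax/Vcmax ratio inside its physiological band
        ratio <- vals[["jmax25"]] / vals[["vcmax25"]]
        ratio <- min(max(ratio, cfg$jmax_ratio_bounds[1]), cfg$jmax_ratio_bounds[2])
        vals[["jmax25"]] <- ratio * vals[["vcmax25"]]
        m_a <- 1e4 / vals[["sla"]]
        k <- k + 1L
        rows[[k]] <- data.frame(
          leaf_id = leaf_id, doy = doy, stage = design$stage[i],
          vcmax25 = vals[["vcmax25"]], jmax25 = vals[["jmax25"]],
          rd25 = cfg$rd_fraction * vals[["vcmax25"]],
          n_area_ug_cm2 = vals[["n_area"]],
          chl_area_ug_cm2 = vals[["chl_area"]],
          car_area_ug_cm2 = vals[["car_area"]],
          sla_cm2_g = vals[["sla"]],
          m_a_g_m2 = m_a,
          n_mass_g_g = 0.01 * vals[["n_area"]] / m_a,
          tleaf_k = cfg$tleaf_k,
          stringsAsFactors = FALSE
        )
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
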