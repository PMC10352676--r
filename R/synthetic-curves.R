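# Synthetic gas-exchange CO2-response curves from known leaf truths.

#' Default Ca setpoint protocol
#'
#' The measurement sequence of ambient CO2 setpoints, including the repeated
#' 380 step used as a stability check: 380, 300, 200, 100, 50, 380, 600, 800,
#' 1000, 1200 umol mol^-1.
#'
#' @return Numeric vector of Ca setpoints.
#' @export
default_protocol <- function() {
  c(380, 300, 200, 100, 50, 380, 600, 800, 1000, 1200)
}

#' Simulate one A/Ci curve for a leaf with known parameters
#'
#' For each Ca setpoint the intercellular CO2 is derived with a constant
#' Ci/Ca operating ratio (stomatal behavior is not modeled; the fitter
#' consumes Ci directly, so any fixed coupling rule suffices), net
#' assimilation is computed from the forward FvCB model at the leaf
#' temperature (capacities projected from 25 degC with the Arrhenius
#' response), and Gaussian instrument noise of standard deviation `noise_sd`
#' is added. The protocol order, including the repeated 380 step, is
#' preserved.
#'
#' @param truth One-row data frame or list with `leaf_id`, `doy`, `vcmax25`,
#'   `jmax25`, `rd25`, `tleaf_k` (and optionally `stage`).
#' @param protocol Ca setpoints, umol mol^-1; default [default_protocol()].
#' @param noise_sd Gaussian noise on A, umol m^-2 s^-1 (default 0.3, a
#'   typical open-path IRGA repeatability).
#' @param seed Master seed; the curve's stream is derived by hashing
#'   (seed, leaf_id, "curve").
#' @param ci_ca_ratio Constant Ci/Ca operating ratio, default 0.7.
#' @param ppfd PPFD recorded on the curve, umol m^-2 s^-1 (default 1500,
#'   saturating).
#' @return Data frame with one row per protocol step: `leaf_id`, `doy`,
#'   `stage`, `step_index`, `Ca_umol_mol`, `Ci_umol_mol`, `A_umol_m2_s`,
#'   `Tleaf_K`, `PPFD_umol_m2_s`.
#' @export
#' @examples
#' truth <- list(leaf_id = "demo", doy = 126, vcmax25 = 100, jmax25 = 160,
#'               rd25 = 1.5, tleaf_k = 298.15)
#' simulate_aci_curve(truth, noise_sd = 0, seed = 1)
simulate_aci_curve <- function(truth, protocol = default_protocol(),
                               noise_sd = 0.3, seed = 1L,
                               ci_ca_ratio = 0.7, ppfd = 1500) {
  stop_positive(protocol, "protocol")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  stop_positive(ci_ca_ratio, "ci_ca_ratio")
  tr <- as.list(truth)
  for (nm in c("vcmax25", "jmax25", "rd25")) stop_positive(tr[[nm]], nm)
  tleaf <- tr$tleaf_k %||% T_REF
  check_tk(tleaf)

  vcmax_tl <- project_from_25(tr$vcmax25, tleaf, arrhenius_preset("vcmax"))
  jmax_tl <- project_from_25(tr$jmax25, tleaf, arrhenius_preset("jmax"))
  kin <- bernacchi_kinetics(tleaf)
  ci <- ci_ca_ratio * protocol
  a <- fvcb_forward(vcmax_tl, jmax_tl, tr$rd25, ci, kin)
  if (noise_sd > 0) {
    with_preserved_seed({
      set.seed(hash_seed(seed, tr$leaf_id %||% "leaf", "curve"))
      a <- a + stats::rnorm(length(a), sd = noise_sd)
    })
  }
  data.frame(
    leaf_id = tr$leaf_id %||% "leaf", doy = tr$doy %||% NA_integer_,
    stage = tr$stage %||% NA_character_,
    step_index = seq_along(protocol),
    Ca_umol_mol = protocol, Ci_umol_mol = ci, A_umol_m2_s = a,
    Tleaf_K = tleaf, PPFD_umol_m2_s = ppfd,
    stringsAsFactors = FALSE
  )
}

#' Simulate curves for every leaf of a season
#'
#' @param truths Season data frame from [simulate_season()].
#' @param seed Master seed shared by all curves (per-leaf streams are
#'   derived from it).
#' @inheritParams simulate_aci_curve
#' @return Row-bound curve data frame (one block per leaf, protocol order
#'   preserved within each block).
#' @export
simulate_curves <- function(truths, protocol = default_protocol(),
                            noise_sd = 0.3, seed = 1L, ci_ca_ratio = 0.7,
                            ppfd = 1500) {
  stopifnot(is.data.frame(truths), nrow(truths) > 0)
  out <- lapply(seq_len(nrow(truths)), function(i) {
    simulate_aci_curve(truths[i, ], protocol = protocol, noise_sd = noise_sd,
                       seed = seed, ci_ca_ratio = ci_ca_ratio, ppfd = ppfd)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
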