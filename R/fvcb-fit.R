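# Estimation of Vcmax, Jmax and Rd from a measured A/Ci curve.
#
# The fitter makes the limitation partition explicit: for each candidate
# transition Ci taken from the observed Ci values, points at or below the
# transition are treated as Rubisco-limited and points above as
# RuBP-regeneration-limited. Conditional on a partition the model
#
#   A_i = Vcmax * x_i * [rubisco] + Jmax * y_i * [rubp] - Rd
#   x_i = (Ci - Gamma*) / (Ci + Kc (1 + O/Ko)),  y_i = (Ci - Gamma*) / (4 Ci + 8 Gamma*)
#
# is linear in (Vcmax, Jmax, Rd), so each candidate is solved by ordinary
# least squares (with a bounded refit when Rd leaves its physical range).
# The partition with the smallest total SSE wins; ties go to the larger
# Rubisco-limited segment, which keeps the search deterministic.
#
# A threshold partition cannot represent one feature of the min rule: below
# the compensation point Gamma* the RuBP expression is again the smaller
# rate, so the lowest-Ci step of the protocol is not Rubisco-limited. The
# winning threshold fit is therefore refined by min-consistency iteration:
# relabel each point to whichever fitted rate (Ac or Aj) is smaller, refit,
# and repeat until the labels are stable. Each sweep cannot increase the SSE
# of the actual min-model, and on noise-free data the iteration lands on the
# exact generating parameters.

#' Options controlling [fit_aci()]
#'
#' @param use_duplicate_380 Keep the repeated Ca = 380 stability-check step in
#'   the fit (default `FALSE`: only the first 380 step is used).
#' @param trim_tpu Drop high-CO2 points (Ca >= 1000) whose assimilation falls
#'   below the preceding lower-Ci point, a symptom of triose-phosphate
#'   limitation which the model does not represent. Default `FALSE`.
#' @param rd_bounds Physical bounds for fitted day respiration,
#'   umol m^-2 s^-1. Default `c(0, 5)`.
#' @param min_rubisco_points,min_rubp_points Minimum points required in the
#'   Rubisco-limited / RuBP-limited segments of a candidate partition.
#' @param column_aliases Optional named character vector mapping canonical
#'   column names (`Ca_umol_mol`, `Ci_umol_mol`, `A_umol_m2_s`, `Tleaf_K`,
#'   `PPFD_umol_m2_s`) to the names used in the input table, e.g. a
#'   Li-6400-style export: `c(Ci_umol_mol = "Ci", A_umol_m2_s = "Photo",
#'   Ca_umol_mol = "CO2R", Tleaf_K = "Tleaf")`. Celsius leaf temperatures
#'   (values < 200) are converted to kelvin.
#' @return A list of class `"aci_fit_options"`.
#' @export
aci_fit_options <- function(use_duplicate_380 = FALSE,
                            trim_tpu = FALSE,
                            rd_bounds = c(0, 5),
                            min_rubisco_points = 3L,
                            min_rubp_points = 2L,
                            column_aliases = NULL) {
  stopifnot(length(rd_bounds) == 2L, rd_bounds[1] >= 0,
            rd_bounds[2] > rd_bounds[1],
            min_rubisco_points >= 2L, min_rubp_points >= 1L)
  structure(list(use_duplicate_380 = isTRUE(use_duplicate_380),
                 trim_tpu = isTRUE(trim_tpu),
                 rd_bounds = as.numeric(rd_bounds),
                 min_rubisco_points = as.integer(min_rubisco_points),
                 min_rubp_points = as.integer(min_rubp_points),
                 column_aliases = column_aliases),
            class = "aci_fit_options")
}

# Rename user columns to the canonical curve schema.
normalize_curve_columns <- function(curve, aliases = NULL) {
  if (!is.null(aliases)) {
    for (canon in names(aliases)) {
      src <- aliases[[canon]]
      if (src %in% names(curve) && !(canon %in% names(curve))) {
        names(curve)[names(curve) == src] <- canon
      }
    }
  }
  if ("Tleaf_K" %in% names(curve)) {
    celsius <- is.finite(curve$Tleaf_K) & curve$Tleaf_K < 200
    curve$Tleaf_K[celsius] <- curve$Tleaf_K[celsius] + 273.15
  }
  curve
}

fit_partition <- function(A, x, y, rub, rd_bounds) {
  X <- cbind(vc = ifelse(rub, x, 0), j = ifelse(rub, 0, y), rd = -1)
  co <- tryCatch(stats::lm.fit(X, A)$coefficients, error = function(e) rep(NA_real_, 3))
  in_bounds <- all(is.finite(co)) && co[1] > 0 && co[2] > 0 &&
    co[3] >= rd_bounds[1] && co[3] <= rd_bounds[2]
  converged <- TRUE
  if (!in_bounds) {
    start <- co
    start[!is.finite(start)] <- c(50, 100, 1)[!is.finite(start)]
    start <- pmin(pmax(start, c(1e-3, 1e-3, rd_bounds[1])),
                  c(1999, 1999, rd_bounds[2]))
    opt <- stats::optim(start, function(p) sum((X %*% p - A)^2),
                        method = "L-BFGS-B",
                        lower = c(1e-6, 1e-6, rd_bounds[1]),
                        upper = c(2000, 2000, rd_bounds[2]))
    co <- opt$par
    converged <- opt$convergence == 0
  }
  list(vcmax = unname(co[1]), jmax = unname(co[2]), rd = unname(co[3]),
       sse = sum((X %*% co - A)^2), fitted = drop(X %*% co),
       converged = converged)
}

#' Fit the FvCB model to one A/Ci curve
#'
#' Estimates Vcmax, Jmax (both at the curve's leaf temperature) and Rd by an
#' exhaustive search over limitation-transition candidates; see the file-level
#' description for the algorithm. Rates can subsequently be normalized to
#' 25 degrees C with [normalize_to_25()].
#'
#' @param curve Data frame with one row per measurement step and (at least)
#'   columns `Ci_umol_mol` and `A_umol_m2_s`; `Ca_umol_mol` and `Tleaf_K` are
#'   used when present (duplicate-380 handling, kinetics temperature).
#'   Alternative column names are handled via `options$column_aliases`.
#' @param kinetics A [kinetic_constants()] object; defaults to
#'   [bernacchi_kinetics()] evaluated at the curve's mean leaf temperature.
#' @param options An [aci_fit_options()] object.
#' @return An object of class `"fvcb_fit"`: a list with elements `vcmax`,
#'   `jmax`, `rd` (umol m^-2 s^-1, at leaf temperature), `transition_ci`,
#'   `limitation` (per used point, `"rubisco"` or `"rubp"`), `rmse`,
#'   `n_points_used`, `converged`, `tleaf_k`, `leaf_id`, `doy`, and the
#'   per-point `fitted` values.
#' @export
#' @examples
#' truth <- list(leaf_id = "demo", doy = 126, stage = "Flowering",
#'               vcmax25 = 100, jmax25 = 160, rd25 = 1.5, tleaf_k = 298.15)
#' crv <- simulate_aci_curve(truth, noise_sd = 0, seed = 1)
#' fit_aci(crv)
fit_aci <- function(curve, kinetics = NULL, options = aci_fit_options()) {
  stopifnot(is.data.frame(curve), inherits(options, "aci_fit_options"))
  curve <- normalize_curve_columns(curve, options$column_aliases)
  leaf_id <- if ("leaf_id" %in% names(curve)) as.character(curve$leaf_id[1]) else "<unnamed>"
  doy <- if ("doy" %in% names(curve)) curve$doy[1] else NA_integer_

  need <- c("Ci_umol_mol", "A_umol_m2_s")
  if (!all(need %in% names(curve))) {
    stop(sprintf("curve '%s' lacks required columns: %s", leaf_id,
                 paste(setdiff(need, names(curve)), collapse = ", ")),
         call. = FALSE)
  }
  if (any(curve$Ci_umol_mol <= 0)) {
    stop(sprintf("curve '%s' has non-positive Ci", leaf_id), call. = FALSE)
  }

  keep <- rep(TRUE, nrow(curve))
  if (!options$use_duplicate_380 && "Ca_umol_mol" %in% names(curve)) {
    at380 <- which(abs(curve$Ca_umol_mol - 380) < 1)
    if (length(at380) > 1L) keep[at380[-1]] <- FALSE
  }
  if (options$trim_tpu && "Ca_umol_mol" %in% names(curve)) {
    ord <- order(curve$Ci_umol_mol)
    a_ord <- curve$A_umol_m2_s[ord]
    high <- curve$Ca_umol_mol[ord] >= 1000
    declining <- c(FALSE, diff(a_ord) < 0) & high
    keep[ord[declining]] <- FALSE
  }
  cv <- curve[keep, , drop = FALSE]
  if (nrow(cv) < 5L) {
    stop(sprintf("curve '%s' has %d usable points; at least 5 are required",
                 leaf_id, nrow(cv)), call. = FALSE)
  }

  tleaf <- if ("Tleaf_K" %in% names(cv)) mean(cv$Tleaf_K) else T_REF
  check_tk(tleaf)
  if (is.null(kinetics)) kinetics <- bernacchi_kinetics(tleaf)

  ci <- cv$Ci_umol_mol
  A <- cv$A_umol_m2_s
  km <- kinetics$kc * (1 + kinetics$o / kinetics$ko)
  gs <- kinetics$gamma_star
  x <- (ci - gs) / (ci + km)
  y <- (ci - gs) / (4 * ci + 8 * gs)

  cand <- sort(unique(ci))
  n_below <- vapply(cand, function(t) sum(ci <= t), integer(1))
  cand <- cand[n_below >= options$min_rubisco_points &
               (length(ci) - n_below) >= options$min_rubp_points]
  if (length(cand) == 0L) {
    stop(sprintf(
      "curve '%s': no transition candidate leaves >=%d Rubisco-limited and >=%d RuBP-limited points",
      leaf_id, options$min_rubisco_points, options$min_rubp_points),
      call. = FALSE)
  }

  fits <- lapply(cand, function(t) fit_partition(A, x, y, ci <= t, options$rd_bounds))
  sse <- vapply(fits, `[[`, numeric(1), "sse")
  # ties (within numerical noise) break toward the larger Rubisco segment,
  # i.e. the largest candidate transition Ci
  best_sse <- min(sse)
  tol <- 1e-9 * max(best_sse, 1e-12)
  best_i <- max(which(sse <= best_sse + tol))
  best <- fits[[best_i]]
  rub <- ci <= cand[best_i]

  # min-consistency refinement (see file header)
  for (iter in seq_len(20L)) {
    ac <- best$vcmax * x
    aj <- best$jmax * y
    rub_new <- ac <= aj
    if (all(rub_new == rub)) break
    if (sum(rub_new) < 2L || sum(!rub_new) < 2L) break  # segment collapse
    cand_fit <- fit_partition(A, x, y, rub_new, options$rd_bounds)
    if (cand_fit$sse > best$sse + tol) break
    best <- cand_fit
    rub <- rub_new
  }

  structure(list(
    vcmax = best$vcmax, jmax = best$jmax, rd = best$rd,
    transition_ci = if (any(rub)) max(ci[rub]) else cand[best_i],
    limitation = ifelse(rub, "rubisco", "rubp"),
    rmse = sqrt(best$sse / length(A)),
    n_points_used = length(A),
    converged = best$converged,
    tleaf_k = tleaf, leaf_id = leaf_id, doy = doy,
    ci = ci, a_obs = A, fitted = best$fitted,
    kinetics = kinetics
  ), class = "fvcb_fit")
}

#' @export
print.fvcb_fit <- function(x, ...) {
  cat(sprintf("FvCB fit for leaf '%s'%s\n", x$leaf_id,
              if (is.na(x$doy)) "" else sprintf(" (DOY %s)", x$doy)))
  cat(sprintf("  Vcmax = %.2f, Jmax = %.2f, Rd = %.2f umol m-2 s-1 at %.2f K\n",
              x$vcmax, x$jmax, x$rd, x$tleaf_k))
  cat(sprintf("  transition Ci = %.1f umol mol-1 (%d Rubisco / %d RuBP points), RMSE = %.3f\n",
              x$transition_ci, sum(x$limitation == "rubisco"),
              sum(x$limitation == "rubp"), x$rmse))
  if (!x$converged) cat("  WARNING: bounded refit did not converge\n")
  invisible(x)
}

#' Light-saturated assimilation at ambient CO2 from a curve
#'
#' Returns the net assimilation recorded at the Ca = 380 umol mol^-1 step of
#' the protocol. The first 380 step is the acclimated reading and is the
#' default; `mode = "mean"` averages all 380 steps (the repeat is a stability
#' check).
#'
#' @param curve Curve data frame (canonical columns, see [fit_aci()]).
#' @param mode `"first"` (default) or `"mean"`.
#' @param ca_setpoint Ambient CO2 setpoint that defines A_sat, default 380.
#' @return A_sat, umol m^-2 s^-1.
#' @export
a_sat_from_curve <- function(curve, mode = c("first", "mean"),
                             ca_setpoint = 380) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(curve), "Ca_umol_mol" %in% names(curve))
  hit <- which(abs(curve$Ca_umol_mol - ca_setpoint) < 1)
  if (length(hit) == 0L) {
    stop(sprintf("curve has no step at Ca = %s umol mol-1", ca_setpoint),
         call. = FALSE)
  }
  if (mode == "first") curve$A_umol_m2_s[hit[1]] else mean(curve$A_umol_m2_s[hit])
}
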