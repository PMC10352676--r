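# Linear models of photosynthetic capacity on leaf traits.

# Canonical predictor units recorded in model metadata. Nitrogen enters the
# regressions in g m^-2 (coefficient magnitudes are only comparable across
# studies on that basis), pigments in ug cm^-2, SLA in cm^2 g^-1.
.PREDICTOR_UNITS <- c(
  n_area_g_m2 = "g m-2", n_area_ug_cm2 = "ug cm-2",
  chl_area_ug_cm2 = "ug cm-2", car_area_ug_cm2 = "ug cm-2",
  sla_cm2_g = "cm2 g-1", vcmax25 = "umol m-2 s-1", jmax25 = "umol m-2 s-1",
  a_sat = "umol m-2 s-1"
)

#' Ordinary least-squares model of a capacity on leaf traits
#'
#' Complete-case OLS fit of `response ~ predictors` with the coefficient of
#' determination and the overall ANOVA F-test of the regression.
#'
#' @param samples Data frame of leaf samples.
#' @param response Response column name (e.g. `"vcmax25"`).
#' @param predictors Character vector of predictor column names.
#' @return Object of class `"trait_lm"`: list with `response`, `predictors`,
#'   `coefficients` (intercept first), `r_squared`, `adj_r_squared`,
#'   `anova_f`, `anova_p`, `n`, `sigma`, `units` and the underlying `fit`.
#' @export
#' @examples
#' season <- simulate_season(cfg = trait_config(rng_seed = 3))
#' season$n_area_g_m2 <- 0.01 * season$n_area_ug_cm2
#' fit_linear_model(season, "vcmax25", c("n_area_g_m2", "chl_area_ug_cm2"))
fit_linear_model <- function(samples, response, predictors) {
  stopifnot(is.data.frame(samples), length(response) == 1L,
            length(predictors) >= 1L)
  missing_cols <- setdiff(c(response, predictors), names(samples))
  if (length(missing_cols) > 0) {
    stop(sprintf("columns not found: %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  dat <- samples[stats::complete.cases(samples[c(response, predictors)]),
                 c(response, predictors), drop = FALSE]
  if (nrow(dat) < length(predictors) + 2L) {
    stop(sprintf("need at least %d complete rows for %d predictor(s), got %d",
                 length(predictors) + 2L, length(predictors), nrow(dat)),
         call. = FALSE)
  }
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient design; collinear predictor(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  anova_p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(
    response = response, predictors = predictors,
    coefficients = stats::coef(fit),
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    anova_f = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    anova_p = unname(anova_p), n = nrow(dat), sigma = sm$sigma,
    units = .PREDICTOR_UNITS[predictors], fit = fit
  ), class = "trait_lm")
}

#' @export
print.trait_lm <- function(x, ...) {
  co <- x$coefficients
  terms <- paste(sprintf("%+.3f %s", co[-1], names(co)[-1]), collapse = " ")
  cat(sprintf("%s = %s %+.3f   (n = %d)\n", x$response, terms, co[1], x$n))
  cat(sprintf("  R2 = %.3f, F = %.2f, p = %.3g\n",
              x$r_squared, x$anova_f, x$anova_p))
  invisible(x)
}

#' The standard battery of capacity-on-trait models
#'
#' Fits the ten models relating photosynthetic capacity to leaf traits:
#' simple regressions of Vcmax25 and Jmax25 on each of N_area, Chl_area and
#' Car_area (six models), and the multiple regressions of Vcmax25 on
#' (N, Chl), (Chl, Car), (N, Car) and (N, Chl, Car) (four models).
#'
#' @param samples Data frame with columns `vcmax25`, `jmax25`,
#'   `n_area_g_m2`, `chl_area_ug_cm2`, `car_area_ug_cm2` (the nitrogen
#'   column is derived from `n_area_ug_cm2` if absent).
#' @return Object of class `"model_suite"`: list with `models` (named list
#'   of [fit_linear_model()] results) and `summary` (one row per model:
#'   response, predictors, n, r_squared, anova_p).
#' @export
model_suite <- function(samples) {
  if (!"n_area_g_m2" %in% names(samples) && "n_area_ug_cm2" %in% names(samples)) {
    samples$n_area_g_m2 <- 0.01 * samples$n_area_ug_cm2
  }
  n <- "n_area_g_m2"; chl <- "chl_area_ug_cm2"; car <- "car_area_ug_cm2"
  specs <- c(
    lapply(c(n, chl, car), function(p) list(resp = "vcmax25", preds = p)),
    lapply(c(n, chl, car), function(p) list(resp = "jmax25", preds = p)),
    list(list(resp = "vcmax25", preds = c(n, chl)),
         list(resp = "vcmax25", preds = c(chl, car)),
         list(resp = "vcmax25", preds = c(n, car)),
         list(resp = "vcmax25", preds = c(n, chl, car)))
  )
  models <- lapply(specs, function(s) fit_linear_model(samples, s$resp, s$preds))
  names(models) <- vapply(specs, function(s) {
    sprintf("%s ~ %s", s$resp, paste(s$preds, collapse = " + "))
  }, character(1))
  summary <- do.call(rbind, lapply(models, function(m) {
    data.frame(response = m$response,
               predictors = paste(m$predictors, collapse = " + "),
               n = m$n, r_squared = m$r_squared, anova_p = m$anova_p,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(models = models, summary = summary), class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat("Capacity ~ trait model battery\n")
  print(transform(x$summary, r_squared = round(r_squared, 3),
                  anova_p = signif(anova_p, 3)), row.names = FALSE)
  invisible(x)
}

#' Serialize fitted models to a flat table
#'
#' @param suite A `"model_suite"` object.
#' @return Data frame, one row per model, with the response, predictor list,
#'   intercept and named slope columns, R-squared, F and p, sample size and
#'   predictor units.
#' @export
as_model_table <- function(suite) {
  stopifnot(inherits(suite, "model_suite"))
  all_preds <- unique(unlist(lapply(suite$models, `[[`, "predictors")))
  rows <- lapply(suite$models, function(m) {
    row <- data.frame(response = m$response,
                      predictors = paste(m$predictors, collapse = " + "),
                      intercept = unname(m$coefficients[1]),
                      stringsAsFactors = FALSE)
    for (p in all_preds) {
      row[[paste0("b_", p)]] <-
        if (p %in% m$predictors) unname(m$coefficients[p]) else NA_real_
    }
    row$r_squared <- m$r_squared
    row$anova_f <- m$anova_f
    row$anova_p <- m$anova_p
    row$n <- m$n
    row$units <- paste(sprintf("%s [%s]", m$predictors, m$units), collapse = "; ")
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
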