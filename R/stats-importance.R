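# Random-forest permutation importance of leaf-trait predictors.

#' Random-forest %IncMSE importance of trait predictors
#'
#' Trains a random-forest regression of the response on the given predictors
#' and reports, per predictor, the percent increase in out-of-bag mean
#' squared error when that predictor's values are permuted (%IncMSE): the raw
#' OOB permutation importance averaged over trees, expressed as a percentage
#' of the forest's OOB MSE. Higher %IncMSE means the predictor carries more
#' information about the response. Deterministic given `seed`; the caller's
#' RNG stream is left untouched.
#'
#' @param samples Data frame of leaf samples.
#' @param response Response column, default `"vcmax25"`.
#' @param predictors Predictor columns; default nitrogen, chlorophyll,
#'   carotenoid and SLA.
#' @param n_trees Number of trees, default 500.
#' @param mtry Predictors tried per split; default `ceiling(p / 3)`.
#' @param seed RNG seed for the forest, default 1.
#' @return Object of class `"rf_importance"`: data frame `predictor`,
#'   `inc_mse_pct` sorted by decreasing importance, with attributes
#'   `oob_mse`, `settings`.
#' @export
#' @examples
#' season <- simulate_season(cfg = trait_config(rng_seed = 2))
#' rf_importance(season, seed = 42)
rf_importance <- function(samples, response = "vcmax25",
                          predictors = c("n_area_ug_cm2", "chl_area_ug_cm2",
                                         "car_area_ug_cm2", "sla_cm2_g"),
                          n_trees = 500, mtry = NULL, seed = 1L) {
  stopifnot(is.data.frame(samples))
  missing_cols <- setdiff(c(response, predictors), names(samples))
  if (length(missing_cols) > 0) {
    stop(sprintf("columns not found: %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  dat <- samples[stats::complete.cases(samples[c(response, predictors)]),
                 c(response, predictors), drop = FALSE]
  if (nrow(dat) < 10) {
    stop(sprintf("need at least 10 complete rows, got %d", nrow(dat)),
         call. = FALSE)
  }
  if (is.null(mtry)) mtry <- ceiling(length(predictors) / 3)
  rf <- with_preserved_seed({
    set.seed(as.integer(seed))
    randomForest::randomForest(
      x = dat[predictors], y = dat[[response]],
      ntree = n_trees, mtry = mtry, importance = TRUE
    )
  })
  raw <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  oob_mse <- rf$mse[n_trees]
  out <- data.frame(predictor = predictors,
                    inc_mse_pct = 100 * unname(raw[predictors]) / oob_mse,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$inc_mse_pct), ]
  rownames(out) <- NULL
  structure(out, class = c("rf_importance", "data.frame"),
            oob_mse = oob_mse,
            settings = list(n_trees = n_trees, mtry = mtry, seed = seed,
                            response = response))
}

#' @export
print.rf_importance <- function(x, ...) {
  s <- attr(x, "settings")
  cat(sprintf("Random-forest permutation importance for %s (%d trees, mtry %d, seed %s)\n",
              s$response, s$n_trees, s$mtry, s$seed))
  print.data.frame(transform(x, inc_mse_pct = round(inc_mse_pct, 2)),
                   row.names = FALSE)
  cat(sprintf("OOB MSE: %.2f\n", attr(x, "oob_mse")))
  invisible(x)
}
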