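# Seasonal-change summaries of per-DOY trait means.

#' Percent change of trait means between two measurement days
#'
#' Computes per-trait means on two days of year and the percent change
#' between them under both common conventions, which differ and are easy to
#' mix up for declines:
#' * `pct_change_rel_first` = 100 * (mean2 - mean1) / mean1 — change relative
#'   to the earlier day ("62% higher" for 100 -> 162);
#' * `pct_change_rel_second` = 100 * (mean2 - mean1) / mean2 — change
#'   relative to the later day (a 133.46 -> 46 decline is "190% lower" under
#'   this convention, which cannot exceed -100% under the first).
#' Both are reported, explicitly labeled; no silent choice is made. The
#' summary also locates each trait's peak DOY across the whole season.
#'
#' @param samples Leaf-sample data frame with a `doy` column.
#' @param traits Trait columns to summarize; defaults to every numeric
#'   column except `doy`.
#' @param doy_pair Length-2 vector `c(first, second)` of DOYs to compare,
#'   default `c(92, 126)`.
#' @return Object of class `"seasonal_summary"`: data frame with `trait`,
#'   `doy_first`, `doy_second`, `mean_first`, `mean_second`,
#'   `pct_change_rel_first`, `pct_change_rel_second`, `peak_doy`,
#'   `peak_mean`.
#' @export
#' @examples
#' season <- simulate_season(cfg = trait_config(rng_seed = 5))
#' seasonal_changes(season, traits = c("vcmax25", "chl_area_ug_cm2"))
seasonal_changes <- function(samples, traits = NULL, doy_pair = c(92, 126)) {
  stopifnot(is.data.frame(samples), "doy" %in% names(samples),
            length(doy_pair) == 2L)
  if (is.null(traits)) {
    num <- vapply(samples, is.numeric, logical(1))
    traits <- setdiff(names(samples)[num], c("doy", "step_index"))
  }
  missing_doy <- setdiff(doy_pair, unique(samples$doy))
  if (length(missing_doy) > 0) {
    stop(sprintf("DOY(s) not present in samples: %s",
                 paste(missing_doy, collapse = ", ")), call. = FALSE)
  }
  rows <- lapply(traits, function(tr) {
    by_doy <- stats::aggregate(samples[[tr]], by = list(doy = samples$doy),
                               FUN = mean)
    m1 <- by_doy$x[by_doy$doy == doy_pair[1]]
    m2 <- by_doy$x[by_doy$doy == doy_pair[2]]
    peak <- which.max(by_doy$x)
    data.frame(trait = tr, doy_first = doy_pair[1], doy_second = doy_pair[2],
               mean_first = m1, mean_second = m2,
               pct_change_rel_first = 100 * (m2 - m1) / m1,
               pct_change_rel_second = 100 * (m2 - m1) / m2,
               peak_doy = by_doy$doy[peak], peak_mean = by_doy$x[peak],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("seasonal_summary", "data.frame"))
}
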