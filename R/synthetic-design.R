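# Sampling design of the emulated field season.

#' Construct a season sampling design
#'
#' A design maps each measurement day of year (DOY) to a sample size and a
#' growth stage. Stages are assigned from `stage_boundaries`, a named vector
#' giving the last DOY of each stage.
#'
#' @param doys Strictly increasing integer DOYs.
#' @param sample_sizes Positive integer leaves measured per DOY.
#' @param stage_boundaries Named numeric vector, stage -> last DOY, in
#'   chronological order.
#' @return Data frame of class `"season_design"` with columns `doy`, `n`,
#'   `stage`.
#' @seealso [build_default_design()]
#' @export
season_design <- function(doys, sample_sizes,
                          stage_boundaries = c(Elongation = 95, Booting = 117,
                                               Flowering = 131, Filling = 161)) {
  doys <- as.integer(doys)
  sample_sizes <- as.integer(sample_sizes)
  if (length(doys) != length(sample_sizes)) {
    stop("`doys` and `sample_sizes` must have the same length", call. = FALSE)
  }
  if (any(diff(doys) <= 0)) stop("`doys` must be strictly increasing", call. = FALSE)
  if (any(sample_sizes < 1L)) stop("all sample sizes must be >= 1", call. = FALSE)
  if (is.null(names(stage_boundaries)) || any(diff(stage_boundaries) <= 0)) {
    stop("`stage_boundaries` must be a named, increasing vector", call. = FALSE)
  }
  if (any(doys > max(stage_boundaries))) {
    stop("some DOYs fall after the last stage boundary", call. = FALSE)
  }
  stage <- names(stage_boundaries)[findInterval(doys, stage_boundaries + 1L) + 1L]
  structure(data.frame(doy = doys, n = sample_sizes, stage = stage,
                       stringsAsFactors = FALSE),
            class = c("season_design", "data.frame"),
            stage_boundaries = stage_boundaries)
}

#' Default winter-wheat sampling design
#'
#' Eight measurement days between DOY 92 (April 2) and DOY 147 (May 27),
#' with 3-4 leaves each (29 in total), spanning the elongation, booting,
#' flowering and filling stages.
#'
#' @return A [season_design()] data frame.
#' @export
#' @examples
#' d <- build_default_design()
#' sum(d$n)  # 29 leaves
build_default_design <- function() {
  season_design(doys = c(92L, 96L, 105L, 119L, 126L, 133L, 140L, 147L),
                sample_sizes = c(4L, 4L, 3L, 3L, 3L, 4L, 4L, 4L))
}
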