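# Pearson correlations between photosynthetic capacity and leaf traits.

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Pearson correlation with two-sided t-test
#'
#' Product-moment correlation
#' \deqn{R = \sum (x - \bar x)(y - \bar y) /
#'   \sqrt{\sum (x - \bar x)^2 \sum (y - \bar y)^2}}
#' with the p-value from `t = R sqrt((n - 2) / (1 - R^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return List with `r`, `n`, `p_value`, `stars`.
#' @export
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))$r  # 0.6
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3) stop("at least 3 paired observations are required", call. = FALSE)
  for (nm in c("x", "y")) {
    v <- get(nm)
    if (any(!is.finite(v))) stop(sprintf("`%s` contains non-finite values", nm), call. = FALSE)
    if (stats::var(v) == 0) {
      stop(sprintf("`%s` has zero variance; correlation undefined", nm), call. = FALSE)
    }
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, n = length(x), p_value = ct$p.value, stars = p_stars(ct$p.value))
}

#' All pairwise trait correlations with significance stars
#'
#' Complete-case pairwise Pearson correlations between the given columns,
#' starred at the 0.05 / 0.01 / 0.001 levels.
#'
#' @param samples Data frame of leaf samples.
#' @param vars Columns to correlate; defaults to the capacity and trait
#'   columns present among `vcmax25`, `jmax25`, `a_sat`, `n_area_ug_cm2`,
#'   `chl_area_ug_cm2`, `car_area_ug_cm2`.
#' @return Object of class `"trait_cor"`: list of matrices `r`, `p`, `stars`
#'   and the sample size `n`.
#' @export
correlation_matrix <- function(samples,
                               vars = c("vcmax25", "jmax25", "a_sat",
                                        "n_area_ug_cm2", "chl_area_ug_cm2",
                                        "car_area_ug_cm2")) {
  vars <- intersect(vars, names(samples))
  if (length(vars) < 2) stop("need at least two variables to correlate", call. = FALSE)
  dat <- samples[stats::complete.cases(samples[vars]), vars, drop = FALSE]
  if (nrow(dat) < 3) stop("fewer than 3 complete rows", call. = FALSE)
  p <- r <- matrix(NA_real_, length(vars), length(vars),
                   dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (i < j) {
      pr <- pearson_r(dat[[i]], dat[[j]])
      r[i, j] <- r[j, i] <- pr$r
      p[i, j] <- p[j, i] <- pr$p_value
    }
  }
  stars <- matrix(p_stars(p), nrow(p), dimnames = dimnames(p))
  diag(stars) <- ""
  structure(list(r = r, p = p, stars = stars, n = nrow(dat)),
            class = "trait_cor")
}

#' @export
print.trait_cor <- function(x, digits = 2, ...) {
  cat(sprintf("Pairwise Pearson correlations (n = %d)\n", x$n))
  shown <- matrix(paste0(format(round(x$r, digits)), x$stars),
                  nrow(x$r), dimnames = dimnames(x$r))
  print(shown, quote = FALSE)
  cat("*, **, ***: p < 0.05, 0.01, 0.001\n")
  invisible(x)
}

#' Tidy a correlation matrix into a long table
#'
#' @param x A `"trait_cor"` object.
#' @return Data frame with one row per unordered variable pair: `var1`,
#'   `var2`, `r`, `p_value`, `stars`, `n`.
#' @export
as_correlation_table <- function(x) {
  stopifnot(inherits(x, "trait_cor"))
  vars <- rownames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  data.frame(var1 = vars[idx[, 1]], var2 = vars[idx[, 2]],
             r = x$r[idx], p_value = x$p[idx], stars = x$stars[idx],
             n = x$n, stringsAsFactors = FALSE)
}
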