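# Independent scalar oracles, deliberately written as plain if/else
# arithmetic so they share no code path with the package's vectorized
# implementations.

oracle_fvcb_scalar <- function(vcmax, jmax, rd, ci, kin = bernacchi_kinetics()) {
  km <- kin$kc * (1 + kin$o / kin$ko)
  ac <- vcmax * (ci - kin$gamma_star) / (ci + km)
  aj <- jmax * (ci - kin$gamma_star) / (4 * ci + 8 * kin$gamma_star)
  if (ac <= aj) ac - rd else aj - rd
}

# Direct summation form of the product-moment correlation.
oracle_pearson <- function(x, y) {
  xb <- sum(x) / length(x)
  yb <- sum(y) / length(y)
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_along(x)) {
    num <- num + (x[i] - xb) * (y[i] - yb)
    dx2 <- dx2 + (x[i] - xb)^2
    dy2 <- dy2 + (y[i] - yb)^2
  }
  num / sqrt(dx2 * dy2)
}

# Run the curve-simulation -> fit -> normalize chain for a season of truths
# and return fitted 25 degC capacities merged with the truth traits.
fit_season_capacities <- function(truths, noise_sd = 0.3, seed = 1) {
  curves <- simulate_curves(truths, noise_sd = noise_sd, seed = seed)
  fits <- lapply(split(curves, curves$leaf_id), function(cv) {
    cv <- cv[order(cv$step_index), ]
    f <- fit_aci(cv)
    data.frame(leaf_id = f$leaf_id,
               vcmax25 = normalize_to_25(f$vcmax, f$tleaf_k, arrhenius_preset("vcmax")),
               jmax25 = normalize_to_25(f$jmax, f$tleaf_k, arrhenius_preset("jmax")),
               stringsAsFactors = FALSE)
  })
  trait_cols <- intersect(c("leaf_id", "doy", "n_area_ug_cm2", "chl_area_ug_cm2",
                            "car_area_ug_cm2", "sla_cm2_g"), names(truths))
  merge(do.call(rbind, fits), truths[trait_cols], by = "leaf_id")
}
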