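test_that("the default design reproduces the published sampling campaign", {
  d <- build_default_design()
  expect_equal(d$doy, c(92, 96, 105, 119, 126, 133, 140, 147))
  expect_equal(d$n, c(4, 4, 3, 3, 3, 4, 4, 4))
  expect_equal(sum(d$n), 29)
  expect_equal(d$stage[d$doy == 126], "Flowering")
  expect_equal(d$stage, c("Elongation", "Booting", "Booting", "Flowering",
                          "Flowering", "Filling", "Filling", "Filling"))
})

test_that("invalid designs and configurations are rejected", {
  expect_error(season_design(c(92, 92), c(3, 3)), "increasing")
  expect_error(season_design(c(92, 96), c(3, 0)), ">= 1")
  expect_error(trait_config(traits = list(vcmax25 = list(baseline = -1))),
               "non-positive")
  expect_error(trait_config(traits = list(n_area = list(cv = -0.1))),
               "negative CV")
})

test_that("seasons are bitwise reproducible under a fixed seed", {
  cfg <- trait_config(rng_seed = 42)
  s1 <- simulate_season(cfg = cfg)
  s2 <- simulate_season(cfg = cfg)
  expect_identical(s1, s2)
  c1 <- simulate_curves(s1[1:3, ], seed = 42)
  c2 <- simulate_curves(s1[1:3, ], seed = 42)
  expect_identical(c1, c2)
  expect_false(identical(simulate_season(cfg = trait_config(rng_seed = 43)), s1))
})

test_that("with zero noise every leaf on a day is identical and trajectories are single-peaked", {
  cfg0 <- trait_config()
  for (nm in names(cfg0$traits)) cfg0$traits[[nm]]$cv <- 0
  season <- simulate_season(cfg = cfg0)
  for (d in unique(season$doy)) {
    day <- season[season$doy == d, ]
    expect_equal(max(day$vcmax25) - min(day$vcmax25), 0)
    expect_equal(max(day$chl_area_ug_cm2) - min(day$chl_area_ug_cm2), 0)
  }
  by_doy <- aggregate(season[c("vcmax25", "jmax25", "n_area_ug_cm2",
                               "chl_area_ug_cm2", "car_area_ug_cm2")],
                      by = list(doy = season$doy), FUN = mean)
  expect_equal(by_doy$doy[which.max(by_doy$vcmax25)], 126)
  for (tr in c("vcmax25", "jmax25", "n_area_ug_cm2", "chl_area_ug_cm2",
               "car_area_ug_cm2")) {
    rising <- by_doy[[tr]][by_doy$doy <= 126]
    falling <- by_doy[[tr]][by_doy$doy >= 126]
    expect_true(all(diff(rising) > 0), label = paste(tr, "rises to the peak"))
    expect_true(all(diff(falling) < 0), label = paste(tr, "falls after the peak"))
  }
})

test_that("doubling all trait anchors doubles the generated values at zero noise", {
  cfg0 <- trait_config()
  cfg2 <- trait_config()
  for (nm in names(cfg0$traits)) {
    cfg0$traits[[nm]]$cv <- 0
    cfg2$traits[[nm]]$cv <- 0
    for (a in c("baseline", "peak", "end")) {
      cfg2$traits[[nm]][[a]] <- 2 * cfg2$traits[[nm]][[a]]
    }
  }
  s1 <- simulate_season(cfg = cfg0)
  s2 <- simulate_season(cfg = cfg2)
  for (col in c("vcmax25", "jmax25", "n_area_ug_cm2", "chl_area_ug_cm2",
                "car_area_ug_cm2", "sla_cm2_g")) {
    expect_equal(s2[[col]], 2 * s1[[col]], tolerance = 1e-12)
  }
})

test_that("the Chl/N ratio plateaus at its configured value from DOY 105 on", {
  # Monte-Carlo mean over 200 replicate seasons at CV = 0.05
  means <- vapply(1:200, function(s) {
    cfg <- trait_config(rng_seed = s)
    for (nm in names(cfg$traits)) cfg$traits[[nm]]$cv <- 0.05
    season <- simulate_season(cfg = cfg)
    late <- season[season$doy >= 105, ]
    mean(late$chl_area_ug_cm2 / late$n_area_ug_cm2)
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.36), 0.02)
})

test_that("ground truths respect physiological invariants across seeds", {
  for (s in 1:5) {
    season <- simulate_season(cfg = trait_config(rng_seed = s))
    ratio <- season$jmax25 / season$vcmax25
    expect_true(all(ratio > 1.0 & ratio < 2.5))
    num <- vapply(season, is.numeric, logical(1))
    expect_true(all(as.matrix(season[num & names(num) != "doy"]) > 0))
  }
})

test_that("simulated curves follow the protocol order and the forward model exactly at zero noise", {
  truth <- list(leaf_id = "fw", doy = 126, vcmax25 = 100, jmax25 = 160,
                rd25 = 1.5, tleaf_k = 298.15)
  crv <- simulate_aci_curve(truth, noise_sd = 0, seed = 1)
  expect_equal(nrow(crv), 10)
  expect_equal(crv$Ca_umol_mol, default_protocol())
  expect_equal(crv$Ci_umol_mol, 0.7 * default_protocol())
  # at 25 degC the Arrhenius projection is identity to ~1e-3, so the curve
  # must match the scalar forward oracle at the projected capacities
  kin <- bernacchi_kinetics(298.15)
  vc <- project_from_25(100, 298.15)
  j <- project_from_25(160, 298.15, arrhenius_preset("jmax"))
  expected <- vapply(crv$Ci_umol_mol,
                     function(c1) oracle_fvcb_scalar(vc, j, 1.5, c1, kin),
                     numeric(1))
  expect_equal(crv$A_umol_m2_s, expected, tolerance = 1e-12)
})
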