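make_truth <- function(vcmax25, ratio = 1.6, rd25 = 1.5, id = "leaf") {
  list(leaf_id = id, doy = 126, stage = "Flowering", vcmax25 = vcmax25,
       jmax25 = ratio * vcmax25, rd25 = rd25, tleaf_k = 298.15)
}

test_that("noise-free curves are refit to the generating parameters", {
  tr <- make_truth(100)
  fit <- fit_aci(simulate_aci_curve(tr, noise_sd = 0, seed = 1))
  expect_equal(normalize_to_25(fit$vcmax, fit$tleaf_k), 100, tolerance = 1e-8)
  expect_equal(normalize_to_25(fit$jmax, fit$tleaf_k, arrhenius_preset("jmax")),
               160, tolerance = 1e-8)
  expect_equal(fit$rd, 1.5, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)
})

test_that("both limitation states appear on a full protocol curve", {
  fit <- fit_aci(simulate_aci_curve(make_truth(100), noise_sd = 0, seed = 1))
  expect_setequal(unique(fit$limitation), c("rubisco", "rubp"))
  # the lowest-Ci step sits below the compensation point, where the
  # RuBP-regeneration expression is the smaller rate
  expect_equal(fit$limitation[which.min(fit$ci)], "rubp")
})

test_that("curves with too few points are rejected with the curve named", {
  crv <- simulate_aci_curve(make_truth(90, id = "short"), protocol = c(380, 200, 100, 600),
                            noise_sd = 0, seed = 1)
  expect_error(fit_aci(crv), "short")
  expect_error(fit_aci(crv), "5")
})

test_that("the duplicate 380 stability step is excluded by default and kept on request", {
  crv <- simulate_aci_curve(make_truth(100), noise_sd = 0, seed = 1)
  expect_equal(fit_aci(crv)$n_points_used, 9)
  fit_all <- fit_aci(crv, options = aci_fit_options(use_duplicate_380 = TRUE))
  expect_equal(fit_all$n_points_used, 10)
  expect_equal(normalize_to_25(fit_all$vcmax, fit_all$tleaf_k), 100,
               tolerance = 1e-8)
})

test_that("gas-analyzer column aliases and Celsius temperatures are handled", {
  crv <- simulate_aci_curve(make_truth(100), noise_sd = 0, seed = 1)
  li <- data.frame(leaf_id = crv$leaf_id, CO2R = crv$Ca_umol_mol,
                   Ci = crv$Ci_umol_mol, Photo = crv$A_umol_m2_s,
                   Tleaf = crv$Tleaf_K - 273.15)
  opts <- aci_fit_options(column_aliases = c(
    Ca_umol_mol = "CO2R", Ci_umol_mol = "Ci", A_umol_m2_s = "Photo",
    Tleaf_K = "Tleaf"))
  fit <- fit_aci(li, options = opts)
  expect_equal(fit$tleaf_k, 298.15, tolerance = 1e-9)
  expect_equal(normalize_to_25(fit$vcmax, fit$tleaf_k), 100, tolerance = 1e-8)
})

test_that("Vcmax recovery stays accurate under moderate instrument noise", {
  set.seed(7)
  errs <- vapply(1:30, function(i) {
    v <- runif(1, 60, 140)
    tr <- make_truth(v, ratio = runif(1, 1.5, 2.0), id = paste0("mc", i))
    fit <- fit_aci(simulate_aci_curve(tr, noise_sd = 0.3, seed = i))
    (normalize_to_25(fit$vcmax, fit$tleaf_k) - v) / v
  }, numeric(1))
  expect_lt(median(abs(errs)), 0.05)
})

test_that("A_sat is read from the acclimated 380 step, optionally averaged", {
  crv <- data.frame(Ca_umol_mol = c(380, 200, 100, 380, 800),
                    A_umol_m2_s = c(20, 12, 6, 22, 27))
  expect_equal(a_sat_from_curve(crv), 20)
  expect_equal(a_sat_from_curve(crv, mode = "mean"), 21)
  crv2 <- data.frame(Ca_umol_mol = c(300, 200), A_umol_m2_s = c(15, 10))
  expect_error(a_sat_from_curve(crv2), "380")
})
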