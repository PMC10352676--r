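test_that("pigment equations reproduce the hand-computed oracle values", {
  # 95%-ethanol coefficient set evaluated by hand for
  # A665 = 0.50, A649 = 0.20, A470 = 0.30, V = 10 mL, area = 5 cm^2:
  #   Chl a = 13.95*0.50 - 6.88*0.20                  = 5.599   ug/mL
  #   Chl b = 24.96*0.20 - 7.32*0.50                  = 1.332   ug/mL
  #   Car   = (300 - 2.05*5.599 - 114.8*1.332) / 245  = 0.55350388 ug/mL
  # area basis: x 10/5 = x2
  pg <- pigments_from_absorbance(0.50, 0.20, 0.30, volume_ml = 10,
                                 leaf_area_cm2 = 5)
  expect_equal(pg$chl_a_ug_ml, 5.599, tolerance = 1e-10)
  expect_equal(pg$chl_b_ug_ml, 1.332, tolerance = 1e-10)
  expect_equal(pg$chl_area_ug_cm2, 13.862, tolerance = 1e-10)
  expect_equal(pg$car_area_ug_cm2, 1.1070077551020408, tolerance = 1e-10)
})

test_that("pigment contents are linear in extract volume and zero at zero absorbance", {
  z <- pigments_from_absorbance(0, 0, 0, 10, 5)
  expect_equal(z$chl_area_ug_cm2, 0)
  expect_equal(z$car_area_ug_cm2, 0)
  p1 <- pigments_from_absorbance(0.4, 0.15, 0.25, 10, 5)
  p2 <- pigments_from_absorbance(0.4, 0.15, 0.25, 20, 5)
  expect_equal(p2$chl_area_ug_cm2, 2 * p1$chl_area_ug_cm2, tolerance = 1e-12)
  expect_equal(p2$car_area_ug_cm2, 2 * p1$car_area_ug_cm2, tolerance = 1e-12)
})

test_that("below-detection pigment readings are clipped to zero with a warning", {
  # high A649 with low A665 drives the chl-a equation negative
  expect_warning(pg <- pigments_from_absorbance(0.01, 0.50, 0.0, 10, 5),
                 "clipped")
  expect_true(all(pg$chl_a_ug_ml >= 0 & pg$car_ug_ml >= 0))
  expect_gt(attr(pg, "n_clipped"), 0)
})

test_that("structural traits obey the SLA/M_A reciprocal identity and unit chain", {
  st <- structural_traits(dry_mass_g = 0.05, leaf_area_cm2 = 10,
                          n_mass_g_g = 0.04)
  expect_equal(st$m_a_g_m2, 50)
  expect_equal(st$sla_cm2_g * st$m_a_g_m2, 1e4, tolerance = 1e-10)
  expect_equal(st$n_area_g_m2, 2)
  expect_equal(st$n_area_ug_cm2, 200)
  expect_error(structural_traits(0, 10, 0.04), "positive")
})

test_that("allocation fractions match hand arithmetic and scale linearly", {
  af <- allocation_fractions(vcmax = 100, jmax = 160, chl_area_ug_cm2 = 72,
                             m_a_g_m2 = 100, n_mass_g_g = 0.04)
  expect_equal(af$p_r, 100 / (6.25 * 20.5 * 100 * 0.04), tolerance = 1e-12)
  expect_equal(af$p_r, 0.1951, tolerance = 1e-3)
  expect_equal(af$p_b, 160 / (8.06 * 156 * 100 * 0.04), tolerance = 1e-12)
  expect_equal(af$p_b, 0.0318, tolerance = 1e-3)
  af2 <- allocation_fractions(200, 160, 72, 100, 0.04)
  expect_equal(af2$p_r, 2 * af$p_r, tolerance = 1e-12)
  expect_equal(af2$p_b, af$p_b, tolerance = 1e-12)
})

test_that("implausible allocation inputs warn with the leaf named rather than fail", {
  expect_warning(
    allocation_fractions(vcmax = 500, jmax = 700, chl_area_ug_cm2 = 60,
                         m_a_g_m2 = 30, n_mass_g_g = 0.01,
                         leaf_id = "bad_leaf"),
    "bad_leaf")
})

test_that("the Chl/N ratio series averages per DOY and flags zero nitrogen", {
  smp <- data.frame(doy = c(126, 126, 133),
                    chl_area_ug_cm2 = c(72, 76, 60),
                    n_area_ug_cm2 = c(200, 200, 60))
  rt <- chl_to_n_ratio(smp)
  expect_equal(rt$chl_to_n[rt$doy == 126], mean(c(72, 76) / 200))
  expect_equal(rt$chl_to_n[rt$doy == 133], 1)
  expect_equal(rt$n_leaves, c(2, 1))
  smp$n_area_ug_cm2[1] <- 0
  expect_error(chl_to_n_ratio(smp), "zero")
})
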