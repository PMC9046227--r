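test_that("standard curves require spread and report fit quality", {
  sc <- fit_standard_curve(c(0, 10, 20, 40), c(0.05, 0.15, 0.25, 0.45))
  expect_equal(sc$slope, 0.01, tolerance = 1e-12)
  expect_equal(sc$intercept, 0.05, tolerance = 1e-12)
  expect_equal(sc$r_squared, 1)
  expect_error(fit_standard_curve(c(5, 5), c(1, 2)), "distinct")
})

test_that("Griess quantification inverts the standard curve with clipping", {
  curve <- fit_standard_curve(c(0, 50), c(0, 0.5))  # 0.01 OD/uM, intercept 0
  expect_equal(quantify_griess(0.25, curve)$nitrite_um, 25)
  # OD equal to blank reads zero
  expect_equal(quantify_griess(0.10, curve, blank_od = 0.10)$nitrite_um, 0)
  # OD below blank clips to zero with the below_blank flag
  below <- quantify_griess(0.05, curve, blank_od = 0.10)
  expect_equal(below$nitrite_um, 0)
  expect_equal(below$flag, "below_blank")
  # poor curves are refused
  bad <- fit_standard_curve(c(0, 10, 20), c(0.3, 0.05, 0.4))
  expect_error(quantify_griess(0.2, bad), "R\\^2")
  # samples above the curve span need the extrapolation flag
  expect_error(quantify_griess(0.9, curve), "extrapolation")
  expect_equal(quantify_griess(0.9, curve, allow_extrapolation = TRUE)$nitrite_um, 90)
})

test_that("arginase activity evaluates the assay formula in U/L", {
  expect_equal(arginase_activity(0), 0)
  # 2 mM urea, 100 ul lysate, 10 ul tested, 60 min:
  # 2 * (100 * 1e6) / (10 * 60 * 1000)
  expect_equal(arginase_activity(2, 100, 10, 60), 2 * (100 * 1e6) / (10 * 60 * 1000))
  expect_equal(arginase_activity(2, 100, 10, 60), 1000 / 3, tolerance = 1e-12)
  # linear in urea
  expect_equal(arginase_activity(4, 100, 10, 60),
               2 * arginase_activity(2, 100, 10, 60))
  expect_error(arginase_activity(1, incubation_time = 0), "positive")
  expect_error(arginase_activity(1, tested_volume = -5), "positive")
})

test_that("glucose consumption uses single-point calibration", {
  # standard 0.5 OD at 5 mM -> 10 mM medium (1.0 OD) minus 6 mM sample (0.6 OD)
  r <- glucose_consumption(0.6, medium_blank_od = 1.0, standard_od = 0.5,
                           standard_conc = 5)
  expect_equal(r$glucose_consumed_mm, 4)
  expect_equal(glucose_consumption(1.0, 1.0, 0.5)$glucose_consumed_mm, 0)
  # apparent production flagged, value preserved
  prod <- glucose_consumption(1.5, 1.0, 0.5)
  expect_equal(prod$glucose_consumed_mm, -5)
  expect_equal(prod$flag, "production?")
  expect_error(glucose_consumption(0.6, 1.0, standard_od = 0), "positive")
})

test_that("lactate endpoint detection follows the stability rule", {
  curve <- fit_standard_curve(c(0, 5, 10), c(0, 500, 1000))  # 100 RFU/mM
  bg <- rep(1000, 5)
  # plateau at background + 1000 -> 10 mM
  tr <- c(bg, 1000 + c(200, 400, 600, 800, 1000, 1000, 1000))
  r <- lactate_from_nadh(tr, 5, curve)
  expect_equal(r$lactate_mm, 10)
  expect_equal(r$flag, "")
  # flat trace equal to background -> 0 mM
  flat <- lactate_from_nadh(c(bg, rep(1000, 5)), 5, curve)
  expect_equal(flat$lactate_mm, 0)
  # strictly rising trace uses the last cycle and is flagged unstable
  rising <- lactate_from_nadh(c(bg, 1000 + seq(100, 1000, by = 100)), 5, curve)
  expect_equal(rising$flag, "unstable")
  expect_equal(rising$lactate_mm, 10)
  expect_error(lactate_from_nadh(c(1000, 1100, 1200), 1, curve), "background")
  expect_error(lactate_from_nadh(c(bg, 1100, 1200), 5, curve), "post-start")
})

test_that("quantifications are invariant to a shared additive offset", {
  curve <- fit_standard_curve(c(0, 50), c(0, 0.5))
  for (c0 in c(0.02, 0.1, 1)) {
    expect_equal(quantify_griess(0.25 + c0, curve, blank_od = c0)$nitrite_um,
                 quantify_griess(0.25, curve, blank_od = 0)$nitrite_um)
  }
  # lactate: offset on every read cancels through background subtraction
  bg <- rep(1000, 5)
  tr <- c(bg, 1000 + c(500, 1000, 1000, 1000))
  r0 <- lactate_from_nadh(tr, 5, curve <- fit_standard_curve(c(0, 10), c(0, 1000)))
  r1 <- lactate_from_nadh(tr + 250, 5, curve)
  expect_equal(r0$lactate_mm, r1$lactate_mm)
})
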