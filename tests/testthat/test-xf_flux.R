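test_that("phase segmentation applies the last-cycle and FCCP-max rules", {
  tr <- constant_phase_trace()
  seg <- segment_phases(tr)
  expect_equal(seg$ocr[seg$phase == "glucose"], 100)
  expect_equal(seg$ecar[seg$phase == "oligomycin"], 40)

  # FCCP max rule picks the peak cycle
  tr2 <- tr
  tr2$ocr[tr2$phase == "fccp"] <- c(80, 95, 90)
  seg2 <- segment_phases(tr2)
  expect_equal(seg2$ocr[seg2$phase == "fccp"], 95)
  seg3 <- segment_phases(tr2, fccp_max = FALSE)
  expect_equal(seg3$ocr[seg3$phase == "fccp"], 90)

  # mean summary option
  tr3 <- tr
  tr3$ocr[tr3$phase == "glucose"] <- c(90, 100, 110)
  expect_equal(segment_phases(tr3, summary = "mean")$ocr[2], 100)
})

test_that("missing or shuffled phases are rejected", {
  tr <- constant_phase_trace()
  expect_error(segment_phases(tr[tr$phase != "aa_rot", ]), "aa_rot absent")
  shuffled <- tr
  shuffled$phase <- sample(shuffled$phase)
  expect_error(segment_phases(shuffled), "contiguous")
})

test_that("Hoechst normalization divides by the mean-centred count factor", {
  # counts 10000/20000 (mean 15000): the sparse well scales 90 -> 135
  r <- normalize_rates(c(90, 120), c(10000, 20000))
  expect_equal(as.numeric(r), c(90 / (10000 / 15000), 120 / (20000 / 15000)))
  expect_equal(as.numeric(r)[1], 135)
  # uniform counts are the identity
  expect_equal(as.numeric(normalize_rates(c(50, 60), c(8000, 8000))), c(50, 60))
  # single well: mean of one
  expect_equal(as.numeric(normalize_rates(42, 12345)), 42)
  # zero counts excluded with warning
  expect_warning(r2 <- normalize_rates(c(10, 20), c(0, 1000)), "excluding")
  expect_true(is.na(r2[1]))
  expect_equal(attr(r2, "excluded_wells"), 1L)
})

test_that("mito stress-test algebra and floor rules", {
  ph <- segment_phases(constant_phase_trace())
  m <- mito_parameters(ph)
  expect_equal(m$basal_respiration, 80)
  expect_equal(m$maximal_respiration, 160)
  expect_equal(m$spare_capacity, 80)
  expect_equal(m$atp_linked_respiration, 60)
  expect_equal(m$proton_leak, 20)
  expect_equal(m$nonmito_ocr, 20)
  expect_equal(m$basal_ocr_total, 100)

  # oligomycin OCR below aa_rot floors the leak at 0 with a flag
  ph2 <- ph; ph2$ocr[ph2$phase == "oligomycin"] <- 15
  m2 <- mito_parameters(ph2)
  expect_equal(m2$proton_leak, 0)
  expect_match(m2$flags, "proton_leak_floored")
  # FCCP equal to glucose phase: zero spare capacity
  ph3 <- ph; ph3$ocr[ph3$phase == "fccp"] <- 100
  expect_equal(mito_parameters(ph3)$spare_capacity, 0)
})

test_that("glycolysis stress-test algebra and floor rules", {
  ph <- segment_phases(constant_phase_trace(
    ecar = c(pre_glucose = 5, glucose = 25, oligomycin = 40, fccp = 40,
             aa_rot = 5)))
  g <- glyco_parameters(ph)
  expect_equal(g$glycolysis, 20)
  expect_equal(g$glycolytic_capacity, 35)
  expect_equal(g$glycolytic_reserve, 15)
  expect_equal(g$nonglycolytic_acidification, 5)

  ph2 <- ph; ph2$ecar[ph2$phase == "glucose"] <- 5
  expect_equal(glyco_parameters(ph2)$glycolysis, 0)
  ph3 <- ph; ph3$ecar[ph3$phase == "oligomycin"] <- 20
  g3 <- glyco_parameters(ph3)
  expect_equal(g3$glycolytic_reserve, 0)
  expect_match(g3$flags, "glycolytic_reserve_floored")
})

test_that("ATP-rate equations reproduce the constant-pinned worked examples", {
  k <- xf_constants(buffer_factor = 2.4)
  # unit OCR difference scales mitoPER by the CO2 contribution factor
  expect_equal(atp_rates(21, 20, 10, k)$mito_per, 0.61)
  # half-unit OCR difference: 0.5 * 2 * 2.75
  expect_equal(atp_rates(20.5, 20, 10, k)$mito_atp, 2.75)
  # full worked example
  r <- atp_rates(100, 20, 50, k)
  expect_equal(r$mito_per, 48.8)
  expect_equal(r$total_per, 50 * 2.4 * 2.28 * 1.60)
  expect_equal(r$total_per, 437.76)
  expect_equal(r$glyco_atp, 388.96)
  expect_equal(r$mito_atp, 80 * 2 * 2.75)
  expect_equal(r$total_atp, 828.96)
  expect_equal(r$total_atp, r$glyco_atp + r$mito_atp)
})

test_that("ATP-rate internal identities hold across random inputs", {
  set.seed(42)
  k <- xf_constants(buffer_factor = 2.4)
  n <- 200
  basal <- runif(n, 10, 300); aarot <- runif(n, 0, 50); ecar <- runif(n, 1, 150)
  r <- atp_rates(basal, aarot, ecar, k)
  expect_equal(r$total_atp, r$glyco_atp + r$mito_atp, tolerance = 1e-12)
  expect_equal(r$glyco_atp, r$glyco_per, tolerance = 0)
  nz <- r$mito_per != 0
  expect_equal(r$mito_atp[nz] / r$mito_per[nz],
               rep(2 * 2.75 / 0.61, sum(nz)), tolerance = 1e-12)
})

test_that("a negative glycoPER is flagged, never floored", {
  k <- xf_constants(buffer_factor = 0.01)  # misconfigured buffer factor
  r <- atp_rates(100, 20, 5, k)
  expect_true(r$glyco_per < 0)
  expect_equal(r$flags, "negative_glyco_per")
  expect_error(atp_rates(100, 20, 5, xf_constants()), "buffer_factor")
})

test_that("plate-level analysis recovers zero-noise ground truth exactly", {
  sim <- generate_xf_experiment(n_subjects = 2, replicates = 2,
                                noise = noise_free())
  res <- analyze_xf_plate(sim$traces, sim$counts, sim$layout,
                          constants = xf_constants(buffer_factor = 2.4))
  m <- merge(res$summary, sim$truth, by = "stimulus", suffixes = c("", ".t"))
  for (p in c("basal_respiration", "maximal_respiration", "spare_capacity",
              "atp_linked_respiration", "proton_leak", "nonmito_ocr",
              "glycolysis", "glycolytic_capacity", "glycolytic_reserve",
              "nonglycolytic_acidification", "basal_ocr_total")) {
    expect_equal(m[[p]], m[[paste0(p, ".t")]], tolerance = 1e-9,
                 info = p)
  }
})

test_that("normalization preserves the plate mean of included wells", {
  set.seed(5)
  rates <- runif(24, 20, 200)
  counts <- rlnorm(24, log(2e4), 0.2)
  norm <- normalize_rates(rates, counts)
  # harmonic-style identity: mean of rate/factor weighted by factor recovers
  # the raw mean, i.e. sum(norm * count) / sum(count) == mean(raw)
  expect_equal(sum(norm * counts) / sum(counts), mean(rates), tolerance = 1e-12)
})
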