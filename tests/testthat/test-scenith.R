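test_that("event summarization takes the median over viable events only", {
  ev <- data.frame(well = "A1", puromycin = c(1, 2, 3, 4, 100), viable = TRUE)
  expect_equal(summarize_events(ev)$mfi, 3)
  ev$viable[5] <- FALSE
  s <- summarize_events(ev)
  expect_equal(s$mfi, 2.5)
  expect_equal(s$n_events, 4)
  ev$viable <- FALSE
  expect_error(summarize_events(ev), "no viable events in well A1")
  expect_error(summarize_events(data.frame(well = "A1", puromycin = -1,
                                           viable = TRUE)), "non-negative")
})

test_that("dependency algebra matches the hand-worked example", {
  p <- scenith_parameters(control = 100, dg = 10, o = 55, dgo = 10)
  expect_equal(p$glucose_dependency, 100)
  expect_equal(p$faao_capacity, 0)
  expect_equal(p$mito_dependency, 50)
  expect_equal(p$glycolytic_capacity, 50)
  # DG at the DGO floor forces complete glucose dependency
  expect_equal(scenith_parameters(80, 20, 50, 20)$glucose_dependency, 100)
  # oligomycin with no effect forces zero mito dependency
  p2 <- scenith_parameters(80, 30, 80, 20)
  expect_equal(p2$mito_dependency, 0)
  expect_equal(p2$glycolytic_capacity, 100)
  expect_error(scenith_parameters(10, 5, 5, 10), "denominator")
})

test_that("complementarity and scale invariance hold; excursions clamp", {
  set.seed(31)
  for (i in 1:50) {
    dgo <- runif(1, 1, 50); ctrl <- dgo + runif(1, 1, 200)
    dg <- runif(1, dgo, ctrl); o <- runif(1, dgo, ctrl)
    p <- scenith_parameters(ctrl, dg, o, dgo)
    expect_equal(p$glucose_dependency + p$faao_capacity, 100)
    expect_equal(p$mito_dependency + p$glycolytic_capacity, 100)
    k <- runif(1, 0.1, 10)
    expect_equal(scenith_parameters(k * ctrl, k * dg, k * o, k * dgo),
                 p, tolerance = 1e-10)
  }
  cl <- scenith_parameters(100, 110, 50, 10)  # DG above control
  expect_equal(cl$glucose_dependency, 0)
  expect_match(cl$flags, "clamped")
  raw <- scenith_parameters(100, 110, 50, 10, clamp = FALSE)
  expect_true(raw$glucose_dependency < 0)
})

test_that("harringtonine background subtraction shifts all conditions", {
  p <- scenith_parameters(110, 20, 65, 20, h = 10, subtract_background = TRUE)
  ref <- scenith_parameters(100, 10, 55, 10)
  expect_equal(p$glucose_dependency, ref$glucose_dependency)
  expect_match(p$flags, "background_subtracted")
  expect_error(scenith_parameters(100, 10, 55, 10, subtract_background = TRUE),
               "harringtonine")
})

test_that("per-sample profiles respect the event minimum", {
  ev <- exact_scenith_events(n = 50)
  prof <- scenith_profiles(ev, min_events = 100)
  expect_match(prof$flags, "low_events")
  prof2 <- scenith_profiles(ev, min_events = 10)
  expect_equal(prof2$glucose_dependency, 100)
  expect_false(grepl("low_events", prof2$flags))
})

test_that("subset gating reproduces ungated profiles and isolates populations", {
  ev <- exact_scenith_events(n = 200)
  all_pass <- profile_by_subset(ev, gates = list(all = function(e) rep(TRUE, nrow(e))))
  ungated <- scenith_profiles(ev)
  expect_equal(all_pass$glucose_dependency, ungated$glucose_dependency)
  expect_equal(all_pass$mito_dependency, ungated$mito_dependency)

  # two zero-noise populations in the same wells, split by a marker gate
  a <- exact_scenith_events(mfis = c(control = 100, DG = 60, O = 40, DGO = 20),
                            n = 150, marker = 10)   # gd 50, md 75
  b <- exact_scenith_events(mfis = c(control = 200, DG = 40, O = 160, DGO = 40),
                            n = 150, marker = 1000) # gd 100, md 25
  ev2 <- rbind(a, b)
  prof <- profile_by_subset(ev2, gates = list(
    lo = function(e) e$marker < 100, hi = function(e) e$marker >= 100))
  expect_equal(prof$glucose_dependency[prof$subset == "lo"], 50)
  expect_equal(prof$mito_dependency[prof$subset == "lo"], 75)
  expect_equal(prof$glucose_dependency[prof$subset == "hi"], 100)
  expect_equal(prof$mito_dependency[prof$subset == "hi"], 25)

  # a gate matching nothing is flagged and skipped
  none <- profile_by_subset(ev2, gates = list(none = function(e) e$marker > 1e6))
  expect_true(is.na(none$glucose_dependency))
  expect_equal(none$flags, "low_events")
})
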