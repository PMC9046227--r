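test_that("plate maps load with validation and default empty wells", {
  lay <- load_plate_layout(four_well_layout_json())
  expect_s3_class(lay, "plate_layout")
  expect_equal(nrow(lay), 96)
  expect_equal(sum(lay$role != "empty"), 4)
  expect_equal(lay$stimulus[lay$well == "A2"], "LPS")
  expect_equal(lay$role[lay$well == "B7"], "empty")
})

test_that("layout violations are rejected with the offending well named", {
  dup <- write_layout_json(data.frame(well = c("A1", "A1"),
                                      role = c("blank", "blank")))
  expect_error(load_plate_layout(dup), "duplicate well A1")
  bad_row <- write_layout_json(data.frame(well = "I1", role = "blank"))
  expect_error(load_plate_layout(bad_row), "row out of range")
  bad_col <- write_layout_json(data.frame(well = "A13", role = "blank"))
  expect_error(load_plate_layout(bad_col), "column out of range")
  no_subj <- write_layout_json(data.frame(well = "A1", role = "sample"))
  expect_error(load_plate_layout(no_subj), "subject_id and stimulus")
})

test_that("layout write/load round trip is content-identical", {
  lay <- load_plate_layout(four_well_layout_json())
  path <- tempfile(fileext = ".json")
  write_plate_layout(lay, path)
  lay2 <- load_plate_layout(path)
  expect_equal(as.data.frame(lay2), as.data.frame(lay))
  expect_equal(attr(lay2, "plate_id"), attr(lay, "plate_id"))
})

test_that("tidy measurement reader handles endpoint and kinetic tables", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("well,quantity,value", "A1,od540,0.25", "A2,od540,0.30",
               "A3,od540,0.05"), p)
  m <- read_tidy_measurements(p)
  expect_equal(nrow(m), 3)
  expect_true(all(is.na(m$time_min)))
  expect_equal(m$value, c(0.25, 0.30, 0.05))

  k <- tempfile(fileext = ".csv")
  kin <- expand.grid(well = c("A1", "A2"), time_min = seq(0, 22, by = 2))
  kin$quantity <- "rfu"; kin$value <- kin$time_min * 2
  utils::write.csv(kin[c("well", "quantity", "time_min", "value")], k,
                   row.names = FALSE)
  mk <- read_tidy_measurements(k)
  expect_equal(nrow(mk), 24)
  expect_true(all(tapply(mk$time_min, mk$well, function(t) all(diff(sort(t)) > 0))))
})

test_that("non-numeric values are reported with their line number", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("well,quantity,value", "A1,od,0.1", "A2,od,0.2", "A3,od,0.3",
               "A4,od,NA"), p)
  expect_error(read_tidy_measurements(p), "line 5")
})

test_that("join_layout annotates measurements and rejects orphan wells", {
  lay <- load_plate_layout(four_well_layout_json())
  m <- data.frame(well = c("A1", "A2"), quantity = "od",
                  time_min = NA_real_, value = c(1, 2))
  ann <- join_layout(m, lay)
  expect_equal(nrow(ann), 2)
  expect_equal(ann$stimulus, c("naive", "LPS"))
  # projection back onto the measurement columns is the identity
  expect_equal(ann[names(m)], m)

  orphan <- data.frame(well = "B7", quantity = "od", time_min = NA_real_,
                       value = 1)
  expect_error(join_layout(orphan, lay), "B7")
  empty <- m[0, ]
  expect_equal(nrow(join_layout(empty, lay)), 0)
})

test_that("instrument constants carry the XFe96 defaults and validate", {
  k <- xf_constants()
  expect_equal(k$ccf, 0.61)
  expect_equal(k$volume_chamber, 2.28)
  expect_equal(k$kvol, 1.60)
  expect_equal(k$po_ratio, 2.75)
  expect_true(is.na(k$buffer_factor))  # medium-specific, measured per assay
  expect_error(xf_constants(ccf = -1), "positive")
  expect_error(xf_constants(kvol = 0), "positive")
})

test_that("the default injection protocol defines the five phases in order", {
  expect_equal(protocol_phases(),
               c("pre_glucose", "glucose", "oligomycin", "fccp", "aa_rot"))
  proto <- default_injection_protocol()
  expect_equal(proto$injection[1], "glucose")
  expect_match(proto$final_concentration[1], "25 mM")
})
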