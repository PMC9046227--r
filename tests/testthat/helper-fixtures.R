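# small fixtures built in code, shared across test files

write_layout_json <- function(wells, path = tempfile(fileext = ".json"),
                              plate_id = "p1") {
  jsonlite::write_json(list(plate_id = plate_id, wells = wells), path,
                       auto_unbox = TRUE, digits = NA)
  path
}

four_well_layout_json <- function() {
  write_layout_json(data.frame(
    well = c("A1", "A2", "A3", "A4"),
    subject_id = c("S1", "S1", NA, NA),
    stimulus = c("naive", "LPS", NA, NA),
    role = c("sample", "sample", "blank", "standard"),
    concentration = c(NA, NA, NA, 25),
    stringsAsFactors = FALSE))
}

# single-well five-phase trace with constant values per phase
constant_phase_trace <- function(ocr = c(pre_glucose = 50, glucose = 100,
                                         oligomycin = 40, fccp = 180,
                                         aa_rot = 20),
                                 ecar = c(pre_glucose = 5, glucose = 25,
                                          oligomycin = 40, fccp = 40,
                                          aa_rot = 5),
                                 cycles = 3) {
  phases <- names(ocr)
  data.frame(well = "A1",
             time_min = seq_len(length(phases) * cycles) * 6,
             phase = rep(phases, each = cycles),
             ocr = rep(unname(ocr), each = cycles),
             ecar = rep(unname(ecar), each = cycles),
             stringsAsFactors = FALSE)
}

# event table with exact (zero-spread) condition medians for one sample
exact_scenith_events <- function(mfis = c(control = 100, DG = 10, O = 55,
                                          DGO = 10),
                                 n = 150, subject = "S1", stimulus = "naive",
                                 marker = NULL) {
  out <- do.call(rbind, lapply(names(mfis), function(cond) {
    data.frame(subject_id = subject, stimulus = stimulus, treatment = cond,
               well = "A1", puromycin = rep(mfis[[cond]], n), viable = TRUE,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(marker)) out$marker <- marker
  out
}
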