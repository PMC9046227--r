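# Build the per-cycle OCR/ECAR level profile for one well from its preset.
# FCCP OCR is peaked (max at the middle cycle) so the max-cycle summary rule
# has something to find; all other phases are flat at the preset level.
xf_phase_levels <- function(preset, cycles_per_phase) {
  k <- cycles_per_phase
  ocr <- list(
    pre_glucose = rep(preset$nonmito_ocr + preset$basal_ocr, k),
    glucose     = rep(preset$nonmito_ocr + preset$basal_ocr, k),
    oligomycin  = rep(preset$nonmito_ocr + preset$leak_ocr, k),
    fccp        = (preset$nonmito_ocr + preset$maximal_ocr) *
                    0.9^abs(seq_len(k) - min(2L, k)),
    aa_rot      = rep(preset$nonmito_ocr, k)
  )
  ecar <- list(
    pre_glucose = rep(preset$ecar_pre, k),
    glucose     = rep(preset$ecar_glucose, k),
    oligomycin  = rep(preset$ecar_oligo, k),
    fccp        = rep(preset$ecar_oligo, k),
    aa_rot      = rep(preset$ecar_pre, k)
  )
  list(ocr = ocr, ecar = ecar)
}

#' Simulate a complete extracellular-flux plate experiment
#'
#' Generates injection-responsive OCR and ECAR kinetic traces for every well
#' of a mito/glyco stress-test run, together with post-run Hoechst cell
#' counts and a ground-truth parameter table. Each well receives a plating
#' factor (lognormal, CV `noise$count_cv`) that scales both its rates and its
#' Hoechst count, so cell-count normalization can recover the preset rates; a
#' per-subject random effect (`noise$subject_sd`, log scale) emulates paired
#' mouse/donor variation; and independent multiplicative read noise
#' (`noise$well_cv`) perturbs every measurement cycle. With [noise_free()]
#' the traces step exactly to the preset phase levels.
#'
#' @param presets data.frame from [phenotype_presets()].
#' @param n_subjects number of mice/donors (each receives every stimulus).
#' @param replicates technical replicate wells per subject x stimulus.
#' @param noise a [noise_model()].
#' @param protocol an injection protocol, see [default_injection_protocol()].
#' @param cycles_per_phase measurement cycles per phase (>= 3 as in a
#'   standard run).
#' @param cycle_minutes minutes per mix+measure cycle.
#' @param nominal_count nominal Hoechst object count per well.
#' @return list with `traces` (well, time_min, phase, ocr, ecar), `counts`
#'   (well, count), `layout` ([plate_layout()]) and `truth` (per-condition
#'   ground-truth stress-test parameters).
#' @export
generate_xf_experiment <- function(presets = phenotype_presets(),
                                   n_subjects = 6, replicates = 3,
                                   noise = noise_model(),
                                   protocol = default_injection_protocol(),
                                   cycles_per_phase = 3,
                                   cycle_minutes = 6,
                                   nominal_count = 2e4) {
  if (cycles_per_phase < 3) stop("a standard run has >= 3 measurement cycles per phase")
  n_wells <- nrow(presets) * n_subjects * replicates
  if (n_wells > 96) {
    stop("capacity: ", n_wells, " wells requested but a plate has 96 ",
         "(conditions x subjects x replicates must fit one plate)")
  }
  set.seed(noise$seed)
  phases <- protocol_phases(protocol)

  grid <- expand.grid(replicate = seq_len(replicates),
                      subject_id = paste0("S", seq_len(n_subjects)),
                      stimulus = presets$name,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$well <- all_wells()[seq_len(nrow(grid))]
  layout <- plate_layout(grid[, c("well", "subject_id", "stimulus", "replicate")],
                         plate_id = "xf_plate")

  subj_eff <- subject_effects(grid$subject_id, noise$subject_sd)
  plating <- lognorm_factor(nrow(grid), noise$count_cv)
  counts <- data.frame(well = grid$well,
                       count = round(nominal_count * plating))

  n_cycles <- length(phases) * cycles_per_phase
  times <- seq_len(n_cycles) * cycle_minutes
  phase_vec <- rep(phases, each = cycles_per_phase)

  traces <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    preset <- presets[presets$name == grid$stimulus[i], ]
    lev <- xf_phase_levels(preset, cycles_per_phase)
    scale_i <- subj_eff[[grid$subject_id[i]]] * plating[i]
    traces[[i]] <- data.frame(
      well = grid$well[i], time_min = times, phase = phase_vec,
      ocr = unlist(lev$ocr, use.names = FALSE) * scale_i *
        lognorm_factor(n_cycles, noise$well_cv),
      ecar = unlist(lev$ecar, use.names = FALSE) * scale_i *
        lognorm_factor(n_cycles, noise$well_cv),
      stringsAsFactors = FALSE
    )
  }
  traces <- do.call(rbind, traces)

  truth <- data.frame(
    stimulus = presets$name,
    basal_respiration = presets$basal_ocr,
    maximal_respiration = presets$maximal_ocr,
    spare_capacity = presets$maximal_ocr - presets$basal_ocr,
    atp_linked_respiration = presets$basal_ocr - presets$leak_ocr,
    proton_leak = presets$leak_ocr,
    nonmito_ocr = presets$nonmito_ocr,
    basal_ocr_total = presets$nonmito_ocr + presets$basal_ocr,
    nonglycolytic_acidification = presets$ecar_pre,
    glycolysis = presets$ecar_glucose - presets$ecar_pre,
    glycolytic_capacity = presets$ecar_oligo - presets$ecar_pre,
    glycolytic_reserve = presets$ecar_oligo - presets$ecar_glucose,
    stringsAsFactors = FALSE
  )
  list(traces = traces, counts = counts, layout = layout, truth = truth)
}
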