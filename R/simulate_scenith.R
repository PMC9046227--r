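SCENITH_CONDITIONS <- c("control", "DG", "O", "DGO", "H")

# Condition-level true puromycin medians implied by a preset's dependencies.
# Constructed so the dependency algebra inverts exactly:
#   glucose_dependency = 100 (C - DG) / (C - DGO)
#   mito_dependency    = 100 (C - O)  / (C - DGO)
scenith_condition_medians <- function(preset) {
  ctrl <- preset$scenith_control_mfi
  dgo <- preset$scenith_floor_mfi
  c(control = ctrl,
    DG = ctrl - preset$glucose_dependency / 100 * (ctrl - dgo),
    O = ctrl - preset$mito_dependency / 100 * (ctrl - dgo),
    DGO = dgo,
    H = preset$scenith_h_mfi)
}

#' Simulate a SCENITH experiment (inhibitor-conditioned puromycin events)
#'
#' For every phenotype x subject x inhibitor condition (control, DG, O, DGO,
#' H) one well of per-cell puromycin intensities is generated, lognormally
#' spread around the condition's true median. Viable-event draws are
#' median-centred, so the sample median of viable events equals the true
#' median exactly and the dependency algebra inverts exactly at zero
#' plate noise; this is the generator's testability contract. A preset dead
#' fraction of events carries `viable = FALSE` and depressed intensities.
#' Well noise (`noise$well_cv`) scales each well's median; the subject effect
#' (`noise$subject_sd`) scales all wells of a subject together and therefore
#' cancels from the (scale-invariant) dependency parameters.
#'
#' @param presets data.frame from [phenotype_presets()].
#' @param n_subjects number of mice/donors.
#' @param events_per_well viable+dead flow events acquired per well; values
#'   below 100 trigger a warning (median unstable).
#' @param noise a [noise_model()].
#' @param event_sigma lognormal sigma of the per-cell intensity spread.
#' @param conditions inhibitor conditions to generate.
#' @return list with `events` (subject_id, stimulus, treatment, well,
#'   puromycin, viable), one synthetic plate per subject, and `truth`
#'   (per-stimulus preset dependencies and capacities).
#' @export
generate_scenith_experiment <- function(presets = phenotype_presets(),
                                        n_subjects = 6,
                                        events_per_well = 5000,
                                        noise = noise_model(),
                                        event_sigma = 0.5,
                                        conditions = SCENITH_CONDITIONS) {
  if (events_per_well < 100) {
    warning("fewer than 100 events per well: median estimates will be unstable")
  }
  conditions <- match.arg(conditions, SCENITH_CONDITIONS, several.ok = TRUE)
  set.seed(noise$seed)
  subjects <- paste0("S", seq_len(n_subjects))
  subj_eff <- subject_effects(subjects, noise$subject_sd)

  grid <- expand.grid(treatment = conditions, stimulus = presets$name,
                      subject_id = subjects,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # one synthetic plate per subject; wells row-major within it
  per_subject <- nrow(presets) * length(conditions)
  if (per_subject > 96) stop("capacity: more than 96 wells per subject plate")
  grid$well <- all_wells()[rep(seq_len(per_subject), n_subjects)]

  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    preset <- presets[presets$name == grid$stimulus[i], ]
    med <- scenith_condition_medians(preset)[[grid$treatment[i]]]
    med_well <- med * subj_eff[[grid$subject_id[i]]] *
      lognorm_factor(1, noise$well_cv)
    n_dead <- round(events_per_well * preset$dead_fraction)
    n_viable <- events_per_well - n_dead
    viable_int <- exp(event_sigma * stats::rnorm(n_viable))
    # rescale so the viable-event sample median equals med_well exactly:
    # the inversion contract of the dependency algebra
    viable_int <- viable_int * (med_well / stats::median(viable_int))
    dead_int <- med_well * 0.2 * exp(event_sigma * stats::rnorm(n_dead))
    out[[i]] <- data.frame(
      subject_id = grid$subject_id[i], stimulus = grid$stimulus[i],
      treatment = grid$treatment[i], well = grid$well[i],
      puromycin = c(viable_int, dead_int),
      viable = rep(c(TRUE, FALSE), c(n_viable, n_dead)),
      stringsAsFactors = FALSE
    )
  }
  truth <- data.frame(
    stimulus = presets$name,
    glucose_dependency = presets$glucose_dependency,
    mito_dependency = presets$mito_dependency,
    glycolytic_capacity = 100 - presets$mito_dependency,
    faao_capacity = 100 - presets$glucose_dependency,
    stringsAsFactors = FALSE
  )
  list(events = do.call(rbind, out), truth = truth)
}
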