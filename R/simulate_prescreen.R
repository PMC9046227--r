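# Instrument-law constants for the synthetic pre-screening assays. Slopes and
# backgrounds are arbitrary-but-fixed plate-reader calibrations; the analysis
# stages must recover concentrations without knowing them.
PRESCREEN_LAWS <- list(
  griess  = list(blank_od = 0.05, slope = 0.005,            # OD per uM nitrite
                 standards_um = c(0, 6.25, 12.5, 25, 50, 100)),
  glucose = list(slope = 0.1, standard_mm = 5, medium_mm = 10),  # OD per mM
  urea    = list(blank_od = 0.04, slope = 0.25,             # OD per mM urea
                 standards_mm = c(0, 0.25, 0.5, 1, 2, 4)),
  lactate = list(background = 1000, slope = 100,            # RFU per mM
                 standards_mm = c(0, 1, 2.5, 5, 10),
                 n_background_cycles = 5, n_post_cycles = 15,
                 cycle_min = 2, ramp_min = 10)
)

# lag/ramp/plateau NADH-formation kinetics reaching exactly background+A
nadh_trace <- function(amplitude, law) {
  t_bg <- (seq_len(law$n_background_cycles) - 1L) * law$cycle_min
  t_post <- max(t_bg) + seq_len(law$n_post_cycles) * law$cycle_min
  frac <- pmin((t_post - t_post[1]) / law$ramp_min, 1)
  data.frame(time_min = c(t_bg, t_post),
             value = c(rep(law$background, length(t_bg)),
                       law$background + amplitude * frac))
}

#' Simulate the four pre-screening assay plates
#'
#' Generates endpoint absorbance tables for the Griess nitrite, GOD-PAP
#' glucose-consumption and urea (arginase) assays and NADH-formation kinetic
#' fluorescence traces for the lactate assay, each on its own plate with
#' standard and blank wells. Standards follow linear signal-concentration
#' laws; the NADH kinetics rise monotonically to a plateau proportional to
#' lactate. Subject effects and well noise multiply the underlying analyte
#' concentration, so zero-noise plates are quantified back to the preset
#' concentrations exactly.
#'
#' @param presets data.frame from [phenotype_presets()].
#' @param n_subjects,replicates design size (samples per stimulus).
#' @param noise a [noise_model()].
#' @param standards named list overriding the default standard series, e.g.
#'   `list(griess = c(0, 25, 50))`. An empty standard series is an error:
#'   quantification would be impossible downstream.
#' @return list with one element per assay (`griess`, `glucose`, `urea`,
#'   `lactate`), each holding a tidy `measurements` table and a `layout`,
#'   plus a `truth` table of preset concentrations (and the implied arginase
#'   activity at the default 100 ul lysate / 10 ul tested / 60 min assay).
#' @export
generate_prescreen_plate <- function(presets = phenotype_presets(),
                                     n_subjects = 6, replicates = 3,
                                     noise = noise_model(),
                                     standards = list()) {
  laws <- PRESCREEN_LAWS
  if (!is.null(standards$griess)) laws$griess$standards_um <- standards$griess
  if (!is.null(standards$urea)) laws$urea$standards_mm <- standards$urea
  if (!is.null(standards$lactate)) laws$lactate$standards_mm <- standards$lactate
  for (a in c("griess", "urea", "lactate")) {
    s <- laws[[a]][[grep("standards", names(laws[[a]]), value = TRUE)]]
    if (length(s) < 2) stop(a, ": at least two standard wells are required, ",
                            "quantification is impossible without them")
  }
  set.seed(noise$seed)
  subjects <- paste0("S", seq_len(n_subjects))
  subj_eff <- subject_effects(subjects, noise$subject_sd)

  samples <- expand.grid(replicate = seq_len(replicates), subject_id = subjects,
                         stimulus = presets$name,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_s <- nrow(samples)
  wells <- all_wells()
  # true per-well analyte concentrations (shared plating of the culture plate
  # is irrelevant here: supernatant concentration, not signal, varies)
  conc_well <- function(column) {
    presets[[column]][match(samples$stimulus, presets$name)] *
      unlist(subj_eff[samples$subject_id]) * lognorm_factor(n_s, noise$well_cv)
  }

  build_layout <- function(std_conc, n_blank, plate_id) {
    n_extra <- length(std_conc) + n_blank
    if (n_s + n_extra > 96) {
      stop("capacity: ", n_s + n_extra, " wells requested for ", plate_id,
           " but a plate has 96")
    }
    lay <- data.frame(well = wells[seq_len(n_s)],
                      subject_id = samples$subject_id,
                      stimulus = samples$stimulus,
                      replicate = samples$replicate,
                      role = "sample", concentration = NA_real_,
                      stringsAsFactors = FALSE)
    extra <- data.frame(
      well = wells[n_s + seq_len(n_extra)],
      subject_id = NA_character_, stimulus = NA_character_,
      replicate = NA_integer_,
      role = rep(c("standard", "blank"), c(length(std_conc), n_blank)),
      concentration = c(std_conc, rep(NA_real_, n_blank)),
      stringsAsFactors = FALSE)
    plate_layout(rbind(lay, extra), plate_id = plate_id)
  }
  endpoint_tbl <- function(layout, od, quantity) {
    keep <- layout$role != "empty"
    data.frame(well = layout$well[keep], quantity = quantity,
               time_min = NA_real_, value = od, stringsAsFactors = FALSE)
  }
  rd <- function(n) lognorm_factor(n, noise$well_cv)  # read noise on standards

  # --- Griess nitrite (OD540) ---
  g <- laws$griess
  lay_g <- build_layout(g$standards_um, 3, "griess_plate")
  od_g <- c(g$blank_od + g$slope * conc_well("nitrite_um"),
            g$blank_od + g$slope * g$standards_um * rd(length(g$standards_um)),
            rep(g$blank_od, 3))
  griess <- list(measurements = endpoint_tbl(lay_g, od_g, "od540"), layout = lay_g)

  # --- GOD-PAP glucose (OD490); "standard" wells carry the 5 mM standard,
  #     "blank" wells carry cell-free medium ---
  gl <- laws$glucose
  lay_gl <- build_layout(rep(gl$standard_mm, 3), 3, "glucose_plate")
  remaining <- pmax(gl$medium_mm - conc_well("glucose_consumed_mm"), 0)
  od_gl <- c(gl$slope * remaining,
             gl$slope * gl$standard_mm * rd(3),
             gl$slope * gl$medium_mm * rd(3))
  glucose <- list(measurements = endpoint_tbl(lay_gl, od_gl, "od490"),
                  layout = lay_gl, medium_mm = gl$medium_mm)

  # --- urea for arginase (OD540) ---
  u <- laws$urea
  lay_u <- build_layout(u$standards_mm, 3, "urea_plate")
  od_u <- c(u$blank_od + u$slope * conc_well("urea_mm"),
            u$blank_od + u$slope * u$standards_mm * rd(length(u$standards_mm)),
            rep(u$blank_od, 3))
  urea <- list(measurements = endpoint_tbl(lay_u, od_u, "od540"), layout = lay_u)

  # --- lactate via NADH-formation kinetics (RFU) ---
  l <- laws$lactate
  lay_l <- build_layout(l$standards_mm, 0, "lactate_plate")
  lact_mm <- conc_well("lactate_mm")
  amp <- c(l$slope * lact_mm, l$slope * l$standards_mm * rd(length(l$standards_mm)))
  kin_wells <- lay_l$well[lay_l$role != "empty"]
  kin <- do.call(rbind, lapply(seq_along(kin_wells), function(i) {
    tr <- nadh_trace(amp[i], l)
    data.frame(well = kin_wells[i], quantity = "nadh_rfu",
               time_min = tr$time_min, value = tr$value, stringsAsFactors = FALSE)
  }))
  lactate <- list(measurements = kin, layout = lay_l,
                  n_background_cycles = l$n_background_cycles)

  truth <- data.frame(
    stimulus = presets$name,
    nitrite_um = presets$nitrite_um,
    glucose_consumed_mm = presets$glucose_consumed_mm,
    lactate_mm = presets$lactate_mm,
    urea_mm = presets$urea_mm,
    arginase_activity = arginase_activity(presets$urea_mm),
    stringsAsFactors = FALSE
  )
  list(griess = griess, glucose = glucose, urea = urea, lactate = lactate,
       truth = truth)
}
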