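#' Ground-truth phenotype presets for the synthetic plate generators
#'
#' One row per macrophage activation state (naive, LPS, LPS+IFNg, IL4) holding
#' every ground-truth quantity the generators need: stress-test OCR/ECAR
#' parameters (pmol O2/min and mpH/min per well scales), SCENITH glucose and
#' mitochondrial dependencies (percent), translation-level MFIs, probe uptake
#' MFIs, and supernatant analyte concentrations.
#'
#' The numeric values are package defaults chosen to encode the qualitative
#' biology of classical vs alternative activation: M(LPS+/-IFNg) shift toward
#' glycolysis (high ECAR, high glucose dependency, suppressed respiration,
#' high NO/nitrite), while M(IL-4) upregulate mitochondrial respiration and
#' spare capacity, arginase and fatty-acid probe uptake.
#'
#' @param names subset of phenotypes to return.
#' @return data.frame, one row per phenotype.
#' @export
phenotype_presets <- function(names = c("naive", "LPS", "LPS+IFNg", "IL4")) {
  p <- data.frame(
    name = c("naive", "LPS", "LPS+IFNg", "IL4"),
    # OCR stress-test truth (all corrected for non-mito except nonmito itself)
    nonmito_ocr   = c(20,  20,  25,  20),
    basal_ocr     = c(80,  50,  40, 100),
    maximal_ocr   = c(160, 60,  45, 250),
    leak_ocr      = c(20,  15,  12,  25),
    # ECAR stress-test truth
    ecar_pre      = c(5,   8,  10,   5),   # non-glycolytic acidification
    ecar_glucose  = c(25,  53,  70,  20),
    ecar_oligo    = c(40,  68,  85,  35),
    # SCENITH truth (percent) and translation MFIs
    glucose_dependency = c(40, 65, 75, 30),
    mito_dependency    = c(60, 30, 20, 75),
    scenith_control_mfi = c(8000, 9000, 9500, 8500),
    scenith_floor_mfi   = c(1000, 1000, 1000, 1000),  # DGO level
    scenith_h_mfi       = c(900,  900,  900,  900),   # harringtonine background
    dead_fraction       = c(0.05, 0.08, 0.10, 0.05),
    # fluorescent probe delta-MFI truth (arbitrary units)
    nbdg_mfi       = c(2000, 3500, 4500, 1800),
    bodipy_mfi     = c(1500, 1200, 1000, 3000),
    mitotracker_mfi = c(3000, 2500, 2200, 5000),
    tmrm_mfi       = c(2500, 2000, 1800, 4500),
    # supernatant / lysate chemistry truth
    nitrite_um          = c(2,  25,  40,  1),
    glucose_consumed_mm = c(3,   6,   8,  4),
    lactate_mm          = c(2,   6,   8,  3),
    urea_mm             = c(0.4, 0.2, 0.1, 2),
    stringsAsFactors = FALSE
  )
  unknown <- setdiff(names, p$name)
  if (length(unknown)) stop("unknown phenotype(s): ", paste(unknown, collapse = ", "))
  out <- p[match(names, p$name), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(out$maximal_ocr >= 0), all(out$glucose_dependency >= 0 & out$glucose_dependency <= 100),
            all(out$mito_dependency >= 0 & out$mito_dependency <= 100))
  out
}

#' Noise model for synthetic plate experiments
#'
#' Three variance components, all optional:
#' \describe{
#'   \item{well_cv}{multiplicative lognormal coefficient of variation applied
#'     independently to each measurement (technical/read noise).}
#'   \item{subject_sd}{SD of a per-subject random effect on the log scale,
#'     shared by all wells of that subject (mouse/donor variation; motivates
#'     the paired statistics).}
#'   \item{count_cv}{lognormal CV of the per-well plating factor, which scales
#'     both the Hoechst cell count and all rates of the well. Plating is the
#'     dominant component on real plates, which is what makes cell-count
#'     normalization worthwhile.}
#' }
#' With all CVs zero the generators are exact: every analysis stage inverts
#' them to the preset ground truth.
#'
#' @param well_cv,subject_sd,count_cv non-negative numbers.
#' @param seed integer RNG seed; identical seeds give bit-identical plates.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(well_cv = 0.05, subject_sd = 0.05, count_cv = 0.15,
                        seed = 1L) {
  stopifnot(well_cv >= 0, subject_sd >= 0, count_cv >= 0)
  structure(list(well_cv = well_cv, subject_sd = subject_sd,
                 count_cv = count_cv, seed = as.integer(seed)),
            class = "noise_model")
}

#' Zero-noise model (exact ground truth)
#' @param seed RNG seed (only consumed by structural randomness, none by noise).
#' @return A [noise_model()] with all CVs zero.
#' @export
noise_free <- function(seed = 1L) noise_model(0, 0, 0, seed)

# lognormal factor with unit median and given CV
lognorm_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2))))
}

# per-subject multiplicative effects, unit median
subject_effects <- function(subject_ids, sd) {
  u <- unique(subject_ids)
  eff <- if (sd <= 0) rep(1, length(u)) else exp(stats::rnorm(length(u), 0, sd))
  names(eff) <- u
  eff
}
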