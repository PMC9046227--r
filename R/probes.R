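# probe -> validation-inhibitor pairing; hard-coded to prevent silent misuse
PROBE_INHIBITORS <- c(
  "2nbdg" = "phloretin",        # glucose-uptake probe vs glucose-transport inhibitor
  "bodipyc16" = "lipofermata",  # fatty-acid-uptake probe vs FATP2 inhibitor
  "mitotrackergreen" = "fccp",  # mitochondrial mass probe vs uncoupler
  "tmrm" = "fccp"               # membrane-potential probe vs uncoupler
)

normalize_probe_name <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(x))
  key <- sub("^2nbdg$|^nbdg$", "2nbdg", key)
  key <- sub("^bodipy(fl)?c?16?$", "bodipyc16", key)
  key <- sub("^mitotracker(green)?$", "mitotrackergreen", key)
  key
}

#' Delta-MFI of a fluorescent metabolic probe
#'
#' `delta_mfi = MFI(sample) - MFI(unstained control)`. Negative values
#' (sample below the unstained control) are reported, not truncated, and
#' flagged.
#'
#' @param sample_mfi,unstained_mfi non-negative MFIs (vectorized).
#' @return data.frame with `delta_mfi` and `flag`.
#' @export
delta_mfi <- function(sample_mfi, unstained_mfi) {
  if (any(sample_mfi < 0) || any(unstained_mfi < 0)) stop("MFIs must be non-negative")
  d <- sample_mfi - unstained_mfi
  data.frame(delta_mfi = d, flag = ifelse(d < 0, "negative", ""),
             stringsAsFactors = FALSE)
}

#' Validate probe specificity with its paired inhibitor
#'
#' The probe signal must be suppressible by its specific transport/function
#' inhibitor (2NB-DG by phloretin, BODIPY C16 by lipofermata,
#' MitoTracker Green and TMRM by FCCP), confirming that the staining
#' concentration is not so high that uptake is unspecific.
#' `fraction_inhibited = 1 - delta_mfi(inhibited) / delta_mfi(uninhibited)`;
#' the check passes when the fraction reaches `threshold`.
#'
#' @param probe probe name (matching is forgiving about case/punctuation).
#' @param inhibitor inhibitor name; must be the probe's validation partner.
#' @param uninhibited_dmfi,inhibited_dmfi delta-MFIs without/with inhibitor;
#'   the uninhibited value must be positive.
#' @param threshold minimum inhibited fraction to pass (default 0.2).
#' @return list with `fraction_inhibited` and logical `pass`.
#' @export
inhibitor_validation <- function(probe, inhibitor, uninhibited_dmfi,
                                 inhibited_dmfi, threshold = 0.2) {
  key <- normalize_probe_name(probe)
  if (!key %in% names(PROBE_INHIBITORS)) stop("unknown probe: ", probe)
  expected <- PROBE_INHIBITORS[[key]]
  if (tolower(gsub("[^A-Za-z0-9]", "", inhibitor)) != expected) {
    stop("probe '", probe, "' must be validated with ", expected,
         ", not ", inhibitor)
  }
  if (uninhibited_dmfi <= 0) stop("uninhibited delta-MFI must be positive")
  fraction <- 1 - inhibited_dmfi / uninhibited_dmfi
  list(fraction_inhibited = fraction, pass = fraction >= threshold)
}

#' Is MitoTracker staining independent of membrane potential?
#'
#' A mitochondrial-mass probe should be insensitive to dissipating the
#' membrane potential: if FCCP co-treatment changes the MitoTracker
#' delta-MFI by more than `tolerance` (relative), the staining is flagged as
#' potential-dependent and should not be read as pure mass.
#'
#' @param mitotracker_dmfi delta-MFI without FCCP (baseline).
#' @param mitotracker_fccp_dmfi delta-MFI with FCCP co-treatment.
#' @param tolerance relative change tolerated (default 0.10).
#' @return list with `verdict` (`"independent"`, `"potential_dependent"` or
#'   `"indeterminate"` when the baseline is 0) and `relative_change`.
#' @export
potential_independence_check <- function(mitotracker_dmfi,
                                         mitotracker_fccp_dmfi,
                                         tolerance = 0.10) {
  if (mitotracker_dmfi < 0 || mitotracker_fccp_dmfi < 0) {
    stop("delta-MFIs must be non-negative")
  }
  if (mitotracker_dmfi == 0) {
    return(list(verdict = "indeterminate", relative_change = NA_real_))
  }
  rel <- abs(mitotracker_fccp_dmfi - mitotracker_dmfi) / mitotracker_dmfi
  list(verdict = if (rel <= tolerance) "independent" else "potential_dependent",
       relative_change = rel)
}
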