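#' Instrument constants for extracellular-flux ATP-rate calculations
#'
#' Bundles the XFe96 constants entering the proton-efflux-rate and ATP
#' production-rate equations. Defaults are the manufacturer-determined values
#' for XFe96 plates: CO2 contribution factor (CCF) 0.61, measurement-chamber
#' volume 2.28 ul, volume scaling factor Kvol 1.60, and P/O ratio 2.75 ADP per
#' oxygen atom. The buffer factor (mM/pH, protons needed to shift the assay
#' medium by one pH unit) is medium-specific, must be measured per experiment,
#' and therefore has no default.
#'
#' @param ccf CO2 contribution factor (dimensionless).
#' @param volume_chamber effective measurement-chamber volume, ul.
#' @param kvol volume scaling factor (dimensionless).
#' @param po_ratio ADP molecules phosphorylated per oxygen atom.
#' @param buffer_factor buffer factor of the assay medium, mM/pH. `NA` until
#'   supplied; [atp_rates()] refuses to run without it.
#' @return An object of class `xf_constants` (named list).
#' @examples
#' xf_constants(buffer_factor = 2.4)
#' @export
xf_constants <- function(ccf = 0.61, volume_chamber = 2.28, kvol = 1.60,
                         po_ratio = 2.75, buffer_factor = NA_real_) {
  num1 <- function(x, nm, allow_na = FALSE) {
    if (length(x) != 1L || !is.numeric(x)) stop(nm, " must be a single number")
    if (is.na(x)) {
      if (!allow_na) stop(nm, " must not be NA")
    } else if (x <= 0) stop(nm, " must be strictly positive")
    as.numeric(x)
  }
  structure(list(
    ccf = num1(ccf, "ccf"),
    volume_chamber = num1(volume_chamber, "volume_chamber"),
    kvol = num1(kvol, "kvol"),
    po_ratio = num1(po_ratio, "po_ratio"),
    buffer_factor = num1(buffer_factor, "buffer_factor", allow_na = TRUE)
  ), class = "xf_constants")
}

#' @export
print.xf_constants <- function(x, ...) {
  cat("XFe96 constants:\n")
  cat(sprintf("  CCF                  %g\n", x$ccf))
  cat(sprintf("  chamber volume (ul)  %g\n", x$volume_chamber))
  cat(sprintf("  Kvol                 %g\n", x$kvol))
  cat(sprintf("  P/O ratio            %g\n", x$po_ratio))
  cat(sprintf("  buffer factor (mM/pH) %s\n",
              if (is.na(x$buffer_factor)) "<not set>" else format(x$buffer_factor)))
  invisible(x)
}

#' Default mito/glyco stress-test injection protocol
#'
#' The four-injection sequence used throughout: glucose (25 mM final),
#' oligomycin (1.5 uM), FCCP (1.5 uM), then antimycin A (2.5 uM) + rotenone
#' (1.25 uM) + Hoechst 33342 (5 ug/ml). Together with the pre-injection
#' baseline this defines five measurement phases:
#' `pre_glucose, glucose, oligomycin, fccp, aa_rot`.
#'
#' @return An `injection_protocol`: data.frame with columns `injection`,
#'   `phase`, `final_concentration`, `units`.
#' @export
default_injection_protocol <- function() {
  proto <- data.frame(
    injection = c("glucose", "oligomycin", "FCCP", "antimycinA+rotenone+Hoechst"),
    phase = c("glucose", "oligomycin", "fccp", "aa_rot"),
    final_concentration = c("25 mM", "1.5 uM", "1.5 uM", "2.5 uM + 1.25 uM + 5 ug/ml"),
    stringsAsFactors = FALSE
  )
  structure(proto, class = c("injection_protocol", "data.frame"))
}

#' Measurement phases implied by an injection protocol
#'
#' @param protocol an `injection_protocol`.
#' @return Character vector of phase names, baseline first.
#' @export
protocol_phases <- function(protocol = default_injection_protocol()) {
  if (anyDuplicated(protocol$injection)) stop("injection names must be unique")
  c("pre_glucose", protocol$phase)
}
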