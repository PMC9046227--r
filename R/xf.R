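#' Segment an extracellular-flux trace into per-phase summaries
#'
#' Collapses the measurement cycles of each injection phase to a single OCR
#' and ECAR value per phase. The default summary is the last cycle of the
#' phase (the steady-state convention of vendor analysis tools); optionally
#' the phase mean. For the FCCP phase the OCR summary is the maximum cycle
#' (default on), since maximal respiration is read at the uncoupling peak.
#'
#' @param trace single-well data.frame with columns `time_min`, `phase`,
#'   `ocr`, `ecar` (times strictly increasing; phase labels contiguous
#'   blocks in protocol order).
#' @param protocol an injection protocol; see [default_injection_protocol()].
#' @param summary `"last"` or `"mean"`.
#' @param fccp_max use the maximum OCR cycle for the FCCP phase.
#' @return data.frame with one row per phase: `phase`, `ocr`, `ecar`.
#' @export
segment_phases <- function(trace, protocol = default_injection_protocol(),
                           summary = c("last", "mean"), fccp_max = TRUE) {
  summary <- match.arg(summary)
  phases <- protocol_phases(protocol)
  trace <- trace[order(trace$time_min), , drop = FALSE]
  if (any(diff(trace$time_min) <= 0)) stop("trace times must be strictly increasing")
  missing <- setdiff(phases, unique(trace$phase))
  if (length(missing)) stop("phase ", paste(missing, collapse = ", "), " absent")
  # phase labels must form contiguous blocks in protocol order
  runs <- rle(as.character(trace$phase))$values
  if (!identical(runs[runs %in% phases], phases)) {
    stop("phase labels must form contiguous blocks in protocol order: ",
         paste(phases, collapse = " -> "))
  }
  one <- function(v, phase) {
    if (phase == "fccp" && fccp_max) return(max(v))
    if (summary == "last") v[length(v)] else mean(v)
  }
  out <- do.call(rbind, lapply(phases, function(p) {
    sub <- trace[trace$phase == p, , drop = FALSE]
    data.frame(phase = p, ocr = one(sub$ocr, p),
               ecar = if (summary == "last") sub$ecar[nrow(sub)] else mean(sub$ecar),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Normalize flux rates to Hoechst cell counts
#'
#' `normalized = rate / (count_well / mean(count over included wells))`, the
#' post-run Hoechst normalization that corrects well-to-well plating
#' differences. Wells with zero or missing counts are excluded (values NA)
#' with a warning listing them.
#'
#' @param rates numeric vector (or all-numeric data.frame/matrix of rate
#'   columns) per well.
#' @param hoechst_counts numeric count per well, aligned with `rates` rows.
#' @return Normalized rates of the same shape, with attribute
#'   `excluded_wells` (integer indices of excluded wells).
#' @export
normalize_rates <- function(rates, hoechst_counts) {
  n <- if (is.null(dim(rates))) length(rates) else nrow(rates)
  if (length(hoechst_counts) != n) stop("counts must align with rates")
  ok <- !is.na(hoechst_counts) & hoechst_counts > 0
  if (!any(ok)) stop("no wells with positive counts")
  if (!all(ok)) {
    warning("excluding ", sum(!ok), " well(s) with zero/missing counts: ",
            paste(which(!ok), collapse = ", "))
  }
  factor <- hoechst_counts / mean(hoechst_counts[ok])
  factor[!ok] <- NA_real_
  out <- if (is.null(dim(rates))) rates / factor else rates / factor
  attr(out, "excluded_wells") <- which(!ok)
  out
}

floor_flag <- function(x, name, flags) {
  if (!is.na(x) && x < 0) list(value = 0, flags = c(flags, paste0(name, "_floored")))
  else list(value = x, flags = flags)
}

#' Mitochondrial stress-test parameters from phase summaries
#'
#' Standard mito stress-test algebra on the phase OCRs: non-mitochondrial
#' respiration is the rotenone/antimycin-A plateau; basal and maximal
#' respiration are the glucose-phase and FCCP-phase OCRs corrected for it;
#' ATP-linked respiration is the oligomycin drop; proton leak the
#' oligomycin-phase OCR above non-mitochondrial. Negative derived values are
#' floored at 0 and flagged. Both the corrected basal respiration and the
#' uncorrected glucose-phase OCR (`basal_ocr_total`, needed by
#' [atp_rates()]) are returned.
#'
#' @param phases data.frame from [segment_phases()].
#' @return one-row data.frame of OCR parameters plus a `flags` string.
#' @export
mito_parameters <- function(phases) {
  p <- function(name) {
    v <- phases$ocr[phases$phase == name]
    if (!length(v)) stop("phase ", name, " absent")
    v
  }
  nonmito <- p("aa_rot")
  flags <- character(0)
  res <- list(
    basal_respiration = p("glucose") - nonmito,
    maximal_respiration = p("fccp") - nonmito,
    atp_linked_respiration = p("glucose") - p("oligomycin"),
    proton_leak = p("oligomycin") - nonmito,
    nonmito_ocr = nonmito,
    basal_ocr_total = p("glucose")
  )
  for (nm in c("basal_respiration", "maximal_respiration",
               "atp_linked_respiration", "proton_leak")) {
    ff <- floor_flag(res[[nm]], nm, flags)
    res[[nm]] <- ff$value; flags <- ff$flags
  }
  res$spare_capacity <- res$maximal_respiration - res$basal_respiration
  ff <- floor_flag(res$spare_capacity, "spare_capacity", flags)
  res$spare_capacity <- ff$value; flags <- ff$flags
  data.frame(res[c("basal_respiration", "maximal_respiration", "spare_capacity",
                   "atp_linked_respiration", "proton_leak", "nonmito_ocr",
                   "basal_ocr_total")],
             flags = paste(ff$flags, collapse = ","), stringsAsFactors = FALSE)
}

#' Glycolysis stress-test parameters from phase summaries
#'
#' Standard glycolysis stress-test algebra on the phase ECARs:
#' non-glycolytic acidification is the pre-glucose ECAR; glycolysis the
#' glucose response above it; glycolytic capacity the oligomycin ECAR above
#' it; reserve the capacity minus glycolysis. Negative values floored at 0
#' with flags.
#'
#' @param phases data.frame from [segment_phases()].
#' @return one-row data.frame of ECAR parameters plus a `flags` string.
#' @export
glyco_parameters <- function(phases) {
  e <- function(name) {
    v <- phases$ecar[phases$phase == name]
    if (!length(v)) stop("phase ", name, " absent")
    v
  }
  nonglyco <- e("pre_glucose")
  flags <- character(0)
  res <- list(
    glycolysis = e("glucose") - nonglyco,
    glycolytic_capacity = e("oligomycin") - nonglyco,
    nonglycolytic_acidification = nonglyco
  )
  for (nm in c("glycolysis", "glycolytic_capacity")) {
    ff <- floor_flag(res[[nm]], nm, flags)
    res[[nm]] <- ff$value; flags <- ff$flags
  }
  res$glycolytic_reserve <- res$glycolytic_capacity - res$glycolysis
  ff <- floor_flag(res$glycolytic_reserve, "glycolytic_reserve", flags)
  res$glycolytic_reserve <- ff$value
  data.frame(res[c("glycolysis", "glycolytic_capacity", "glycolytic_reserve",
                   "nonglycolytic_acidification")],
             flags = paste(ff$flags, collapse = ","), stringsAsFactors = FALSE)
}

#' ATP production-rate decomposition from OCR and ECAR
#'
#' The proton-efflux / ATP-rate equations with XFe96 constants:
#' \deqn{mitoPER = CCF (OCR_{basal} - OCR_{Rot/AA})}
#' \deqn{totalPER = ECAR \cdot BF \cdot Vol_{chamber} \cdot K_{vol}}
#' \deqn{glycoATP = glycoPER = totalPER - mitoPER}
#' \deqn{mitoATP = (OCR_{basal} - OCR_{Rot/AA}) \cdot 2 \cdot P/O}
#' \deqn{totalATP = glycoATP + mitoATP}
#' `OCR_basal` is the uncorrected glucose-phase OCR (the equation subtracts
#' only the rotenone/antimycin-A OCR); the ECAR is the glucose-phase (basal)
#' ECAR. A negative glycoPER usually signals a misconfigured buffer factor
#' and is flagged, never floored.
#'
#' @param basal_ocr_total uncorrected glucose-phase OCR (pmol O2/min).
#' @param aa_rot_ocr rotenone/antimycin-A phase OCR.
#' @param ecar basal (glucose-phase) ECAR (mpH/min).
#' @param constants an [xf_constants()]; `buffer_factor` must be set.
#' @return data.frame with `mito_per`, `total_per`, `glyco_per`,
#'   `glyco_atp`, `mito_atp`, `total_atp` and `flags` (vectorized).
#' @examples
#' atp_rates(20.5, 20, 1, xf_constants(buffer_factor = 0.625))
#' @export
atp_rates <- function(basal_ocr_total, aa_rot_ocr, ecar,
                      constants = xf_constants()) {
  stopifnot(inherits(constants, "xf_constants"))
  if (is.na(constants$buffer_factor)) {
    stop("buffer_factor is not set in xf_constants(); it must be measured ",
         "per assay medium")
  }
  d_ocr <- basal_ocr_total - aa_rot_ocr
  mito_per <- constants$ccf * d_ocr
  total_per <- ecar * constants$buffer_factor * constants$volume_chamber *
    constants$kvol
  glyco_per <- total_per - mito_per
  mito_atp <- d_ocr * 2 * constants$po_ratio
  data.frame(mito_per = mito_per, total_per = total_per, glyco_per = glyco_per,
             glyco_atp = glyco_per, mito_atp = mito_atp,
             total_atp = glyco_per + mito_atp,
             flags = ifelse(glyco_per < 0, "negative_glyco_per", ""),
             stringsAsFactors = FALSE)
}

#' Analyze a full extracellular-flux plate
#'
#' Per-well pipeline: segment phases, normalize the phase summaries to
#' Hoechst counts, derive the mito and glyco stress-test parameters (and the
#' ATP-rate decomposition when a buffer factor is configured), and annotate
#' with the plate layout.
#'
#' @param traces long data.frame (`well`, `time_min`, `phase`, `ocr`,
#'   `ecar`) for all wells, e.g. `generate_xf_experiment()$traces`.
#' @param counts data.frame (`well`, `count`).
#' @param layout a [plate_layout()].
#' @param constants an [xf_constants()]; ATP rates are computed only when its
#'   `buffer_factor` is set.
#' @param normalize normalize to cell counts before deriving parameters.
#' @param ... passed to [segment_phases()].
#' @return list with `wells` (per-well parameters, annotated) and `summary`
#'   (per-stimulus means of every parameter).
#' @export
analyze_xf_plate <- function(traces, counts, layout,
                             constants = xf_constants(), normalize = TRUE,
                             ...) {
  well_ids <- unique(traces$well)
  seg <- lapply(well_ids, function(w) {
    segment_phases(traces[traces$well == w, , drop = FALSE], ...)
  })
  phases <- seg[[1]]$phase
  ocr_mat <- t(vapply(seg, `[[`, numeric(length(phases)), "ocr"))
  ecar_mat <- t(vapply(seg, `[[`, numeric(length(phases)), "ecar"))
  colnames(ocr_mat) <- colnames(ecar_mat) <- phases

  cnt <- counts$count[match(well_ids, counts$well)]
  if (normalize) {
    ocr_mat <- normalize_rates(ocr_mat, cnt)
    ecar_mat <- normalize_rates(ecar_mat, cnt)
  }
  per_well <- do.call(rbind, lapply(seq_along(well_ids), function(i) {
    ph <- data.frame(phase = phases, ocr = ocr_mat[i, ], ecar = ecar_mat[i, ],
                     stringsAsFactors = FALSE)
    if (anyNA(ph$ocr)) {
      return(NULL)  # excluded by normalization (zero/missing count)
    }
    m <- mito_parameters(ph)
    g <- glyco_parameters(ph)
    out <- cbind(data.frame(well = well_ids[i], stringsAsFactors = FALSE),
                 m[setdiff(names(m), "flags")], g[setdiff(names(g), "flags")])
    out$flags <- paste(Filter(nzchar, c(m$flags, g$flags)), collapse = ",")
    if (!is.na(constants$buffer_factor)) {
      atp <- atp_rates(m$basal_ocr_total, m$nonmito_ocr, ph$ecar[ph$phase == "glucose"],
                       constants)
      out <- cbind(out, atp[setdiff(names(atp), "flags")])
      out$flags <- paste(Filter(nzchar, c(out$flags, atp$flags)), collapse = ",")
    }
    out
  }))
  ann <- join_layout(per_well, layout)
  num_cols <- names(ann)[vapply(ann, is.numeric, TRUE)]
  num_cols <- setdiff(num_cols, c("replicate", "concentration", "time_min"))
  summary <- stats::aggregate(ann[num_cols], list(stimulus = ann$stimulus), mean)
  list(wells = ann, summary = summary)
}
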