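#' Summarize flow events to per-well median fluorescence intensity
#'
#' MFI is the median puromycin intensity over viable events only; dead
#' events (viability flag FALSE) are excluded first, which is why a
#' viability dye is required in the panel.
#'
#' @param event_table per-cell data.frame with at least a `well` column, the
#'   intensity column and the viability column.
#' @param viability_column name of the logical viability column.
#' @param intensity_column name of the intensity column.
#' @return data.frame per well: `well`, `mfi`, `n_events` (viable count).
#' @export
summarize_events <- function(event_table, viability_column = "viable",
                             intensity_column = "puromycin") {
  for (col in c("well", viability_column, intensity_column)) {
    if (is.null(event_table[[col]])) stop("event table lacks column '", col, "'")
  }
  if (any(event_table[[intensity_column]] < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative")
  }
  out <- do.call(rbind, lapply(split(event_table, event_table$well), function(d) {
    viable <- d[isTRUE_vec(d[[viability_column]]), , drop = FALSE]
    if (nrow(viable) == 0L) {
      stop("no viable events in well ", d$well[1])
    }
    data.frame(well = d$well[1],
               mfi = stats::median(viable[[intensity_column]]),
               n_events = nrow(viable), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' SCENITH metabolic dependencies and capacities from condition MFIs
#'
#' With background-corrected puromycin MFIs under control (c), deoxyglucose
#' (dg), oligomycin (o) and the double inhibition (dgo):
#' \deqn{glucose\_dependency = 100 (c - dg) / (c - dgo)}
#' \deqn{mito\_dependency = 100 (c - o) / (c - dgo)}
#' \deqn{glycolytic\_capacity = 100 - mito\_dependency}
#' \deqn{faao\_capacity = 100 - glucose\_dependency}
#' i.e. the percent of translation (ATP-synthesis proxy) lost under each
#' inhibitor relative to full inhibition, and the complementary maximal
#' activity sustainable on the alternative pathway. Values outside [0,100]
#' (noise excursions) are clamped and flagged.
#'
#' @param control,dg,o,dgo condition MFIs (vectorized).
#' @param h optional harringtonine (full translation arrest) background MFI.
#' @param subtract_background subtract `h` from every condition (floored at
#'   0) before computing parameters; off by default.
#' @param clamp clamp parameters into [0,100] (flagged); set FALSE to see
#'   raw excursions.
#' @return data.frame: `glucose_dependency`, `mito_dependency`,
#'   `glycolytic_capacity`, `faao_capacity`, `flags`.
#' @export
scenith_parameters <- function(control, dg, o, dgo, h = NULL,
                               subtract_background = FALSE, clamp = TRUE) {
  if (any(c(control, dg, o, dgo, h) < 0)) stop("MFIs must be non-negative")
  flags <- rep("", length(control))
  if (subtract_background) {
    if (is.null(h)) stop("background subtraction requested but no harringtonine MFI given")
    control <- pmax(control - h, 0); dg <- pmax(dg - h, 0)
    o <- pmax(o - h, 0); dgo <- pmax(dgo - h, 0)
    flags <- paste0(flags, "background_subtracted")
  }
  denom <- control - dgo
  if (any(denom <= 0)) {
    stop("control MFI must exceed DGO MFI (undefined denominator)")
  }
  gd <- 100 * (control - dg) / denom
  md <- 100 * (control - o) / denom
  if (clamp) {
    out_of_range <- gd < 0 | gd > 100 | md < 0 | md > 100
    flags <- ifelse(out_of_range,
                    paste0(flags, ifelse(nzchar(flags), ",", ""), "clamped"), flags)
    gd <- pmin(pmax(gd, 0), 100)
    md <- pmin(pmax(md, 0), 100)
  }
  data.frame(glucose_dependency = gd, mito_dependency = md,
             glycolytic_capacity = 100 - md, faao_capacity = 100 - gd,
             flags = flags, stringsAsFactors = FALSE)
}

# condition MFIs (viable-event medians) for one sample's event subset
condition_mfis <- function(events, condition_column, min_events,
                           viability_column, intensity_column) {
  need <- c("control", "DG", "O", "DGO")
  mfi <- numeric(0); n <- integer(0)
  for (cond in unique(events[[condition_column]])) {
    sub <- events[events[[condition_column]] == cond, , drop = FALSE]
    sub$well <- "w"  # summarize the whole condition subset as one pool
    s <- summarize_events(sub, viability_column, intensity_column)
    mfi[cond] <- s$mfi; n[cond] <- s$n_events
  }
  if (!all(need %in% names(mfi))) {
    stop("missing SCENITH condition(s): ",
         paste(setdiff(need, names(mfi)), collapse = ", "))
  }
  list(mfi = mfi, n = n, low = any(n[need] < min_events))
}

#' Per-sample SCENITH profiles from an annotated event table
#'
#' Groups events by sample key (default subject x stimulus), computes the
#' viable-event median MFI per inhibitor condition, and applies
#' [scenith_parameters()]. Samples where any condition has fewer viable
#' events than `min_events` are flagged `low_events`.
#'
#' @param events data.frame with sample-key columns, a condition column
#'   (values control/DG/O/DGO and optionally H), the intensity and viability
#'   columns.
#' @param by character vector of sample-key columns.
#' @param condition_column,viability_column,intensity_column column names.
#' @param min_events minimum viable events per condition (default 100).
#' @param subtract_background,clamp passed to [scenith_parameters()].
#' @return data.frame, one row per sample: keys + parameters + flags.
#' @export
scenith_profiles <- function(events, by = c("subject_id", "stimulus"),
                             condition_column = "treatment",
                             viability_column = "viable",
                             intensity_column = "puromycin",
                             min_events = 100,
                             subtract_background = FALSE, clamp = TRUE) {
  keys <- interaction(events[by], drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(split(events, keys), function(d) {
    cm <- condition_mfis(d, condition_column, min_events,
                         viability_column, intensity_column)
    prof <- scenith_parameters(cm$mfi[["control"]], cm$mfi[["DG"]],
                               cm$mfi[["O"]], cm$mfi[["DGO"]],
                               h = if ("H" %in% names(cm$mfi)) cm$mfi[["H"]],
                               subtract_background = subtract_background,
                               clamp = clamp)
    if (cm$low) {
      prof$flags <- paste0(prof$flags, ifelse(nzchar(prof$flags), ",", ""),
                           "low_events")
    }
    cbind(d[1, by, drop = FALSE], prof)
  }))
  rownames(out) <- NULL
  out
}

#' SCENITH profiles per gated cell subset
#'
#' Partitions events with each gate (a named list of predicate functions on
#' the event table, typically thresholds on surface-marker columns) and
#' computes a [scenith_profiles()] row per gate. Gates may overlap. A gate
#' matching fewer viable events than `min_events` in any condition is
#' reported with NA parameters and a `low_events` flag; an empty gate is
#' skipped the same way. Subset profiles are population summaries, not truly
#' single-cell readouts.
#'
#' @param events annotated event table (one biological sample).
#' @param gates named list of functions `events -> logical`.
#' @param ... passed to [scenith_profiles()] (`by` is fixed to the gate).
#' @inheritParams scenith_profiles
#' @return data.frame, one row per gate: `subset` + parameters + flags.
#' @export
profile_by_subset <- function(events, gates, condition_column = "treatment",
                              viability_column = "viable",
                              intensity_column = "puromycin",
                              min_events = 100, ...) {
  stopifnot(is.list(gates), !is.null(names(gates)))
  out <- lapply(names(gates), function(g) {
    sel <- gates[[g]](events)
    sub <- events[isTRUE_vec(sel), , drop = FALSE]
    na_row <- data.frame(subset = g, glucose_dependency = NA_real_,
                         mito_dependency = NA_real_,
                         glycolytic_capacity = NA_real_,
                         faao_capacity = NA_real_, flags = "low_events",
                         stringsAsFactors = FALSE)
    if (nrow(sub) == 0L) return(na_row)
    viable_n <- tapply(isTRUE_vec(sub[[viability_column]]),
                       sub[[condition_column]], sum)
    need <- c("control", "DG", "O", "DGO")
    if (!all(need %in% names(viable_n)) || any(viable_n[need] < min_events)) {
      return(na_row)
    }
    sub$.subset <- g
    prof <- scenith_profiles(sub, by = ".subset",
                             condition_column = condition_column,
                             viability_column = viability_column,
                             intensity_column = intensity_column,
                             min_events = min_events, ...)
    names(prof)[names(prof) == ".subset"] <- "subset"
    prof
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
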