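#' Maximum color-formation rate of a substrate-plate kinetic trace
#'
#' Slides a `fit_span`-minute window across the analysis interval (default
#' 1-4 h), fits an ordinary least-squares slope in each window position
#' anchored at an observed timepoint, and returns the maximum slope. A trace
#' whose every window slope is negative reports 0 with a `floored` flag.
#'
#' @param times,values kinetic trace (minutes, dye signal).
#' @param window_start,window_end analysis interval, minutes (default 60-240).
#' @param fit_span window width for the local slope fit, minutes.
#' @param well,substrate identifiers used in error messages.
#' @return list with `max_rate` (signal/min), `t_start` (window anchor of
#'   the maximum) and `flag`.
#' @export
max_rate <- function(times, values, window_start = 60, window_end = 240,
                     fit_span = 30, well = NULL, substrate = NULL) {
  id <- paste(c(well, substrate), collapse = "/")
  o <- order(times)
  times <- times[o]; values <- values[o]
  in_win <- times >= window_start & times <= window_end
  if (sum(in_win) < 3) {
    stop("too few timepoints in [", window_start, ", ", window_end, "] min",
         if (nzchar(id)) paste0(" for ", id))
  }
  anchors <- times[in_win & times + fit_span <= window_end]
  if (!length(anchors)) anchors <- min(times[in_win])
  slopes <- vapply(anchors, function(t0) {
    sel <- times >= t0 & times <= t0 + fit_span & in_win
    if (sum(sel) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(values[sel] ~ times[sel]))[2])
  }, numeric(1))
  slopes <- slopes[is.finite(slopes)]
  if (!length(slopes)) {
    stop("no fittable window in [", window_start, ", ", window_end, "] min",
         if (nzchar(id)) paste0(" for ", id))
  }
  best <- max(slopes)
  if (best < 0) {
    list(max_rate = 0, t_start = anchors[which.max(slopes)], flag = "floored")
  } else {
    list(max_rate = best, t_start = anchors[which.max(slopes)], flag = "")
  }
}

#' Maximum rates for every trace of a substrate experiment
#'
#' @param traces long data.frame as `generate_substrate_plate()$traces`.
#' @param ... passed to [max_rate()].
#' @return data.frame per (plate, well): identifiers + `max_rate` + `flag`.
#' @export
substrate_rates <- function(traces, ...) {
  key <- interaction(traces$plate, traces$well, drop = TRUE)
  out <- do.call(rbind, lapply(split(traces, key), function(d) {
    r <- max_rate(d$time_min, d$value, well = d$well[1],
                  substrate = d$substrate[1], ...)
    data.frame(d[1, intersect(c("plate", "well", "substrate", "plate_type",
                                "subject_id", "stimulus"), names(d)),
                 drop = FALSE],
               max_rate = r$max_rate, flag = r$flag, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare substrate utilization between conditions
#'
#' Per substrate, a two-sided Student's t test of each condition against the
#' reference condition, paired on subject when every subject appears in both
#' conditions (falling back to an unpaired test with an `unpaired` flag
#' otherwise). Raw p values are reported alongside Sidak-adjusted ones
#' (family = substrates within a condition comparison).
#'
#' @param rates data.frame with columns `max_rate`, `substrate`, `stimulus`,
#'   `subject_id` (e.g. from [substrate_rates()]).
#' @param reference_condition reference level of `stimulus`.
#' @return data.frame: substrate, condition, mean difference, t, df, p,
#'   Sidak-adjusted p, significance stars, flag.
#' @export
compare_substrates <- function(rates, reference_condition = "naive") {
  stopifnot(all(c("max_rate", "substrate", "stimulus", "subject_id") %in% names(rates)))
  if (!reference_condition %in% rates$stimulus) {
    stop("reference condition '", reference_condition, "' not present")
  }
  conds <- setdiff(unique(rates$stimulus), reference_condition)
  out <- list()
  for (cond in conds) {
    rows <- list()
    for (sub in unique(rates$substrate)) {
      a <- rates[rates$substrate == sub & rates$stimulus == cond, ]
      b <- rates[rates$substrate == sub & rates$stimulus == reference_condition, ]
      if (nrow(a) < 2 || nrow(b) < 2) {
        stop("need >= 2 replicates per condition for substrate ", sub)
      }
      paired <- setequal(a$subject_id, b$subject_id) &&
        !anyDuplicated(a$subject_id) && !anyDuplicated(b$subject_id)
      if (paired) {
        b <- b[match(a$subject_id, b$subject_id), ]
        tt <- safe_t_test(a$max_rate, b$max_rate, paired = TRUE)
        flag <- ""
      } else {
        tt <- safe_t_test(a$max_rate, b$max_rate, paired = FALSE)
        flag <- "unpaired"
      }
      rows[[sub]] <- data.frame(
        substrate = sub, condition = cond, reference = reference_condition,
        estimate = mean(a$max_rate) - mean(b$max_rate),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value, flag = flag, stringsAsFactors = FALSE)
    }
    fam <- do.call(rbind, rows)
    fam$p_sidak <- sidak_adjust(fam$p, nrow(fam))
    fam$stars <- p_stars(fam$p_sidak)
    out[[cond]] <- fam
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
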