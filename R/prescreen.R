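#' Fit a linear standard curve
#'
#' Ordinary least-squares fit of signal against concentration for a series of
#' standard wells.
#'
#' @param concentration known standard concentrations (>= 2 distinct values).
#' @param signal measured signals (OD or RFU), same length.
#' @return A `standard_curve`: list with `slope`, `intercept`, `r_squared`,
#'   `n` and the signal `range` spanned by the standards.
#' @export
fit_standard_curve <- function(concentration, signal) {
  stopifnot(length(concentration) == length(signal))
  if (length(unique(concentration)) < 2) {
    stop("standard curve needs >= 2 distinct concentrations")
  }
  fit <- stats::lm(signal ~ concentration)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope)) stop("standard-curve slope is not finite")
  ss_tot <- sum((signal - mean(signal))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(signal), range = range(signal)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve: signal = %.4g + %.4g * conc (R^2 = %.4f, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

# shared linear inversion for curve-based quantification
invert_curve <- function(signal, curve, blank = 0) {
  (signal - blank - curve$intercept) / curve$slope
}

#' Quantify nitrite from Griess optical densities
#'
#' Inverts a nitrite standard curve: `concentration = (OD - blank -
#' intercept) / slope`. Negative concentrations are clipped to zero and
#' flagged `below_blank`.
#'
#' @param sample_od vector of sample OD540 readings.
#' @param standard_curve a [fit_standard_curve()] result (nitrite standards).
#' @param blank_od reagent-blank OD to subtract (0 when the curve intercept
#'   already absorbs the background).
#' @param r2_threshold minimum acceptable curve R^2.
#' @param allow_extrapolation permit samples outside the signal range spanned
#'   by the standards.
#' @return data.frame with `nitrite_um` and `flag` per sample.
#' @export
quantify_griess <- function(sample_od, standard_curve, blank_od = 0,
                            r2_threshold = 0.95, allow_extrapolation = FALSE) {
  stopifnot(inherits(standard_curve, "standard_curve"))
  if (standard_curve$r_squared < r2_threshold) {
    stop(sprintf("standard curve R^2 = %.3f below threshold %.3f",
                 standard_curve$r_squared, r2_threshold))
  }
  if (!allow_extrapolation) {
    rng <- standard_curve$range
    out <- sample_od - blank_od < min(rng) - 1e-9 | sample_od - blank_od > max(rng) + 1e-9
    # samples below blank fall below the curve span but are handled by clipping
    if (any(out & sample_od - blank_od > min(rng))) {
      stop("sample OD outside the standard-curve span; set allow_extrapolation = TRUE")
    }
  }
  conc <- invert_curve(sample_od, standard_curve, blank_od)
  flag <- ifelse(conc < 0, "below_blank", "")
  data.frame(nitrite_um = pmax(conc, 0), flag = flag, stringsAsFactors = FALSE)
}

#' Arginase activity from urea concentration
#'
#' Evaluates `[Urea] * (total_volume * 10^6) / (tested_volume * time * 1000)`.
#' With urea in mM, volumes in ul and time in minutes this yields U/L, the
#' classical arginase assay unit (one unit producing 1 umol urea per minute).
#'
#' @param urea_concentration urea formed during the incubation, mM.
#' @param total_volume lysate volume, ul (default 100).
#' @param tested_volume lysate volume assayed, ul (default 10).
#' @param incubation_time arginine incubation at 37 C, minutes (default 60).
#' @return activity, U/L (vectorized over `urea_concentration`).
#' @examples
#' arginase_activity(2)  # 2 mM urea -> 333.3 U/L at assay defaults
#' @export
arginase_activity <- function(urea_concentration, total_volume = 100,
                              tested_volume = 10, incubation_time = 60) {
  if (any(total_volume <= 0) || any(tested_volume <= 0)) {
    stop("volumes must be strictly positive")
  }
  if (any(incubation_time <= 0)) stop("incubation_time must be strictly positive")
  urea_concentration * (total_volume * 1e6) /
    (tested_volume * incubation_time * 1000)
}

#' Glucose consumption by single-point GOD-PAP calibration
#'
#' `conc(x) = x / standard_od * standard_conc`; consumption is the glucose of
#' cell-free medium minus that of the cell supernatant. Apparent production
#' (sample above medium by more than `tolerance` mM) is reported as a
#' negative value with a `production?` flag rather than silently truncated.
#'
#' @param sample_od supernatant ODs.
#' @param medium_blank_od OD of medium incubated without cells.
#' @param standard_od OD of the glucose standard (> 0).
#' @param standard_conc standard concentration, mM (default 5).
#' @param tolerance mM of apparent production tolerated before flagging.
#' @return data.frame with `glucose_consumed_mm` and `flag`.
#' @export
glucose_consumption <- function(sample_od, medium_blank_od, standard_od,
                                standard_conc = 5, tolerance = 0.1) {
  if (length(standard_od) != 1 || standard_od <= 0) {
    stop("standard_od must be a single positive OD")
  }
  conc <- function(x) x / standard_od * standard_conc
  consumed <- conc(medium_blank_od) - conc(sample_od)
  flag <- ifelse(consumed < -tolerance, "production?", "")
  data.frame(glucose_consumed_mm = consumed, flag = flag, stringsAsFactors = FALSE)
}

# endpoint of an NADH-formation kinetic: first post-start cycle whose change
# from the previous cycle is below stability_tol of the current signal
lactate_endpoint <- function(values, n_background_cycles, stability_tol = 0.01) {
  nb <- n_background_cycles
  if (nb < 2) stop("need >= 2 background cycles")
  post <- values[-seq_len(nb)]
  if (length(post) < 3) stop("need >= 3 post-start cycles")
  background <- mean(values[seq_len(nb)])
  # tiny floor keeps all-zero traces (0 change, 0 signal) counted as stable
  stable <- which(abs(diff(post)) <= stability_tol * pmax(abs(post[-1]), 1e-12)) + 1L
  if (length(stable)) {
    list(endpoint = post[stable[1]], background = background, flag = "")
  } else {
    list(endpoint = post[length(post)], background = background, flag = "unstable")
  }
}

#' Lactate from NADH-formation kinetics
#'
#' Lactate dehydrogenase converts lactate to NADH; fluorescence rises to a
#' plateau. The endpoint is the first post-start cycle whose change from the
#' previous cycle is below `stability_tol` (default 1%) of the current
#' signal; a trace that never stabilizes uses the last cycle and is flagged
#' `unstable`. The background mean (pre-start cycles) is subtracted and the
#' net signal converted via the lactate standard curve.
#'
#' @param kinetic_fluorescence full read sequence: background cycles first,
#'   then post-start cycles.
#' @param n_background_cycles number of leading background cycles (>= 2).
#' @param standard_curve [fit_standard_curve()] of net endpoint signal vs
#'   lactate mM.
#' @param stability_tol per-cycle relative stability tolerance.
#' @return list with `lactate_mm`, `signal`, `flag`.
#' @export
lactate_from_nadh <- function(kinetic_fluorescence, n_background_cycles,
                              standard_curve, stability_tol = 0.01) {
  stopifnot(inherits(standard_curve, "standard_curve"))
  ep <- lactate_endpoint(kinetic_fluorescence, n_background_cycles, stability_tol)
  signal <- ep$endpoint - ep$background
  conc <- invert_curve(signal, standard_curve)
  flag <- ep$flag
  if (conc < 0) {
    conc <- 0
    flag <- paste0(flag, if (nzchar(flag)) "," else "", "below_blank")
  }
  list(lactate_mm = conc, signal = signal, flag = flag)
}

#' Quantify all four pre-screening assays of a (synthetic or real) plate set
#'
#' Driver matching the output of [generate_prescreen_plate()]: fits standard
#' curves from the standard wells of each assay plate, quantifies every
#' sample well, and summarizes per stimulus.
#'
#' @param plates list with `griess`, `glucose`, `urea`, `lactate` elements
#'   (each `measurements` + `layout`), as returned by
#'   [generate_prescreen_plate()].
#' @param arginase assay geometry passed to [arginase_activity()]:
#'   list(total_volume, tested_volume, incubation_time).
#' @return list with `wells` (per-well quantifications) and `summary`
#'   (means per stimulus).
#' @export
analyze_prescreen <- function(plates,
                              arginase = list(total_volume = 100,
                                              tested_volume = 10,
                                              incubation_time = 60)) {
  ann <- function(assay) join_layout(assay$measurements, assay$layout)

  # Griess: curve on raw standard ODs (intercept absorbs reagent background)
  g <- ann(plates$griess)
  std <- g[g$role == "standard", ]
  curve_g <- fit_standard_curve(std$concentration, std$value)
  smp <- g[g$role == "sample", ]
  q_g <- quantify_griess(smp$value, curve_g, blank_od = 0,
                         allow_extrapolation = TRUE)
  griess <- cbind(smp[c("well", "subject_id", "stimulus", "replicate")], q_g)

  # glucose: single-point standard + medium blanks
  gl <- ann(plates$glucose)
  q_gl <- glucose_consumption(
    gl$value[gl$role == "sample"],
    medium_blank_od = mean(gl$value[gl$role == "blank"]),
    standard_od = mean(gl$value[gl$role == "standard"]),
    standard_conc = unique(gl$concentration[gl$role == "standard"]))
  glucose <- cbind(gl[gl$role == "sample",
                      c("well", "subject_id", "stimulus", "replicate")], q_gl)

  # urea -> arginase activity
  u <- ann(plates$urea)
  std_u <- u[u$role == "standard", ]
  curve_u <- fit_standard_curve(std_u$concentration, std_u$value)
  smp_u <- u[u$role == "sample", ]
  urea_mm <- invert_curve(smp_u$value, curve_u)
  urea <- cbind(smp_u[c("well", "subject_id", "stimulus", "replicate")],
                data.frame(urea_mm = urea_mm,
                           arginase_activity = arginase_activity(
                             pmax(urea_mm, 0), arginase$total_volume,
                             arginase$tested_volume, arginase$incubation_time)))

  # lactate: endpoint signals for standards define the curve, then samples
  l <- ann(plates$lactate)
  nb <- plates$lactate$n_background_cycles
  per_well_signal <- function(df) {
    df <- df[order(df$time_min), ]
    ep <- lactate_endpoint(df$value, nb)
    ep$endpoint - ep$background
  }
  l_split <- split(l, l$well)
  sig <- vapply(l_split, per_well_signal, numeric(1))
  meta <- do.call(rbind, lapply(l_split, function(d) d[1, , drop = FALSE]))
  curve_l <- fit_standard_curve(meta$concentration[meta$role == "standard"],
                                sig[meta$role == "standard"])
  keep <- meta$role == "sample"
  lact <- data.frame(meta[keep, c("well", "subject_id", "stimulus", "replicate")],
                     lactate_mm = pmax(invert_curve(sig[keep], curve_l), 0),
                     stringsAsFactors = FALSE)

  wells <- list(griess = griess, glucose = glucose, arginase = urea,
                lactate = lact)
  agg <- function(df, col) {
    out <- stats::aggregate(df[[col]], list(stimulus = df$stimulus), mean)
    names(out)[2] <- col
    out
  }
  summary <- Reduce(function(a, b) merge(a, b, by = "stimulus"), list(
    agg(griess, "nitrite_um"), agg(glucose, "glucose_consumed_mm"),
    agg(urea, "arginase_activity"), agg(lact, "lactate_mm")))
  list(wells = wells, summary = summary,
       curves = list(griess = curve_g, urea = curve_u, lactate = curve_l))
}
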