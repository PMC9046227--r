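# Relative substrate-utilization multipliers per phenotype: classical
# activation suppresses mitochondrial substrate oxidation, IL-4 enhances it,
# and glycolytic substrates run the other way.
SUBSTRATE_PHENOTYPE_FACTOR <- c(naive = 1, LPS = 0.6, `LPS+IFNg` = 0.45, IL4 = 1.5)
GLYCOLYTIC_SUBSTRATES <- c("D-Glucose", "D-Glucose-6-Phosphate", "D-Fructose")
GLYCOLYTIC_FACTOR <- c(naive = 1, LPS = 1.6, `LPS+IFNg` = 2.0, IL4 = 0.9)

#' Default substrate panel for the synthetic substrate plates
#'
#' A compact panel drawn from the common mitochondrial (MitoPlate-style) and
#' carbon (PM-M1-style) substrate sets, with a nominal maximum
#' color-formation rate (signal units/min) for the naive phenotype.
#' Representative (partial, package-curated) panel listings ship in
#' `inst/extdata/mitoplate_s1_substrates.csv` and
#' `inst/extdata/pm_m1_substrates.csv`; they are not the vendor's
#' authoritative plate maps.
#'
#' @return data.frame with columns `substrate`, `plate_type`, `base_rate`.
#' @export
default_substrates <- function() {
  data.frame(
    substrate = c("L-Malate", "Succinate", "Pyruvate", "L-Glutamate",
                  "D-Glucose", "D-Glucose-6-Phosphate", "L-Glutamine",
                  "a-Keto-Glutarate"),
    plate_type = c("mito", "mito", "mito", "mito",
                   "carbon", "carbon", "carbon", "mito"),
    base_rate = c(2.0, 3.0, 2.5, 1.5, 3.5, 1.8, 1.2, 1.6),
    stringsAsFactors = FALSE
  )
}

#' Simulate substrate-plate color-formation kinetics
#'
#' One plate per subject x phenotype (as with real substrate plates, where a
#' plate holds one sample across many substrate wells). Each trace is
#' sigmoid-like: flat lag, then a linear color-formation ramp whose slope is
#' the ground-truth maximum rate, then a plateau. The linear segment spans
#' the 1-4 h analysis window, so a sliding-window least-squares maximum rate
#' recovers the truth exactly at zero noise.
#'
#' @param presets data.frame from [phenotype_presets()].
#' @param substrates data.frame as [default_substrates()].
#' @param n_subjects number of mice/donors.
#' @param noise a [noise_model()].
#' @param t_max,dt trace duration and sampling interval, minutes.
#' @param lag lag before color formation starts, minutes.
#' @param plateau_t time at which the ramp saturates, minutes.
#' @return list with `traces` (plate, well, substrate, plate_type,
#'   subject_id, stimulus, time_min, value) and `truth` (per stimulus x
#'   substrate ground-truth maximum rate, signal/min).
#' @export
generate_substrate_plate <- function(presets = phenotype_presets(),
                                     substrates = default_substrates(),
                                     n_subjects = 6,
                                     noise = noise_model(),
                                     t_max = 360, dt = 15,
                                     lag = 75, plateau_t = 255) {
  if (nrow(substrates) > 96) stop("capacity: more than 96 substrate wells per plate")
  set.seed(noise$seed)
  subjects <- paste0("S", seq_len(n_subjects))
  subj_eff <- subject_effects(subjects, noise$subject_sd)
  times <- seq(0, t_max, by = dt)
  ramp <- pmax(pmin(times, plateau_t) - lag, 0)  # minutes of active ramp

  true_rate <- function(stim, sub) {
    base <- substrates$base_rate[substrates$substrate == sub]
    fac <- if (sub %in% GLYCOLYTIC_SUBSTRATES) GLYCOLYTIC_FACTOR[[stim]] else
      SUBSTRATE_PHENOTYPE_FACTOR[[stim]]
    base * fac
  }

  grid <- expand.grid(substrate = substrates$substrate, stimulus = presets$name,
                      subject_id = subjects,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$plate <- paste(grid$subject_id, grid$stimulus, sep = "_")
  grid$well <- all_wells()[rep(seq_len(nrow(substrates)),
                               n_subjects * nrow(presets))]
  grid$plate_type <- substrates$plate_type[match(grid$substrate, substrates$substrate)]

  out <- vector("list", nrow(grid))
  truth_rate <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    s <- true_rate(grid$stimulus[i], grid$substrate[i])
    truth_rate[i] <- s
    slope_i <- s * subj_eff[[grid$subject_id[i]]]
    vals <- slope_i * ramp * lognorm_factor(length(times), noise$well_cv)
    out[[i]] <- data.frame(plate = grid$plate[i], well = grid$well[i],
                           substrate = grid$substrate[i],
                           plate_type = grid$plate_type[i],
                           subject_id = grid$subject_id[i],
                           stimulus = grid$stimulus[i],
                           time_min = times, value = vals,
                           stringsAsFactors = FALSE)
  }
  truth <- unique(data.frame(stimulus = grid$stimulus,
                             substrate = grid$substrate,
                             plate_type = grid$plate_type,
                             max_rate = truth_rate, stringsAsFactors = FALSE))
  list(traces = do.call(rbind, out), truth = truth)
}
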