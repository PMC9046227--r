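write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

read_required_csv <- function(path, stage) {
  if (!file.exists(path)) {
    stop("stage ", stage, ": required file not found: ", path, call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

default_run_config <- function() {
  list(out_dir = "immunoplate_out", seed = 1L,
       stages = c("prescreen", "xf", "scenith", "substrate"),
       xf_constants = list(buffer_factor = 2.4),
       simulate = list(n_subjects = 6, replicates = 3,
                       events_per_well = 5000, noise = list()),
       thresholds = list(stability_tol = 0.01, inhibitor_pass = 0.2,
                         min_events = 100))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      merge_config(base[[nm]], override[[nm]])
    } else override[[nm]]
  }
  base
}

#' Run the full simulate-then-analyze pipeline
#'
#' Orchestrates the toolbox end to end: simulates the four plate experiments
#' (unless input file paths are supplied), writes the simulated raw tables
#' and ground-truth sidecars, runs every analysis stage from those files,
#' and writes per-well results, per-condition summaries, a cross-assay
#' report joined on stimulus, and a run manifest (seed, configuration,
#' package version, output checksums). All randomness derives from
#' `config$seed`, so a rerun with the same configuration reproduces every
#' numeric output byte for byte.
#'
#' @param config configuration list (or path to a JSON file); see
#'   `default_run_config()` internals: `out_dir`, `seed`, `stages`,
#'   `xf_constants`, `simulate` (n_subjects, replicates, events_per_well,
#'   noise overrides) or `inputs` (per-stage file paths), `thresholds`.
#' @return Invisibly, a list of written file paths by stage.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  cfg <- merge_config(default_run_config(), config)
  out <- cfg$out_dir
  sim_dir <- file.path(out, "simulated")
  res_dir <- file.path(out, "results")
  for (d in c(out, sim_dir, res_dir)) {
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  }
  constants <- do.call(xf_constants, cfg$xf_constants)
  noise <- do.call(noise_model, c(cfg$simulate$noise, list(seed = cfg$seed)))
  paths <- list()
  msg <- function(stage, ...) message("[", stage, "] ", ...)

  inputs <- cfg$inputs
  simulate_missing <- is.null(inputs)
  if (simulate_missing) {
    msg("simulate", "generating synthetic experiments (seed ", cfg$seed, ")")
    xf_sim <- generate_xf_experiment(n_subjects = cfg$simulate$n_subjects,
                                     replicates = cfg$simulate$replicates,
                                     noise = noise)
    sc_sim <- generate_scenith_experiment(n_subjects = cfg$simulate$n_subjects,
                                          events_per_well = cfg$simulate$events_per_well,
                                          noise = noise)
    pre_sim <- generate_prescreen_plate(n_subjects = cfg$simulate$n_subjects,
                                        replicates = cfg$simulate$replicates,
                                        noise = noise)
    sub_sim <- generate_substrate_plate(n_subjects = cfg$simulate$n_subjects,
                                        noise = noise)
    inputs <- list(
      xf = list(traces = file.path(sim_dir, "xf_traces.csv"),
                counts = file.path(sim_dir, "xf_counts.csv"),
                layout = file.path(sim_dir, "xf_layout.json")),
      scenith = list(events = file.path(sim_dir, "scenith_events.csv")),
      substrate = list(traces = file.path(sim_dir, "substrate_traces.csv")),
      prescreen = lapply(stats::setNames(nm = c("griess", "glucose", "urea", "lactate")),
                         function(a) list(
                           measurements = file.path(sim_dir, paste0(a, "_measurements.csv")),
                           layout = file.path(sim_dir, paste0(a, "_layout.json")))))
    write_csv_plain(xf_sim$traces, inputs$xf$traces)
    write_csv_plain(xf_sim$counts, inputs$xf$counts)
    write_plate_layout(xf_sim$layout, inputs$xf$layout)
    write_csv_plain(sc_sim$events, inputs$scenith$events)
    write_csv_plain(sub_sim$traces, inputs$substrate$traces)
    for (a in names(inputs$prescreen)) {
      write_csv_plain(pre_sim[[a]]$measurements, inputs$prescreen[[a]]$measurements)
      write_plate_layout(pre_sim[[a]]$layout, inputs$prescreen[[a]]$layout)
    }
    paths$truth <- c(
      write_csv_plain(xf_sim$truth, file.path(sim_dir, "xf_truth.csv")),
      write_csv_plain(sc_sim$truth, file.path(sim_dir, "scenith_truth.csv")),
      write_csv_plain(pre_sim$truth, file.path(sim_dir, "prescreen_truth.csv")),
      write_csv_plain(sub_sim$truth, file.path(sim_dir, "substrate_truth.csv")))
  }

  summaries <- list()
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  if ("xf" %in% cfg$stages && !is.null(inputs$xf)) {
    msg("xf", "extracellular-flux parameter extraction")
    paths$xf <- run_stage("xf", function() {
      traces <- read_required_csv(inputs$xf$traces, "xf")
      counts <- read_required_csv(inputs$xf$counts, "xf")
      if (!file.exists(inputs$xf$layout)) {
        stop("required file not found: ", inputs$xf$layout)
      }
      layout <- load_plate_layout(inputs$xf$layout)
      res <- analyze_xf_plate(traces, counts, layout, constants = constants)
      summaries$xf <<- res$summary
      c(write_csv_plain(res$wells, file.path(res_dir, "xf_wells.csv")),
        write_csv_plain(res$summary, file.path(res_dir, "xf_summary.csv")))
    })
  }
  if ("scenith" %in% cfg$stages && !is.null(inputs$scenith)) {
    msg("scenith", "metabolic dependency profiling")
    paths$scenith <- run_stage("scenith", function() {
      events <- read_required_csv(inputs$scenith$events, "scenith")
      prof <- scenith_profiles(events, min_events = cfg$thresholds$min_events)
      num <- c("glucose_dependency", "mito_dependency", "glycolytic_capacity",
               "faao_capacity")
      summ <- stats::aggregate(prof[num], list(stimulus = prof$stimulus), mean)
      summaries$scenith <<- summ
      c(write_csv_plain(prof, file.path(res_dir, "scenith_profiles.csv")),
        write_csv_plain(summ, file.path(res_dir, "scenith_summary.csv")))
    })
  }
  if ("prescreen" %in% cfg$stages && !is.null(inputs$prescreen)) {
    msg("prescreen", "Griess / arginase / glucose / lactate quantification")
    paths$prescreen <- run_stage("prescreen", function() {
      plates <- lapply(inputs$prescreen, function(p) {
        if (!file.exists(p$layout)) stop("required file not found: ", p$layout)
        list(measurements = read_required_csv(p$measurements, "prescreen"),
             layout = load_plate_layout(p$layout))
      })
      plates$lactate$n_background_cycles <- PRESCREEN_LAWS$lactate$n_background_cycles
      res <- analyze_prescreen(plates)
      summaries$prescreen <<- res$summary
      files <- vapply(names(res$wells), function(a) {
        write_csv_plain(res$wells[[a]], file.path(res_dir, paste0("prescreen_", a, ".csv")))
      }, character(1))
      c(files, write_csv_plain(res$summary, file.path(res_dir, "prescreen_summary.csv")))
    })
  }
  if ("substrate" %in% cfg$stages && !is.null(inputs$substrate)) {
    msg("substrate", "substrate-plate maximum rates")
    paths$substrate <- run_stage("substrate", function() {
      traces <- read_required_csv(inputs$substrate$traces, "substrate")
      rates <- substrate_rates(traces)
      summ <- stats::aggregate(rates["max_rate"],
                               list(stimulus = rates$stimulus,
                                    substrate = rates$substrate), mean)
      cmp <- compare_substrates(rates, reference_condition = "naive")
      summaries$substrate <<- summ
      c(write_csv_plain(rates, file.path(res_dir, "substrate_rates.csv")),
        write_csv_plain(summ, file.path(res_dir, "substrate_summary.csv")),
        write_csv_plain(cmp, file.path(res_dir, "substrate_comparisons.csv")))
    })
  }

  # cross-assay report joined on stimulus
  joinable <- Filter(function(s) !is.null(s) && "stimulus" %in% names(s),
                     summaries[c("prescreen", "xf", "scenith")])
  if (length(joinable)) {
    report <- Reduce(function(a, b) merge(a, b, by = "stimulus", all = TRUE),
                     joinable)
    paths$report <- write_csv_plain(report, file.path(res_dir, "report.csv"))
  }

  outputs <- sort(unname(unlist(paths)))
  manifest <- list(
    package = "immunoplate",
    version = as.character(utils::packageVersion("immunoplate")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs)),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, manifest = file.path(out, "manifest.json")))
}
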