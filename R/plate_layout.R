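LAYOUT_ROLES <- c("sample", "standard", "blank", "unstained", "empty")

#' Construct a validated 96-well plate layout
#'
#' A plate layout maps each well to its biological annotation: subject,
#' stimulus (e.g. naive, LPS, LPS+IFNg, IL4), treatment (inhibitor/probe),
#' replicate index and role. Wells not listed default to `role = "empty"`.
#'
#' @param wells data.frame with at least a `well` column; optional columns
#'   `subject_id`, `stimulus`, `treatment`, `replicate`, `role`,
#'   `concentration` (for standards), `exclude`.
#' @param plate_id plate identifier.
#' @return A `plate_layout`: data.frame with one row per populated well plus
#'   implicit empty wells, row-major sorted, with attribute `plate_id`.
#' @export
plate_layout <- function(wells, plate_id = "plate1") {
  if (!is.data.frame(wells) || is.null(wells$well)) {
    stop("wells must be a data.frame with a 'well' column")
  }
  pw <- parse_well(wells$well)
  wells$well <- pw$well
  dup <- wells$well[duplicated(wells$well)]
  if (length(dup)) stop("duplicate well ", paste(unique(dup), collapse = ", "))

  defaults <- list(subject_id = NA_character_, stimulus = NA_character_,
                   treatment = NA_character_, replicate = NA_integer_,
                   role = "sample", concentration = NA_real_, exclude = FALSE)
  for (nm in names(defaults)) {
    if (is.null(wells[[nm]])) wells[[nm]] <- defaults[[nm]]
  }
  wells$role[is.na(wells$role)] <- "sample"
  bad_role <- setdiff(unique(wells$role), LAYOUT_ROLES)
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "),
         " (expected one of ", paste(LAYOUT_ROLES, collapse = ", "), ")")
  }
  is_sample <- wells$role == "sample"
  missing_ann <- is_sample & (is.na(wells$subject_id) | is.na(wells$stimulus))
  if (any(missing_ann)) {
    stop("sample wells must have subject_id and stimulus: ",
         paste(wells$well[missing_ann], collapse = ", "))
  }

  # fill remaining plate positions as empty
  rest <- setdiff(all_wells(), wells$well)
  if (length(rest)) {
    empty <- data.frame(well = rest, subject_id = NA_character_,
                        stimulus = NA_character_, treatment = NA_character_,
                        replicate = NA_integer_, role = "empty",
                        concentration = NA_real_, exclude = FALSE,
                        stringsAsFactors = FALSE)
    wells <- rbind(wells[names(empty)], empty)
  } else {
    wells <- wells[c("well", "subject_id", "stimulus", "treatment",
                     "replicate", "role", "concentration", "exclude")]
  }
  wells <- wells[well_order(wells$well), , drop = FALSE]
  rownames(wells) <- NULL
  structure(wells, plate_id = as.character(plate_id),
            class = c("plate_layout", "data.frame"))
}

#' @export
print.plate_layout <- function(x, ...) {
  pop <- x[x$role != "empty", , drop = FALSE]
  cat(sprintf("plate_layout '%s': %d populated / 96 wells\n",
              attr(x, "plate_id"), nrow(pop)))
  print(table(role = pop$role))
  invisible(x)
}

#' Read a plate layout from JSON
#'
#' The JSON plate-map dialect is an object with `plate_id` and a `wells`
#' array; each element has a `well` address plus any of `subject_id`,
#' `stimulus`, `treatment`, `replicate`, `role`, `concentration`, `exclude`.
#' Unlisted wells default to `role = "empty"`.
#'
#' @param path JSON file path.
#' @return A [plate_layout()].
#' @export
load_plate_layout <- function(path) {
  if (!file.exists(path)) stop("plate-map file not found: ", path)
  plate_map <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(plate_map$wells)) stop("plate map must contain a 'wells' array")
  wells <- as.data.frame(plate_map$wells, stringsAsFactors = FALSE)
  plate_layout(wells, plate_id = if (is.null(plate_map$plate_id)) "plate1" else plate_map$plate_id)
}

#' Write a plate layout to JSON
#'
#' Inverse of [load_plate_layout()]: only populated (non-empty) wells are
#' written, so a load/write round trip is content-identical up to key order.
#'
#' @param layout a `plate_layout`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_plate_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  pop <- as.data.frame(layout)[layout$role != "empty", , drop = FALSE]
  keep <- vapply(pop, function(col) !all(is.na(col)), TRUE)
  keep["well"] <- TRUE
  pop <- pop[, keep, drop = FALSE]
  if (!any(pop$exclude)) pop$exclude <- NULL
  jsonlite::write_json(list(plate_id = attr(layout, "plate_id"), wells = pop),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read tidy long-format plate measurements from CSV
#'
#' Expected dialect: UTF-8 comma-separated with header
#' `well,quantity,time_min,value` (the `time_min` column may be absent for
#' endpoint reads; extra annotation columns are carried through). Wave-style
#' exports can be mapped by renaming `Well -> well`, `Measurement -> quantity`,
#' `Time -> time_min`, `Rate/OD/RFU -> value` before or at read time via
#' `col_map`.
#'
#' @param path CSV file path.
#' @param col_map optional named character vector mapping input column names to
#'   the dialect names, e.g. `c(Well = "well", Rate = "value")`.
#' @return data.frame with columns `well`, `quantity`, `time_min` (NA for
#'   endpoint reads) and numeric `value`.
#' @export
read_tidy_measurements <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (!is.null(col_map)) {
    hit <- match(names(col_map), names(raw))
    names(raw)[hit[!is.na(hit)]] <- unname(col_map[!is.na(hit)])
  }
  for (req in c("well", "value")) {
    if (is.null(raw[[req]])) stop("measurement CSV must have a '", req, "' column")
  }
  if (is.null(raw$quantity)) raw$quantity <- "value"
  if (is.null(raw$time_min)) raw$time_min <- NA_character_

  val <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(val) & !(raw$value %in% c("", NA)))
  if (length(bad)) {
    # +1 for the header row: report the physical line in the file
    stop("non-numeric value '", raw$value[bad[1]], "' on line ", bad[1] + 1L,
         " of ", path)
  }
  if (anyNA(val)) stop("missing value on line ", which(is.na(val))[1] + 1L, " of ", path)
  tm <- suppressWarnings(as.numeric(raw$time_min))
  raw$well <- parse_well(raw$well)$well
  out <- raw
  out$value <- val
  out$time_min <- tm
  core <- c("well", "quantity", "time_min", "value")
  out[c(core, setdiff(names(out), core))]
}

#' Annotate measurements with plate-layout metadata
#'
#' Left-joins measurement records onto the layout by well, attaching
#' `subject_id`, `stimulus`, `treatment`, `replicate` and `role`. Every
#' measured well must be mapped (role other than `empty`).
#'
#' @param measurements data.frame from [read_tidy_measurements()].
#' @param layout a [plate_layout()].
#' @return Annotated data.frame, one row per measurement record.
#' @export
join_layout <- function(measurements, layout) {
  stopifnot(inherits(layout, "plate_layout"))
  if (nrow(measurements) == 0L) {
    ann <- measurements
    for (nm in c("subject_id", "stimulus", "treatment", "replicate", "role")) {
      ann[[nm]] <- vector(mode = class(layout[[nm]])[1], length = 0L)
    }
    return(ann)
  }
  idx <- match(measurements$well, layout$well)
  orphan <- unique(measurements$well[is.na(idx) | layout$role[idx] == "empty"])
  if (length(orphan)) {
    stop("measured well(s) not in layout: ", paste(orphan, collapse = ", "))
  }
  ann <- cbind(measurements,
               as.data.frame(layout)[idx, c("subject_id", "stimulus", "treatment",
                                            "replicate", "role", "concentration",
                                            "exclude")])
  rownames(ann) <- NULL
  ann
}
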