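#' @keywords internal
"_PACKAGE"

PLATE_ROWS <- LETTERS[1:8]
PLATE_COLS <- 1:12

#' All 96 well addresses in row-major order
#'
#' @return Character vector `c("A1", ..., "H12")`.
#' @export
all_wells <- function() {
  as.vector(t(outer(PLATE_ROWS, PLATE_COLS, paste0)))
}

#' Parse well addresses
#'
#' Splits addresses like `"A1"` or `"H12"` into row letter and column number,
#' validating the 96-well range (rows A-H, columns 1-12).
#'
#' @param well character vector of addresses.
#' @return data.frame with columns `well`, `row`, `col`.
#' @export
parse_well <- function(well) {
  well <- toupper(trimws(as.character(well)))
  m <- regmatches(well, regexec("^([A-Za-z])([0-9]{1,2})$", well))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed well address: ", paste(unique(well[bad]), collapse = ", "))
  }
  row <- vapply(m, `[[`, "", 2L)
  col <- as.integer(vapply(m, `[[`, "", 3L))
  out_row <- !(row %in% PLATE_ROWS)
  if (any(out_row)) {
    stop("row out of range (A-H) for well ", paste(unique(well[out_row]), collapse = ", "))
  }
  out_col <- col < 1L | col > 12L
  if (any(out_col)) {
    stop("column out of range (1-12) for well ", paste(unique(well[out_col]), collapse = ", "))
  }
  data.frame(well = paste0(row, col), row = row, col = col, stringsAsFactors = FALSE)
}

# row-major sort order of a well vector
well_order <- function(well) {
  p <- parse_well(well)
  order(match(p$row, PLATE_ROWS), p$col)
}
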