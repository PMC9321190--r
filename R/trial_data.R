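# Trial-level data: schemas, validation, CSV round-trip.
#
# All horizontal coordinates are millimetres, rightward positive, in an
# environmental reference frame; the origin is arbitrary because every
# downstream estimator is translation-invariant.

.bisection_cols <- c(
  "participant_id", "group", "trial_index",
  "left_mm", "right_mm", "response_mm"
)

.reproduction_cols <- c(
  "participant_id", "group", "trial_index",
  "left_mm", "right_mm", "bisection_response_mm",
  "probed_side", "reproduced_mm"
)

.group_levels <- c("control", "neglect", "unknown")

check_header <- function(header, expected, path) {
  dup <- unique(header[duplicated(header)])
  if (length(dup) > 0) {
    stop_nw("nw_schema_error", sprintf(
      "duplicate column(s) in '%s': %s", path, paste(dup, collapse = ", ")
    ))
  }
  missing <- setdiff(expected, header)
  if (length(missing) > 0) {
    stop_nw("nw_schema_error", sprintf(
      "missing column(s) in '%s': %s", path, paste(missing, collapse = ", ")
    ))
  }
  extra <- setdiff(header, expected)
  if (length(extra) > 0) {
    stop_nw("nw_schema_error", sprintf(
      "unexpected column(s) in '%s': %s", path, paste(extra, collapse = ", ")
    ))
  }
  invisible(header)
}

read_trial_csv <- function(path, expected, col_types) {
  if (!file.exists(path)) {
    stop_nw("nw_io_error", sprintf("file not found: '%s'", path))
  }
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  check_header(trimws(header), expected, path)
  df <- suppressWarnings(
    readr::read_csv(path, col_types = col_types, progress = FALSE)
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop_nw("nw_parse_error", sprintf(
      "could not parse '%s' at data row %d, column '%s': expected %s, got '%s'",
      path, probs$row[1] - 1L, names(df)[probs$col[1]],
      probs$expected[1], probs$actual[1]
    ))
  }
  df[expected]
}

row_fail <- function(bad, what) {
  stop_nw("nw_validation_error", sprintf(
    "%s at data row(s) %s", what, paste(which(bad), collapse = ", ")
  ))
}

validate_common <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  bad_group <- !(df$group %in% .group_levels)
  if (any(bad_group)) row_fail(bad_group, "group must be control/neglect/unknown")
  bad_idx <- is.na(df$trial_index) | df$trial_index < 0
  if (any(bad_idx)) row_fail(bad_idx, "trial_index must be a non-negative integer")
  num <- intersect(names(df), c("left_mm", "right_mm", "response_mm",
                                "bisection_response_mm", "reproduced_mm"))
  for (col in num) {
    bad <- !is.finite(df[[col]])
    if (any(bad)) row_fail(bad, sprintf("non-finite value in '%s'", col))
  }
  bad_line <- df$left_mm >= df$right_mm
  if (any(bad_line)) row_fail(bad_line, "left_mm must be < right_mm")
  invisible(df)
}

#' Validate a table of line bisection trials
#'
#' Checks the bisection trial schema: columns `participant_id`, `group`
#' (control/neglect/unknown), `trial_index` (non-negative integer), and the
#' millimetre coordinates `left_mm < right_mm` and `response_mm`, all finite.
#'
#' @param trials A data frame of bisection trials.
#' @return The validated trials as a tibble, invisibly usable in pipelines.
#' @export
validate_bisection_trials <- function(trials) {
  check_header(names(trials), .bisection_cols, "<data frame>")
  trials <- as_tibble(trials)[.bisection_cols]
  validate_common(trials)
  trials
}

#' Validate a table of endpoint reproduction trials
#'
#' As [validate_bisection_trials()], for the reproduction schema: the real
#' endpoints `left_mm < right_mm`, the paired `bisection_response_mm`,
#' `probed_side` (`"left"` or `"right"`) and the touched `reproduced_mm`.
#'
#' @param trials A data frame of reproduction trials.
#' @return The validated trials as a tibble.
#' @export
validate_reproduction_trials <- function(trials) {
  check_header(names(trials), .reproduction_cols, "<data frame>")
  trials <- as_tibble(trials)[.reproduction_cols]
  if (nrow(trials) > 0) {
    bad_side <- !(trials$probed_side %in% c("left", "right"))
    if (any(bad_side)) row_fail(bad_side, "probed_side must be 'left' or 'right'")
  }
  validate_common(trials)
  trials
}

#' Read line bisection trials from CSV
#'
#' Reads a long-format trial table, one row per bisection response, with
#' header `participant_id,group,trial_index,left_mm,right_mm,response_mm`.
#' Schema mismatches, unparseable numbers and inverted endpoints raise classed
#' errors naming the offending column or row.
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated bisection trials, row order preserved.
#' @seealso [write_bisection_csv()], [derive_bisection_measures()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("participant_id,group,trial_index,left_mm,right_mm,response_mm",
#'              "P01,control,1,-50,50,0"), f)
#' read_bisection_csv(f)
read_bisection_csv <- function(path) {
  df <- read_trial_csv(path, .bisection_cols, readr::cols(
    participant_id = readr::col_character(),
    group = readr::col_character(),
    trial_index = readr::col_integer(),
    left_mm = readr::col_double(),
    right_mm = readr::col_double(),
    response_mm = readr::col_double()
  ))
  validate_common(df)
  df
}

#' Read endpoint reproduction trials from CSV
#'
#' Header: `participant_id,group,trial_index,left_mm,right_mm,`
#' `bisection_response_mm,probed_side,reproduced_mm`. `probed_side` says which
#' real endpoint the reproduced position is compared against.
#'
#' @inheritParams read_bisection_csv
#' @return A tibble of validated reproduction trials.
#' @export
read_reproduction_csv <- function(path) {
  df <- read_trial_csv(path, .reproduction_cols, readr::cols(
    participant_id = readr::col_character(),
    group = readr::col_character(),
    trial_index = readr::col_integer(),
    left_mm = readr::col_double(),
    right_mm = readr::col_double(),
    bisection_response_mm = readr::col_double(),
    probed_side = readr::col_character(),
    reproduced_mm = readr::col_double()
  ))
  validate_reproduction_trials(df)
}

round6 <- function(df) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], round, digits = 6)
  df
}

#' Write trial tables to CSV
#'
#' Writes the validated table in the schema read back by
#' [read_bisection_csv()] / [read_reproduction_csv()]. Coordinates are stored
#' as decimal text rounded to 6 fractional digits, so a write/read round trip
#' is lossless at that precision.
#'
#' @param trials A trial table in the matching schema.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bisection_csv <- function(trials, path) {
  trials <- validate_bisection_trials(trials)
  readr::write_csv(round6(trials), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_bisection_csv
#' @export
write_reproduction_csv <- function(trials, path) {
  trials <- validate_reproduction_trials(trials)
  readr::write_csv(round6(trials), path, progress = FALSE)
  invisible(path)
}

#' Derive directional bisection error and line length
#'
#' Adds the classical per-trial measures: `dbe_mm = response_mm − (left_mm +
#' right_mm)/2` (directional bisection error, rightward positive, so left
#' neglect gives positive values and the short-line cross-over shows up as
#' negative values) and `length_mm = right_mm − left_mm`. Both are invariant
#' under translation of all coordinates.
#'
#' @param trials A bisection trial table.
#' @return The input tibble with `dbe_mm` and `length_mm` columns appended.
#' @export
#' @examples
#' trials <- tibble::tibble(
#'   participant_id = "P01", group = "neglect", trial_index = 1L,
#'   left_mm = -125, right_mm = 125, response_mm = 12
#' )
#' derive_bisection_measures(trials)
derive_bisection_measures <- function(trials) {
  trials <- validate_bisection_trials(trials)
  dplyr::mutate(trials,
    dbe_mm = .data$response_mm - (.data$left_mm + .data$right_mm) / 2,
    length_mm = .data$right_mm - .data$left_mm
  )
}
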