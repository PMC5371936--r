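#' Validate a cohort census table
#'
#' A cohort census records one row per individual per census day, with columns
#' `cohort_id`, `individual_id`, `day` (non-negative integer, 0 = cohort
#' start), `stage` (a label from the schema) and `status` (`"alive"` or
#' `"dead"`). An optional `sex` column (`"female"`/`"male"`/`NA`) is allowed.
#' Validation enforces:
#'
#' * days strictly increase within an individual;
#' * stage index never decreases over an individual's alive records
#'   (no reverse molts);
#' * death is absorbing: no record of any kind after a `dead` record.
#'
#' @param census A data frame with the columns above.
#' @param schema A [stage_schema()] the stage labels must resolve against.
#' @return The validated census as a tibble, invisibly usable in pipes.
#' @examples
#' census <- tibble::tibble(
#'   cohort_id = "c1", individual_id = "i1", day = 0:2,
#'   stage = c("egg", "egg", "larva"), status = "alive"
#' )
#' validate_census(census, cbb_schema())
#' @export
validate_census <- function(census, schema) {
  stopifnot(inherits(schema, "stage_schema"))
  census <- as_tibble(census)
  required <- c("cohort_id", "individual_id", "day", "stage", "status")
  missing <- setdiff(required, names(census))
  if (length(missing) > 0) {
    abort(paste0(
      "Census is missing required column(s): ",
      paste(missing, collapse = ", "), "."
    ), class = "cohortdem_validation_error")
  }
  if (nrow(census) == 0) {
    abort("Census has no records.", class = "cohortdem_validation_error")
  }
  if (any(census$day < 0) || any(census$day != floor(census$day))) {
    abort("`day` must be a non-negative integer.",
      class = "cohortdem_validation_error"
    )
  }
  if (!all(as.character(census$status) %in% c("alive", "dead"))) {
    abort("`status` must be 'alive' or 'dead'.",
      class = "cohortdem_validation_error"
    )
  }
  idx <- stage_index(census$stage, schema, context = "census row")

  ord <- order(census$cohort_id, census$individual_id, census$day)
  key <- paste(census$cohort_id[ord], census$individual_id[ord], sep = "\r")
  same <- key[-1] == key[-length(key)]
  day_o <- census$day[ord]
  idx_o <- idx[ord]
  dead_o <- as.character(census$status)[ord] == "dead"

  if (any(same & diff(day_o) <= 0)) {
    bad <- which(same & diff(day_o) <= 0)[1]
    abort(sprintf(
      "Duplicate or non-increasing census days for individual '%s' (cohort '%s').",
      census$individual_id[ord][bad], census$cohort_id[ord][bad]
    ), class = "cohortdem_validation_error")
  }
  if (any(same & dead_o[-length(dead_o)])) {
    bad <- which(same & dead_o[-length(dead_o)])[1]
    abort(sprintf(
      "Individual '%s' (cohort '%s') has a record after being recorded dead; death is absorbing.",
      census$individual_id[ord][bad], census$cohort_id[ord][bad]
    ), class = "cohortdem_validation_error")
  }
  alive_pair <- same & !dead_o[-1] # alive -> next alive record of same ind.
  if (any(alive_pair & diff(idx_o) < 0)) {
    bad <- which(alive_pair & diff(idx_o) < 0)[1]
    abort(sprintf(
      "Individual '%s' (cohort '%s') regresses in stage on day %d; reverse molts are not supported.",
      census$individual_id[ord][bad + 1], census$cohort_id[ord][bad + 1],
      day_o[bad + 1]
    ), class = "cohortdem_validation_error")
  }
  census
}

#' Read a cohort census CSV
#'
#' The file must be comma-separated UTF-8 with a header row and columns
#' `cohort_id,individual_id,day,stage,status` (extra columns such as `sex`
#' are kept). The table is validated against the schema; see
#' [validate_census()] for the invariants.
#'
#' @param path Path to a census CSV file.
#' @param schema A [stage_schema()].
#' @return A validated census tibble.
#' @export
read_census <- function(path, schema) {
  census <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_census(census, schema)
}

#' Write a cohort census CSV
#' @param census A census tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  readr::write_csv(census, path, progress = FALSE)
  invisible(path)
}

#' Validate an oviposition table
#'
#' One row per female per observed day: columns `female_id`, `treatment`,
#' `day` (non-negative integer) and `eggs` (non-negative integer count).
#' Within a female, `(female_id, day)` must be unique. Days with no record
#' inside a female's observation window are interpreted as zero-egg days by
#' downstream fertility estimation.
#'
#' @param oviposition A data frame with the columns above.
#' @return The validated table as a tibble.
#' @export
validate_oviposition <- function(oviposition) {
  oviposition <- as_tibble(oviposition)
  required <- c("female_id", "treatment", "day", "eggs")
  missing <- setdiff(required, names(oviposition))
  if (length(missing) > 0) {
    abort(paste0(
      "Oviposition table is missing required column(s): ",
      paste(missing, collapse = ", "), "."
    ), class = "cohortdem_validation_error")
  }
  if (nrow(oviposition) == 0) {
    abort("Oviposition table has no records.",
      class = "cohortdem_validation_error"
    )
  }
  if (any(oviposition$day < 0) || any(oviposition$day != floor(oviposition$day))) {
    abort("`day` must be a non-negative integer.",
      class = "cohortdem_validation_error"
    )
  }
  if (any(oviposition$eggs < 0) || any(oviposition$eggs != floor(oviposition$eggs))) {
    abort("`eggs` must be a non-negative integer count.",
      class = "cohortdem_validation_error"
    )
  }
  if (anyDuplicated(oviposition[, c("treatment", "female_id", "day")]) > 0) {
    abort("Duplicate (female_id, day) records in oviposition table.",
      class = "cohortdem_validation_error"
    )
  }
  oviposition
}

#' Read an oviposition CSV
#'
#' Columns `female_id,treatment,day,eggs`; see [validate_oviposition()].
#'
#' @param path Path to an oviposition CSV file.
#' @return A validated oviposition tibble.
#' @export
read_oviposition <- function(path) {
  ovi <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_oviposition(ovi)
}

#' Write an oviposition CSV
#' @param oviposition An oviposition tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_oviposition <- function(oviposition, path) {
  readr::write_csv(oviposition, path, progress = FALSE)
  invisible(path)
}
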