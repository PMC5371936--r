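#' Define a stage schema
#'
#' A stage schema names the developmental stages in order, identifies the
#' reproductive stage (which must be the last stage), and fixes the projection
#' interval: the number of days per time step of the projection matrix.
#'
#' @param stages Character vector of unique stage names, in developmental
#'   order (first stage = newborn stage).
#' @param reproductive_stage Name of the stage with nonzero fertility.
#'   Must equal the last element of `stages`.
#' @param interval_days Positive integer, days per projection-matrix time step.
#'
#' @return An object of class `stage_schema`.
#' @examples
#' stage_schema(c("egg", "larva", "adult"), interval_days = 6)
#' @export
stage_schema <- function(stages,
                         reproductive_stage = stages[length(stages)],
                         interval_days = 6) {
  stages <- as.character(stages)
  if (length(stages) < 1 || anyDuplicated(stages)) {
    abort("`stages` must be a non-empty vector of unique stage names.")
  }
  if (!identical(reproductive_stage, stages[length(stages)])) {
    abort(sprintf(
      "`reproductive_stage` ('%s') must be the last stage in order ('%s').",
      reproductive_stage, stages[length(stages)]
    ))
  }
  interval_days <- as.integer(interval_days)
  if (length(interval_days) != 1 || is.na(interval_days) || interval_days < 1) {
    abort("`interval_days` must be a single positive integer.")
  }
  structure(
    list(
      stages = stages,
      reproductive_stage = reproductive_stage,
      interval_days = interval_days
    ),
    class = "stage_schema"
  )
}

#' Coffee berry borer stage schema
#'
#' The six-stage life cycle used throughout: egg, larva, pre-pupa, pupa,
#' juvenile, adult, projected at 6-day intervals.
#'
#' @param interval_days Days per projection step (default 6).
#' @return A [stage_schema()].
#' @examples
#' cbb_schema()
#' @export
cbb_schema <- function(interval_days = 6) {
  stage_schema(
    c("egg", "larva", "prepupa", "pupa", "juvenile", "adult"),
    interval_days = interval_days
  )
}

#' @export
print.stage_schema <- function(x, ...) {
  cat("<stage_schema> ", length(x$stages), " stages: ",
    paste(x$stages, collapse = " -> "),
    "\n  reproductive stage: ", x$reproductive_stage,
    "; projection interval: ", x$interval_days, " days\n",
    sep = ""
  )
  invisible(x)
}

#' Number of stages in a schema
#' @param schema A [stage_schema()].
#' @return Integer number of stages.
#' @export
n_stages <- function(schema) {
  stopifnot(inherits(schema, "stage_schema"))
  length(schema$stages)
}

# resolve stage labels against a schema; error names the offending label/row
stage_index <- function(stage, schema, context = "record") {
  idx <- match(as.character(stage), schema$stages)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    abort(sprintf(
      "Unknown stage label '%s' (%s %d); schema stages are: %s.",
      as.character(stage)[bad], context, bad,
      paste(schema$stages, collapse = ", ")
    ), class = "cohortdem_schema_error")
  }
  idx
}
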