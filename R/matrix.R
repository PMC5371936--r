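#' Assemble a Lefkovitch projection matrix
#'
#' Builds the stage-structured projection matrix with stasis probabilities
#' `P` on the diagonal, growth (molt) probabilities `G` on the subdiagonal,
#' and fertility `fertility` of the reproductive (last) stage in the
#' top-right entry. All other entries are exactly zero. With `s` stages the
#' matrix maps the stage-abundance vector one projection interval forward:
#' `N[t+1] = A N[t]`.
#'
#' @param P Numeric vector of length `s`: per-interval probability of
#'   surviving and remaining in each stage.
#' @param G Numeric vector of length `s - 1`: per-interval probability of
#'   surviving and advancing out of each non-terminal stage.
#' @param fertility Non-negative scalar: offspring per reproductive female
#'   per interval (top-right entry).
#' @param schema A [stage_schema()] with `s` stages.
#' @param adult_survival_override Optional probability replacing the last
#'   diagonal entry (adult stasis). Insect life-table studies often fix adult
#'   survival externally (e.g. 0.99 per interval) when observed adult
#'   mortality is too rare to estimate; `NULL` keeps the supplied `P[s]`.
#' @return An object of class `projection_matrix` with elements `schema`,
#'   `P`, `G`, `fertility` and `A` (the assembled matrix).
#' @examples
#' schema <- stage_schema(c("juvenile", "adult"), interval_days = 6)
#' projection_matrix(P = c(0, 0.8), G = 0.5, fertility = 10, schema = schema)
#' @export
projection_matrix <- function(P, G, fertility, schema,
                              adult_survival_override = NULL) {
  stopifnot(inherits(schema, "stage_schema"))
  s <- n_stages(schema)
  P <- as.double(P)
  G <- as.double(G)
  fertility <- as.double(fertility)
  if (length(P) != s) {
    abort(sprintf("`P` must have length %d (one entry per stage).", s))
  }
  if (length(G) != s - 1) {
    abort(sprintf("`G` must have length %d (stages except the last).", s - 1))
  }
  if (length(fertility) != 1 || is.na(fertility) || fertility < 0) {
    abort("`fertility` must be a single non-negative number.")
  }
  if (!is.null(adult_survival_override)) {
    adult_survival_override <- as.double(adult_survival_override)
    if (length(adult_survival_override) != 1 ||
      adult_survival_override < 0 || adult_survival_override > 1) {
      abort("`adult_survival_override` must be a probability.")
    }
    P[s] <- adult_survival_override
  }
  check_stage_probs(P, G, schema)
  A <- matrix(0, s, s, dimnames = list(schema$stages, schema$stages))
  diag(A) <- P
  if (s > 1) {
    A[cbind(2:s, 1:(s - 1))] <- G
    A[1, s] <- fertility
  } else {
    A[1, 1] <- P + fertility
  }
  structure(
    list(schema = schema, P = P, G = G, fertility = fertility, A = A),
    class = "projection_matrix"
  )
}

check_stage_probs <- function(P, G, schema) {
  s <- length(P)
  if (anyNA(P) || any(P < 0) || any(P > 1)) {
    abort("Stasis probabilities `P` must lie in [0, 1].",
      class = "cohortdem_validation_error"
    )
  }
  if (s > 1 && (anyNA(G) || any(G < 0) || any(G > 1))) {
    abort("Growth probabilities `G` must lie in [0, 1].",
      class = "cohortdem_validation_error"
    )
  }
  tot <- P[-s] + G
  if (s > 1 && any(tot > 1 + 1e-12)) {
    bad <- which(tot > 1 + 1e-12)[1]
    abort(sprintf(
      "P + G exceeds 1 for stage '%s' (%.6f); survival cannot exceed 1.",
      schema$stages[bad], tot[bad]
    ), class = "cohortdem_validation_error")
  }
  invisible(TRUE)
}

#' @export
print.projection_matrix <- function(x, digits = 4, ...) {
  cat("<projection_matrix> ", n_stages(x$schema), " stages, interval ",
    x$schema$interval_days, " days\n",
    sep = ""
  )
  print(round(x$A, digits))
  invisible(x)
}

#' @describeIn projection_matrix Extract the plain numeric matrix.
#' @param x A `projection_matrix`.
#' @export
as_matrix <- function(x) {
  if (inherits(x, "projection_matrix")) {
    return(x$A)
  }
  if (is.matrix(x)) {
    return(x)
  }
  abort("Cannot interpret `x` as a projection matrix.")
}

# positional class of each matrix entry: P1..Ps on the diagonal, G1..G(s-1)
# on the subdiagonal, F in the top-right corner, "" elsewhere
entry_terms <- function(s) {
  term <- matrix("", s, s)
  diag(term) <- paste0("P", seq_len(s))
  if (s > 1) {
    term[cbind(2:s, 1:(s - 1))] <- paste0("G", seq_len(s - 1))
    term[1, s] <- "F"
  }
  term
}

#' @export
tidy.projection_matrix <- function(x, ...) {
  s <- n_stages(x$schema)
  term <- entry_terms(s)
  out <- tibble(
    row = rep(seq_len(s), times = s),
    col = rep(seq_len(s), each = s),
    from = x$schema$stages[rep(seq_len(s), each = s)],
    to = x$schema$stages[rep(seq_len(s), times = s)],
    term = as.vector(term),
    value = as.vector(x$A)
  )
  dplyr::filter(out, .data$term != "" | .data$value != 0)
}

#' Validate the structural mask of a projection matrix
#'
#' Checks the structure invariants: probabilities in range, `P + G <= 1`
#' per stage, non-negative fertility, and zeros everywhere outside the
#' diagonal, subdiagonal and top-right entry.
#'
#' @param m A `projection_matrix`.
#' @return `m`, invisibly, or an error.
#' @export
validate_projection_matrix <- function(m) {
  stopifnot(inherits(m, "projection_matrix"))
  s <- n_stages(m$schema)
  check_stage_probs(m$P, m$G, m$schema)
  if (m$fertility < 0) {
    abort("Fertility must be non-negative.",
      class = "cohortdem_validation_error"
    )
  }
  mask <- entry_terms(s) != ""
  if (s == 1) mask[1, 1] <- TRUE
  if (any(m$A[!mask] != 0)) {
    bad <- which(!mask & m$A != 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Nonzero entry at (%d, %d) violates the Lefkovitch structure (only stasis, growth and top-right fertility entries may be nonzero).",
      bad[1], bad[2]
    ), class = "cohortdem_validation_error")
  }
  if (any(m$A < 0)) {
    abort("Projection matrix must be non-negative.",
      class = "cohortdem_validation_error"
    )
  }
  invisible(m)
}

#' Write / read a projection matrix as JSON
#'
#' The JSON layout is
#' `{"schema": {"stages": [...], "interval_days": n}, "P": [...],
#' "G": [...], "F": x, "matrix": [[...], ...]}`. Values are serialized at
#' full double precision so that `read_matrix(write_matrix(m, p))`
#' reproduces `m` bit-exactly. On read the assembled matrix (when present)
#' is checked against the structural mask and the `P`/`G`/`F` blocks.
#'
#' @param m A `projection_matrix`.
#' @param path Output / input path.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()`
#'   returns a validated `projection_matrix`.
#' @export
write_matrix <- function(m, path) {
  validate_projection_matrix(m)
  payload <- list(
    schema = list(
      stages = m$schema$stages,
      interval_days = m$schema$interval_days
    ),
    P = m$P,
    G = m$G,
    F = m$fertility,
    matrix = unname(m$A)
  )
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (field in c("schema", "P", "G", "F")) {
    if (is.null(payload[[field]])) {
      abort(sprintf("Matrix JSON is missing the '%s' block.", field),
        class = "cohortdem_validation_error"
      )
    }
  }
  schema <- stage_schema(
    payload$schema$stages,
    interval_days = payload$schema$interval_days
  )
  m <- projection_matrix(
    P = payload$P, G = payload$G, fertility = payload$F, schema = schema
  )
  if (!is.null(payload$matrix)) {
    stored <- payload$matrix
    if (!is.matrix(stored)) {
      stored <- do.call(rbind, lapply(stored, as.double))
    }
    projection_matrix_from_raw(stored, schema) # errors on mask violation
    if (any(stored != m$A)) {
      abort(
        "Stored matrix block disagrees with the P/G/F blocks in the file.",
        class = "cohortdem_validation_error"
      )
    }
  }
  validate_projection_matrix(m)
  m
}

# rebuild from a raw numeric matrix, erroring if the mask is violated
projection_matrix_from_raw <- function(A, schema) {
  s <- n_stages(schema)
  if (!is.matrix(A) || nrow(A) != s || ncol(A) != s) {
    abort("Stored matrix block has the wrong dimensions.",
      class = "cohortdem_validation_error"
    )
  }
  mask <- entry_terms(s) != ""
  if (s == 1) mask[1, 1] <- TRUE
  if (any(A[!mask] != 0)) {
    bad <- which(!mask & A != 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Nonzero entry at (%d, %d) in matrix file violates the Lefkovitch structure.",
      bad[1], bad[2]
    ), class = "cohortdem_validation_error")
  }
  projection_matrix(
    P = diag(A),
    G = if (s > 1) A[cbind(2:s, 1:(s - 1))] else double(),
    fertility = if (s > 1) A[1, s] else 0,
    schema = schema
  )
}

#' @export
autoplot.projection_matrix <- function(object, ...) {
  td <- tidy(object)
  td$from <- factor(td$from, levels = object$schema$stages)
  td$to <- factor(td$to, levels = rev(object$schema$stages))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$from, y = .data$to)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$value), colour = "grey70") +
    ggplot2::geom_text(ggplot2::aes(
      label = paste0(.data$term, "\n", signif(.data$value, 3))
    ), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      x = "stage at t", y = "stage at t + 1", fill = "rate",
      title = "Projection matrix"
    ) +
    ggplot2::theme_minimal()
}
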