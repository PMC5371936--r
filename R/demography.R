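#' Project a stage-abundance vector forward
#'
#' Iterates `N[t+1] = A N[t]` for `steps` projection intervals and returns
#' the whole trajectory in long form.
#'
#' @param A A [projection_matrix()] or plain non-negative matrix.
#' @param n0 Non-negative numeric vector of initial stage abundances.
#' @param steps Positive integer number of projection steps.
#' @return A tibble with columns `step` (0..steps), `stage`, `abundance`,
#'   of class `cohort_projection`.
#' @examples
#' schema <- stage_schema(c("juvenile", "adult"), interval_days = 6)
#' A <- projection_matrix(c(0, 0), G = 0.5, fertility = 2, schema = schema)
#' project(A, c(1, 0), steps = 4)
#' @export
project <- function(A, n0, steps) {
  M <- as_matrix(A)
  s <- nrow(M)
  if (length(n0) != s) {
    abort(sprintf("`n0` must have length %d.", s))
  }
  if (any(n0 < 0) || anyNA(n0)) {
    abort("Initial abundances must be non-negative.")
  }
  steps <- as.integer(steps)
  if (steps < 1) abort("`steps` must be a positive integer.")
  stages <- colnames(M) %||% paste0("stage", seq_len(s))
  traj <- matrix(0, steps + 1, s, dimnames = list(NULL, stages))
  traj[1, ] <- n0
  n <- as.double(n0)
  for (t in seq_len(steps)) {
    n <- drop(M %*% n)
    traj[t + 1, ] <- n
  }
  out <- tibble(
    step = rep(0:steps, times = s),
    stage = rep(stages, each = steps + 1),
    abundance = as.vector(traj)
  )
  class(out) <- c("cohort_projection", class(out))
  out
}

#' @export
autoplot.cohort_projection <- function(object, log10 = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$step, y = .data$abundance, colour = .data$stage
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "projection step", y = "abundance",
      title = "Projected stage abundances"
    ) +
    ggplot2::theme_minimal()
  if (log10) p <- p + ggplot2::scale_y_log10()
  p
}

# dominant eigen-pair of a non-negative matrix; Perron-Frobenius guarantees
# a real non-negative dominant root, so any imaginary residue is numerical
dominant_eigen <- function(M, left = FALSE) {
  e <- eigen(if (left) t(M) else M)
  i <- which.max(Mod(e$values))
  lam <- e$values[i]
  if (abs(Im(lam)) > 1e-8 * max(1, Mod(lam))) {
    abort("Dominant eigenvalue has a non-negligible imaginary part; is the matrix non-negative?")
  }
  vec <- Re(e$vectors[, i])
  if (sum(vec) < 0) vec <- -vec
  list(value = Re(lam), vector = vec)
}

#' Population growth rate (dominant eigenvalue)
#'
#' The per-interval multiplicative growth factor `lambda`: the eigenvalue of
#' largest modulus of the projection matrix, real and non-negative for any
#' non-negative matrix.
#'
#' @param A A [projection_matrix()] or plain non-negative matrix.
#' @param method `"eigen"` (direct eigendecomposition, default) or
#'   `"power"` (power iteration; useful as an independent numerical check).
#' @param tol Convergence tolerance for power iteration.
#' @param max_iter Iteration cap for power iteration.
#' @return `lambda` (scalar).
#' @examples
#' schema <- stage_schema(c("juvenile", "adult"), interval_days = 6)
#' A <- projection_matrix(c(0, 0), G = 0.5, fertility = 2, schema = schema)
#' growth_rate(A) # sqrt(F * G) = 1
#' @export
growth_rate <- function(A, method = c("eigen", "power"),
                        tol = 1e-13, max_iter = 100000L) {
  M <- as_matrix(A)
  if (any(M < 0)) abort("Projection matrix must be non-negative.")
  method <- match.arg(method)
  if (method == "eigen") {
    return(dominant_eigen(M)$value)
  }
  s <- nrow(M)
  # shift by the identity to break periodicity; lambda(A + I) = lambda(A) + 1
  Ms <- M + diag(s)
  v <- rep(1, s)
  lam_old <- 0
  for (i in seq_len(max_iter)) {
    v_new <- drop(Ms %*% v)
    nrm <- sum(abs(v_new))
    if (nrm == 0) {
      return(0)
    }
    v_new <- v_new / nrm
    lam <- sum(v_new * drop(Ms %*% v_new)) / sum(v_new * v_new)
    if (abs(lam - lam_old) < tol * max(1, abs(lam))) {
      return(lam - 1)
    }
    lam_old <- lam
    v <- v_new
  }
  lam_old - 1
}

#' Stable stage distribution and reproductive values
#'
#' `stable_distribution()` returns the right eigenvector of the dominant
#' eigenvalue scaled to sum to 1 (the long-run proportional stage
#' composition). `reproductive_value()` returns the left eigenvector scaled
#' so its inner product with the stable distribution equals 1 (each stage's
#' relative contribution to long-run growth).
#'
#' A reducible matrix (a broken stage chain: some growth probability equal
#' to zero below the reproductive stage, or zero fertility) triggers a
#' warning; the eigenvectors of the dominant block are still returned.
#'
#' @inheritParams growth_rate
#' @return A named numeric vector over stages.
#' @export
stable_distribution <- function(A) {
  M <- as_matrix(A)
  warn_if_reducible(A)
  w <- dominant_eigen(M)$vector
  w <- abs(w)
  setNames(w / sum(w), colnames(M))
}

#' @rdname stable_distribution
#' @export
reproductive_value <- function(A) {
  M <- as_matrix(A)
  warn_if_reducible(A)
  w <- dominant_eigen(M)$vector
  w <- abs(w) / sum(abs(w))
  v <- abs(dominant_eigen(M, left = TRUE)$vector)
  setNames(v / sum(v * w), colnames(M))
}

warn_if_reducible <- function(A) {
  if (!inherits(A, "projection_matrix")) {
    return(invisible(FALSE))
  }
  if ((length(A$G) > 0 && any(A$G == 0)) || A$fertility == 0) {
    warn("Projection matrix is reducible (a zero growth probability or zero fertility breaks the stage chain); eigen-structure refers to the dominant block.")
    return(invisible(TRUE))
  }
  invisible(FALSE)
}

#' Sensitivity and elasticity of the growth rate
#'
#' The sensitivity matrix has entries `S_ij = d lambda / d a_ij = v_i w_j`
#' with the reproductive-value and stable-distribution vectors normalised so
#' `<v, w> = 1`. The elasticity matrix rescales to proportional change,
#' `E_ij = (a_ij / lambda) S_ij`; elasticities are non-negative and sum to 1.
#'
#' @inheritParams growth_rate
#' @return A numeric matrix with stage dimnames.
#' @export
sensitivity <- function(A) {
  M <- as_matrix(A)
  w <- suppressWarnings(stable_distribution(A))
  v <- suppressWarnings(reproductive_value(A))
  S <- outer(v, w)
  dimnames(S) <- dimnames(M)
  S
}

#' @rdname sensitivity
#' @export
elasticity <- function(A) {
  M <- as_matrix(A)
  lam <- growth_rate(M)
  E <- (M / lam) * sensitivity(A)
  dimnames(E) <- dimnames(M)
  E
}

# split A into survival transitions U and fertilities Fm; for the Lefkovitch
# structure the only fertility entry is the top-right corner
split_survival_fertility <- function(A) {
  M <- as_matrix(A)
  s <- nrow(M)
  Fm <- matrix(0, s, s, dimnames = dimnames(M))
  if (inherits(A, "projection_matrix")) {
    if (s == 1) {
      Fm[1, 1] <- A$fertility
    } else {
      Fm[1, s] <- A$fertility
    }
  } else if (s > 1) {
    Fm[1, s] <- M[1, s]
  } else {
    abort("Cannot separate survival from fertility in a 1 x 1 plain matrix; supply a projection_matrix.")
  }
  list(U = M - Fm, Fm = Fm)
}

#' Net reproductive rate
#'
#' The expected lifetime offspring per newborn: the dominant eigenvalue of
#' `Fm (I - U)^-1`, where `U` holds the survival transitions (stasis and
#' growth) and `Fm` the fertilities, `(I - U)^-1` being the fundamental
#' matrix of expected interval counts spent in each stage.
#'
#' @inheritParams growth_rate
#' @return `R0` (scalar).
#' @examples
#' schema <- stage_schema(c("juvenile", "adult"), interval_days = 6)
#' A <- projection_matrix(c(0, 0.8), G = 0.5, fertility = 10, schema = schema)
#' net_reproductive_rate(A) # 10 * 0.5 / (1 - 0.8) = 25
#' @export
net_reproductive_rate <- function(A) {
  parts <- split_survival_fertility(A)
  s <- nrow(parts$U)
  rho <- max(Mod(eigen(parts$U, only.values = TRUE)$values))
  if (rho >= 1) {
    abort("Survival transitions have spectral radius >= 1 (an immortal stage); set adult_survival_override < 1.",
      class = "cohortdem_estimation_error"
    )
  }
  N <- solve(diag(s) - parts$U)
  R <- parts$Fm %*% N
  max(Re(eigen(R, only.values = TRUE)$values))
}

#' Mean generation time
#'
#' `T = ln(R0) / ln(lambda)`, in projection intervals: the time over which
#' the population grows by a factor of its net reproductive rate. Multiply
#' by the interval length for days.
#'
#' @param lambda Population growth rate per interval (> 0, != 1).
#' @param R0 Net reproductive rate (> 0).
#' @return Generation time in projection intervals.
#' @export
generation_time <- function(lambda, R0) {
  if (any(lambda <= 0) || any(R0 <= 0)) {
    abort("`lambda` and `R0` must be positive.")
  }
  if (any(lambda == 1)) {
    abort("Generation time is undefined at lambda = 1.")
  }
  log(R0) / log(lambda)
}

#' Full demographic analysis of a projection matrix
#'
#' Computes the growth rate, net reproductive rate, generation time,
#' stable stage distribution, reproductive values, and the sensitivity and
#' elasticity matrices in one call.
#'
#' @inheritParams growth_rate
#' @return An object of class `demography` with elements `lambda`, `R0`,
#'   `T_intervals`, `T_days` (using the schema's interval; equals
#'   `T_intervals` for a plain matrix), `w`, `v`, `S`, `E`, `schema`.
#'   Use [glance()] for a one-row parameter summary and [tidy()] for
#'   stage-level structure.
#' @examples
#' sim <- simulate_cohorts(control_config(seed = 1))
#' A <- estimate_projection_matrix(sim$census, sim$oviposition, cbb_schema())
#' demography(A)
#' @export
demography <- function(A) {
  M <- as_matrix(A)
  lam <- growth_rate(M)
  R0 <- net_reproductive_rate(A)
  Ti <- if (lam > 0 && lam != 1 && R0 > 0) generation_time(lam, R0) else NA_real_
  interval <- if (inherits(A, "projection_matrix")) {
    A$schema$interval_days
  } else {
    1L
  }
  structure(
    list(
      lambda = lam,
      R0 = R0,
      T_intervals = Ti,
      T_days = Ti * interval,
      w = suppressWarnings(stable_distribution(A)),
      v = suppressWarnings(reproductive_value(A)),
      S = sensitivity(A),
      E = elasticity(A),
      schema = if (inherits(A, "projection_matrix")) A$schema else NULL,
      matrix = M
    ),
    class = "demography"
  )
}

#' @export
print.demography <- function(x, digits = 4, ...) {
  cat("<demography>\n")
  cat(sprintf(
    "  lambda = %.*f per interval; R0 = %.*f; T = %.*f intervals (%.*f days)\n",
    digits, x$lambda, digits, x$R0, digits, x$T_intervals, digits, x$T_days
  ))
  cat("  stable stage distribution:\n")
  print(round(x$w, digits))
  invisible(x)
}

#' @export
glance.demography <- function(x, ...) {
  tibble(
    lambda = x$lambda,
    R0 = x$R0,
    T_intervals = x$T_intervals,
    T_days = x$T_days
  )
}

#' @export
tidy.demography <- function(x, ...) {
  stages <- names(x$w) %||% paste0("stage", seq_along(x$w))
  tibble(
    stage = stages,
    stable_stage = unname(x$w),
    reproductive_value = unname(x$v)
  )
}

#' @export
autoplot.demography <- function(object, ...) {
  td <- tidy(object) |>
    tidyr::pivot_longer(-"stage", names_to = "quantity", values_to = "value")
  td$stage <- factor(td$stage, levels = names(object$w))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$stage, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = "Stable stage distribution and reproductive values"
    ) +
    ggplot2::theme_minimal()
}

#' Summarise demographic parameters over replicate cohorts
#'
#' Takes one row per replicate (as returned by [glance()] on `demography`
#' objects, e.g. via `purrr::map_dfr`) and returns the mean and standard
#' error (`sd / sqrt(n)`) of each parameter — the usual "mean over cohorts"
#' presentation of insect life tables. With fewer than 2 replicates the SE
#' is `NA`. Replicates with an undefined (`NA`) value of a parameter — e.g.
#' the generation time of a cohort that failed before reproducing — are
#' dropped from that parameter's summary, and `n` reports the replicates
#' actually used.
#'
#' @param replicates A data frame with numeric parameter columns, one row
#'   per replicate cohort.
#' @param parameters Columns to summarise (default: all numeric columns).
#' @return A tibble with `parameter`, `mean`, `se`, `n`.
#' @export
replicate_summary <- function(replicates,
                              parameters = NULL) {
  replicates <- as_tibble(replicates)
  if (is.null(parameters)) {
    parameters <- names(replicates)[vapply(replicates, is.numeric, logical(1))]
  }
  if (nrow(replicates) < 2) {
    inform("Fewer than 2 replicates: standard errors are undefined (NA).")
  }
  replicates |>
    dplyr::select(dplyr::all_of(parameters)) |>
    tidyr::pivot_longer(
      dplyr::everything(),
      names_to = "parameter", values_to = "value"
    ) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = if (dplyr::n() >= 2) {
        stats::sd(.data$value) / sqrt(dplyr::n())
      } else {
        NA_real_
      },
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$parameter, parameters))
}
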