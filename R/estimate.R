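#' Tabulate stage transitions over projection intervals
#'
#' Pools interval-aligned transition counts over all cohorts and windows.
#' With interval `k` (from the schema), windows start at days
#' `0, k, 2k, ...`; an individual observed alive in stage `i` at a window
#' start contributes exactly once to that window:
#'
#' * `n_stay` if observed alive in the same stage one interval later;
#' * `n_advance` if observed alive in any later stage (multi-stage advances
#'   within one window count as an advance of the starting stage);
#' * `n_die` if recorded dead at or before the window end;
#' * otherwise (no record at the window end, not recorded dead) the
#'   individual is right-censored for that window and counts only in
#'   `n_start`.
#'
#' @param census A validated census tibble (see [validate_census()]).
#' @param schema A [stage_schema()].
#' @return A tibble with one row per stage: `stage`, `n_start`, `n_stay`,
#'   `n_advance`, `n_die`, `n_censored`.
#' @examples
#' census <- simulate_cohorts(control_config(seed = 1))$census
#' tabulate_transitions(census, cbb_schema())
#' @export
tabulate_transitions <- function(census, schema) {
  census <- validate_census(census, schema)
  k <- schema$interval_days
  horizon <- max(census$day)
  if (horizon < k) {
    abort(sprintf(
      "Census horizon (%d days) is shorter than one projection interval (%d days).",
      horizon, k
    ), class = "cohortdem_validation_error")
  }
  census$stage_idx <- stage_index(census$stage, schema)
  census$status <- as.character(census$status)

  # death is absorbing, so each individual has at most one dead record
  deaths <- census |>
    dplyr::filter(.data$status == "dead") |>
    dplyr::select("cohort_id", "individual_id", death_day = "day")

  starts <- seq(0, horizon - k, by = k)
  at_start <- census |>
    dplyr::filter(.data$status == "alive", .data$day %in% starts) |>
    dplyr::select("cohort_id", "individual_id",
      day_start = "day", start_idx = "stage_idx"
    )
  at_end <- census |>
    dplyr::select("cohort_id", "individual_id",
      day_end = "day", end_idx = "stage_idx", end_status = "status"
    )
  joined <- at_start |>
    dplyr::mutate(day_end = .data$day_start + k) |>
    dplyr::left_join(at_end,
      by = c("cohort_id", "individual_id", "day_end")
    ) |>
    dplyr::left_join(deaths, by = c("cohort_id", "individual_id")) |>
    dplyr::mutate(outcome = dplyr::case_when(
      !is.na(.data$end_status) & .data$end_status == "dead" ~ "die",
      !is.na(.data$end_status) & .data$end_idx == .data$start_idx ~ "stay",
      !is.na(.data$end_status) & .data$end_idx > .data$start_idx ~ "advance",
      is.na(.data$end_status) & !is.na(.data$death_day) &
        .data$death_day <= .data$day_end ~ "die",
      TRUE ~ "censored"
    ))

  counts <- joined |>
    dplyr::count(.data$start_idx, .data$outcome) |>
    tidyr::pivot_wider(
      names_from = "outcome", values_from = "n", values_fill = 0L
    )
  for (col in c("stay", "advance", "die", "censored")) {
    if (is.null(counts[[col]])) counts[[col]] <- 0L
  }
  tibble(stage = schema$stages, stage_idx = seq_along(schema$stages)) |>
    dplyr::left_join(counts, by = c(stage_idx = "start_idx")) |>
    dplyr::mutate(dplyr::across(
      c("stay", "advance", "die", "censored"),
      ~ tidyr::replace_na(.x, 0L)
    )) |>
    dplyr::transmute(
      stage = .data$stage,
      n_start = .data$stay + .data$advance + .data$die + .data$censored,
      n_stay = .data$stay,
      n_advance = .data$advance,
      n_die = .data$die,
      n_censored = .data$censored
    )
}

#' Estimate stasis and growth probabilities from transition counts
#'
#' Per-interval probabilities are the pooled binomial fractions
#' `P_i = n_stay / n_eff` and `G_i = n_advance / n_eff` with
#' `n_eff = n_stay + n_advance + n_die` (right-censored window entries are
#' excluded from the denominator). By construction `P_i + G_i <= 1`.
#'
#' @param transitions A tibble from [tabulate_transitions()].
#' @return A tibble with `stage`, `P`, `G` (`NA` for the last stage),
#'   and `n_effective`. Stages never reached have `P = G = 0` and
#'   `n_effective = 0`.
#' @export
estimate_stage_probs <- function(transitions) {
  required <- c("stage", "n_start", "n_stay", "n_advance", "n_die")
  if (!all(required %in% names(transitions))) {
    abort("`transitions` must come from tabulate_transitions().")
  }
  n_eff <- transitions$n_stay + transitions$n_advance + transitions$n_die
  reached <- transitions$n_start > 0
  starved <- reached & n_eff == 0
  if (any(starved)) {
    abort(sprintf(
      "Stage '%s' was reached but every interval entry was censored; cannot estimate its transition probabilities.",
      transitions$stage[which(starved)[1]]
    ), class = "cohortdem_estimation_error")
  }
  s <- nrow(transitions)
  P <- ifelse(n_eff > 0, transitions$n_stay / n_eff, 0)
  G <- ifelse(n_eff > 0, transitions$n_advance / n_eff, 0)
  tibble(
    stage = transitions$stage,
    P = P,
    G = c(G[-s], NA_real_),
    n_effective = as.integer(n_eff)
  )
}

#' Estimate per-interval fertility from an oviposition table
#'
#' Fertility is the mean daily egg-laying rate over all observed
#' female-days, scaled to the projection interval:
#' `F = sex_ratio_scale * interval_days * total_eggs / total_female_days`.
#' Non-ovipositing females contribute to the denominator. A female's
#' observed days span her observation window (first to last recorded day,
#' inclusive); days inside the window with no record count as zero-egg days.
#'
#' @param oviposition A validated oviposition tibble.
#' @param schema A [stage_schema()] (supplies `interval_days`).
#' @param sex_ratio_scale Factor in `[0, 1]` applied to fertility, e.g. the
#'   fraction of eggs that are female when fertility should count daughters
#'   only. Default 1 counts all eggs.
#' @return Fertility (offspring per female per projection interval).
#' @examples
#' ovi <- tibble::tibble(
#'   female_id = rep(c("f1", "f2"), each = 60),
#'   treatment = "control", day = rep(0:59, 2),
#'   eggs = rep(c(0L, 1L), 60)
#' )
#' estimate_fertility(ovi, cbb_schema()) # 6 * 60 / 120 = 3 eggs/interval
#' @export
estimate_fertility <- function(oviposition, schema, sex_ratio_scale = 1) {
  oviposition <- validate_oviposition(oviposition)
  stopifnot(inherits(schema, "stage_schema"))
  if (sex_ratio_scale < 0 || sex_ratio_scale > 1) {
    abort("`sex_ratio_scale` must lie in [0, 1].")
  }
  per_female <- oviposition |>
    dplyr::group_by(.data$female_id) |>
    dplyr::summarise(
      days = max(.data$day) - min(.data$day) + 1,
      eggs = sum(.data$eggs),
      .groups = "drop"
    )
  total_days <- sum(per_female$days)
  if (total_days <= 0) {
    abort("Zero observed female-days; cannot estimate fertility.",
      class = "cohortdem_estimation_error"
    )
  }
  sex_ratio_scale * schema$interval_days * sum(per_female$eggs) / total_days
}

#' Estimate a projection matrix from census and oviposition data
#'
#' End-to-end estimator: tabulates interval transitions from the census,
#' converts them to stasis/growth probabilities, estimates fertility from
#' the oviposition table, and assembles the projection matrix.
#'
#' @inheritParams tabulate_transitions
#' @inheritParams estimate_fertility
#' @param adult_survival_override Probability replacing the estimated adult
#'   stasis entry (default 0.99 per interval, the conventional value when
#'   adult deaths are too rare to estimate), or `NULL` to keep the estimate.
#' @param fertility Optional precomputed fertility, bypassing
#'   `oviposition` (used when one oviposition experiment serves several
#'   cohorts).
#' @return A [projection_matrix()].
#' @examples
#' sim <- simulate_cohorts(control_config(seed = 1))
#' estimate_projection_matrix(sim$census, sim$oviposition, cbb_schema())
#' @export
estimate_projection_matrix <- function(census, oviposition = NULL, schema,
                                       sex_ratio_scale = 1,
                                       adult_survival_override = 0.99,
                                       fertility = NULL) {
  if (is.null(fertility)) {
    if (is.null(oviposition)) {
      abort("Supply either `oviposition` or a precomputed `fertility`.")
    }
    fertility <- estimate_fertility(oviposition, schema, sex_ratio_scale)
  }
  probs <- census |>
    tabulate_transitions(schema) |>
    estimate_stage_probs()
  s <- nrow(probs)
  projection_matrix(
    P = probs$P,
    G = probs$G[-s],
    fertility = fertility,
    schema = schema,
    adult_survival_override = adult_survival_override
  )
}
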