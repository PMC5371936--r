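#' Pearson chi-square test of independence
#'
#' Classical Pearson statistic on an r x c contingency table of counts,
#' without continuity correction: `sum((O - E)^2 / E)` with
#' `E_ij = row_i * col_j / total` and `df = (r - 1)(c - 1)`.
#'
#' @param counts A numeric matrix, table or data frame of non-negative
#'   integer counts with at least 2 rows and 2 columns.
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @examples
#' # ovipositing vs not, per diet
#' tab <- rbind(
#'   tetracycline = c(ovipositing = 19, not = 31),
#'   control = c(34, 16),
#'   penicillin = c(33, 17)
#' )
#' chi_square_independence(tab) # statistic 11.50, df 2
#' @export
chi_square_independence <- function(counts) {
  m <- as.matrix(counts)
  storage.mode(m) <- "double"
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("Contingency table needs at least 2 rows and 2 columns.")
  }
  if (anyNA(m) || any(m < 0) || any(m != floor(m))) {
    abort("Counts must be non-negative integers.")
  }
  if (sum(m) <= 0) abort("Grand total must be positive.")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("A zero row or column margin makes expected counts zero; drop the empty category.",
      class = "cohortdem_validation_error"
    )
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value)
  )
}

#' Sex ratio summary over replicates
#'
#' Per-replicate female:male ratio, averaged across replicates (mean of
#' ratios, not ratio of means — the convention in per-vial insect rearing
#' summaries, and generally larger than the pooled ratio by Jensen's
#' inequality). Replicates with zero males are excluded with a warning.
#'
#' @param counts A data frame with numeric columns `females` and `males`,
#'   one row per replicate (vial/cohort).
#' @return A tibble with `mean_ratio`, `se`, `n_used`, `n_excluded`.
#' @examples
#' sex_ratio_summary(tibble::tibble(females = c(20, 24), males = c(2, 3)))
#' @export
sex_ratio_summary <- function(counts) {
  counts <- as_tibble(counts)
  if (!all(c("females", "males") %in% names(counts))) {
    abort("`counts` needs columns `females` and `males`.")
  }
  excluded <- counts$males == 0
  if (any(excluded)) {
    warn(sprintf(
      "%d replicate(s) with zero males excluded from the sex-ratio summary.",
      sum(excluded)
    ))
  }
  kept <- counts[!excluded, , drop = FALSE]
  if (nrow(kept) == 0) {
    abort("No replicates with males >= 1; sex ratio undefined.")
  }
  ratio <- kept$females / kept$males
  tibble(
    mean_ratio = mean(ratio),
    se = if (length(ratio) >= 2) sd(ratio) / sqrt(length(ratio)) else NA_real_,
    n_used = length(ratio),
    n_excluded = sum(excluded)
  )
}

#' Developmental-time summary from a daily census
#'
#' Per-individual stage duration is the number of daily census records
#' spent in the stage; only individuals that complete a stage (observed
#' alive in a later stage) contribute to that stage's mean. Egg-to-adult
#' time is the first adult census day minus the first egg census day,
#' over individuals reaching adulthood. Stages with no completions are
#' reported with `NA`.
#'
#' @inheritParams tabulate_transitions
#' @return A tibble with `stage` (each non-terminal stage plus
#'   `"egg_to_adult"`-style `first_to_last`), `mean_days`, `se`, `n`.
#' @export
developmental_time_summary <- function(census, schema) {
  census <- validate_census(census, schema)
  s <- n_stages(schema)
  alive <- census |>
    dplyr::filter(as.character(.data$status) == "alive") |>
    dplyr::mutate(stage_idx = stage_index(.data$stage, schema))

  per_stage <- alive |>
    dplyr::group_by(.data$cohort_id, .data$individual_id, .data$stage_idx) |>
    dplyr::summarise(
      n_days = dplyr::n(), first_day = min(.data$day), .groups = "drop"
    ) |>
    dplyr::group_by(.data$cohort_id, .data$individual_id) |>
    dplyr::mutate(max_idx = max(.data$stage_idx)) |>
    dplyr::ungroup()

  durations <- per_stage |>
    dplyr::filter(.data$stage_idx < .data$max_idx, .data$stage_idx < s) |>
    dplyr::group_by(.data$stage_idx) |>
    dplyr::summarise(
      mean_days = mean(.data$n_days),
      se = if (dplyr::n() >= 2) {
        sd(.data$n_days) / sqrt(dplyr::n())
      } else {
        NA_real_
      },
      n = dplyr::n(),
      .groups = "drop"
    )

  full_span <- per_stage |>
    dplyr::group_by(.data$cohort_id, .data$individual_id) |>
    dplyr::summarise(
      adult_day = .data$first_day[match(s, .data$stage_idx)],
      start_day = min(.data$first_day),
      .groups = "drop"
    ) |>
    dplyr::filter(!is.na(.data$adult_day)) |>
    dplyr::mutate(span = .data$adult_day - .data$start_day)

  out <- tibble(stage = schema$stages[-s], stage_idx = seq_len(s - 1)) |>
    dplyr::left_join(durations, by = "stage_idx") |>
    dplyr::select(-"stage_idx")
  total_label <- paste0(schema$stages[1], "_to_", schema$stages[s])
  total <- tibble(
    stage = total_label,
    mean_days = if (nrow(full_span) > 0) mean(full_span$span) else NA_real_,
    se = if (nrow(full_span) >= 2) {
      sd(full_span$span) / sqrt(nrow(full_span))
    } else {
      NA_real_
    },
    n = nrow(full_span)
  )
  dplyr::bind_rows(out, total)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test) across
#' groups; the workhorse comparison for per-cohort life-table parameters
#' and developmental times across diets.
#'
#' @param data A data frame, or a list of numeric vectors (one per group).
#' @param value,group Column names (strings) when `data` is a data frame.
#' @return A tibble with `statistic` (F), `df_between`, `df_within`,
#'   `p_value`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6))) # F = 13.5
#' @export
one_way_anova <- function(data, value = "value", group = "group") {
  if (is.list(data) && !is.data.frame(data)) {
    nm <- names(data) %||% paste0("g", seq_along(data))
    data <- tibble(
      value = unlist(data, use.names = FALSE),
      group = rep(nm, lengths(data))
    )
    value <- "value"
    group <- "group"
  }
  df <- tibble(
    value = as.double(data[[value]]),
    group = as.factor(data[[group]])
  )
  if (nlevels(df$group) < 2) abort("Need at least 2 groups.")
  if (any(table(df$group) < 2)) abort("Every group needs at least 2 values.")
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  f_stat <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  ssb <- tab[["Sum Sq"]][1]
  ssw <- tab[["Sum Sq"]][2]
  # guard numerically-zero within-group variance (aov reports a huge
  # finite F from rounding noise)
  if (ssw <= 1e-12 * (ssb + ssw)) {
    if (ssb > 0) {
      warn("Zero within-group variance with unequal means: F is infinite, p reported as 0.")
      f_stat <- Inf
      p <- 0
    } else {
      # all values identical everywhere: no variance to explain
      f_stat <- 0
      p <- 1
    }
  }
  tibble(
    statistic = f_stat,
    df_between = tab[["Df"]][1],
    df_within = tab[["Df"]][2],
    p_value = p
  )
}

#' Pairwise Welch t tests with Holm correction
#'
#' Post-hoc pairwise comparisons after a one-way ANOVA, using Welch
#' (unequal-variance) t tests with Holm-adjusted p values.
#'
#' @inheritParams one_way_anova
#' @return A tibble with `group1`, `group2`, `p_value` (Holm-adjusted).
#' @export
pairwise_welch <- function(data, value = "value", group = "group") {
  if (is.list(data) && !is.data.frame(data)) {
    nm <- names(data) %||% paste0("g", seq_along(data))
    data <- tibble(
      value = unlist(data, use.names = FALSE),
      group = rep(nm, lengths(data))
    )
    value <- "value"
    group <- "group"
  }
  pt <- stats::pairwise.t.test(
    as.double(data[[value]]), as.factor(data[[group]]),
    pool.sd = FALSE, p.adjust.method = "holm"
  )
  pv <- pt$p.value
  out <- as_tibble(as.table(pv), .name_repair = "minimal")
  names(out) <- c("group1", "group2", "p_value")
  dplyr::filter(out, !is.na(.data$p_value))
}

#' Descriptive oviposition summaries per treatment
#'
#' Group totals and egg-laying rates with exact Poisson confidence
#' intervals, plus the ovipositing/non-ovipositing contingency table used
#' by the chi-square comparison of the proportion of females that
#' oviposited.
#'
#' @param oviposition A validated oviposition tibble covering one or more
#'   treatments.
#' @param conf_level Confidence level for the exact Poisson interval.
#' @return A list with `rates` (per-treatment tibble: `n_females`,
#'   `female_days`, `total_eggs`, `eggs_per_female`, `eggs_per_female_day`
#'   with CI, `prop_ovipositing`) and `contingency` (treatments x
#'   ovipositing/not matrix of female counts).
#' @export
oviposition_group_summary <- function(oviposition, conf_level = 0.95) {
  oviposition <- validate_oviposition(oviposition)
  per_female <- oviposition |>
    dplyr::group_by(.data$treatment, .data$female_id) |>
    dplyr::summarise(
      days = max(.data$day) - min(.data$day) + 1,
      eggs = sum(.data$eggs),
      .groups = "drop"
    )
  rates <- per_female |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(
      n_females = dplyr::n(),
      female_days = sum(.data$days),
      total_eggs = sum(.data$eggs),
      eggs_per_female = mean(.data$eggs),
      prop_ovipositing = mean(.data$eggs > 0),
      .groups = "drop"
    ) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      eggs_per_female_day = .data$total_eggs / .data$female_days,
      rate_ci_low = stats::poisson.test(
        .data$total_eggs,
        T = .data$female_days, conf.level = conf_level
      )$conf.int[1],
      rate_ci_high = stats::poisson.test(
        .data$total_eggs,
        T = .data$female_days, conf.level = conf_level
      )$conf.int[2]
    ) |>
    dplyr::ungroup()
  contingency <- per_female |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(
      ovipositing = sum(.data$eggs > 0),
      not_ovipositing = sum(.data$eggs == 0),
      .groups = "drop"
    )
  mat <- as.matrix(contingency[, c("ovipositing", "not_ovipositing")])
  rownames(mat) <- contingency$treatment
  list(rates = rates, contingency = mat)
}
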