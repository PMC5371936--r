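#' Run the full demographic pipeline over treatments
#'
#' Orchestrates the whole analysis for one or more treatments: estimates a
#' projection matrix per cohort (stasis/growth probabilities per cohort;
#' fertility shared within a treatment, since one oviposition experiment
#' serves all its cohorts), derives per-cohort demographic parameters and
#' their replicate summaries, runs the LTRE of every treatment against the
#' named reference, and computes the treatment-comparison statistics
#' (ovipositing-female chi-square, oviposition rates, developmental times,
#' sex ratios, and one-way ANOVAs of the per-cohort parameters).
#'
#' @param treatments A named list. Each element is either a
#'   [simulation_config()] (the data are simulated) or a list with elements
#'   `census` and `oviposition` (observed tables).
#' @param reference Name of the reference treatment for the LTRE
#'   comparisons; `NULL` (allowed only with a single treatment) skips LTRE.
#' @param schema A [stage_schema()].
#' @param sex_ratio_scale,adult_survival_override Passed to
#'   [estimate_projection_matrix()].
#' @param seed Optional integer overriding the seed of every simulated
#'   treatment (offset by the treatment's position so treatments stay
#'   independent).
#' @return An object of class `cohort_pipeline`: a list with
#'   `matrices` (pooled per-treatment `projection_matrix` objects),
#'   `cohort_matrices`, `demography` (per-cohort parameter tibble),
#'   `summary` (per-treatment mean +/- SE of lambda, R0, T),
#'   `ltre` (named list of [ltre()] results vs the reference),
#'   `stats` (list: `chi_square`, `oviposition`, `development`,
#'   `sex_ratio`, `anova`) and `manifest` (seed and input hash).
#' @examples
#' \donttest{
#' res <- run_pipeline(
#'   list(control = control_config(), tetracycline = tetracycline_config()),
#'   reference = "control", seed = 1
#' )
#' res$summary
#' }
#' @export
run_pipeline <- function(treatments, reference = NULL,
                         schema = cbb_schema(),
                         sex_ratio_scale = 1,
                         adult_survival_override = 0.99,
                         seed = NULL) {
  if (is.null(names(treatments)) || any(names(treatments) == "")) {
    abort("`treatments` must be a named list.")
  }
  if (length(treatments) > 1 && is.null(reference)) {
    abort("Name a `reference` treatment for the LTRE comparisons.")
  }
  if (!is.null(reference) && !reference %in% names(treatments)) {
    abort(sprintf("Reference treatment '%s' is not among the treatments.", reference))
  }

  data <- purrr::imap(treatments, function(trt, name) {
    if (inherits(trt, "simulation_config")) {
      use_seed <- if (is.null(seed)) {
        trt$seed
      } else {
        derive_seed(seed, match(name, names(treatments)))
      }
      sim <- simulate_cohorts(trt, seed = use_seed)
      list(
        census = sim$census,
        oviposition = dplyr::mutate(sim$oviposition, treatment = name),
        simulated = TRUE, seed = use_seed
      )
    } else {
      list(
        census = validate_census(trt$census, schema),
        oviposition = dplyr::mutate(
          validate_oviposition(trt$oviposition),
          treatment = name
        ),
        simulated = FALSE, seed = NA_integer_
      )
    }
  })

  per_treatment <- purrr::imap(data, function(d, name) {
    fert <- estimate_fertility(d$oviposition, schema, sex_ratio_scale)
    inform(sprintf(
      "[%s] fertility %.4f offspring/female/interval from %d female-days",
      name, fert,
      sum(dplyr::count(d$oviposition, .data$female_id)$n)
    ))
    pooled <- estimate_projection_matrix(
      d$census, schema = schema,
      fertility = fert,
      adult_survival_override = adult_survival_override
    )
    cohorts <- split(d$census, d$census$cohort_id)
    cohort_matrices <- purrr::map(cohorts, function(cen) {
      estimate_projection_matrix(
        cen, schema = schema,
        fertility = fert,
        adult_survival_override = adult_survival_override
      )
    })
    cohort_glances <- purrr::imap_dfr(cohort_matrices, function(m, cid) {
      dplyr::mutate(
        glance(suppressWarnings(demography(m))),
        treatment = name, cohort_id = cid, .before = 1
      )
    })
    list(
      pooled = pooled, cohort_matrices = cohort_matrices,
      cohort_glances = cohort_glances, fertility = fert
    )
  })

  demography_tbl <- purrr::map_dfr(per_treatment, "cohort_glances")
  summary_tbl <- demography_tbl |>
    dplyr::group_by(.data$treatment) |>
    dplyr::group_modify(~ replicate_summary(
      .x,
      parameters = c("lambda", "R0", "T_days")
    )) |>
    dplyr::ungroup()

  ltre_results <- NULL
  if (!is.null(reference) && length(treatments) > 1) {
    others <- setdiff(names(treatments), reference)
    ltre_results <- purrr::map(
      setNames(others, others),
      ~ ltre(per_treatment[[.x]]$pooled, per_treatment[[reference]]$pooled)
    )
  } else if (length(treatments) == 1) {
    inform("Single treatment: LTRE comparison skipped.")
  }

  ovi_all <- purrr::map_dfr(data, "oviposition")
  ovi_summary <- oviposition_group_summary(ovi_all)
  chi <- if (length(treatments) > 1 &&
    all(colSums(ovi_summary$contingency) > 0)) {
    chi_square_independence(ovi_summary$contingency)
  } else {
    NULL
  }

  development <- purrr::imap_dfr(
    data,
    ~ dplyr::mutate(
      developmental_time_summary(.x$census, schema),
      treatment = .y, .before = 1
    )
  )

  sex_ratio <- purrr::imap_dfr(data, function(d, name) {
    if (!"sex" %in% names(d$census)) {
      return(tibble())
    }
    counts <- d$census |>
      dplyr::filter(!is.na(.data$sex), as.character(.data$status) == "alive") |>
      dplyr::group_by(.data$cohort_id, .data$individual_id) |>
      dplyr::slice_tail(n = 1) |>
      dplyr::group_by(.data$cohort_id) |>
      dplyr::summarise(
        females = sum(.data$sex == "female"),
        males = sum(.data$sex == "male"),
        .groups = "drop"
      )
    if (nrow(counts) == 0 || all(counts$males == 0)) {
      return(tibble())
    }
    dplyr::mutate(
      suppressWarnings(sex_ratio_summary(counts)),
      treatment = name, .before = 1
    )
  })

  anova_tbl <- NULL
  if (length(treatments) > 1 &&
    all(table(demography_tbl$treatment) >= 2)) {
    anova_tbl <- purrr::map_dfr(
      c("lambda", "R0", "T_days"),
      function(par) {
        dplyr::mutate(
          one_way_anova(demography_tbl, value = par, group = "treatment"),
          parameter = par, .before = 1
        )
      }
    )
  }

  structure(
    list(
      matrices = purrr::map(per_treatment, "pooled"),
      cohort_matrices = purrr::map(per_treatment, "cohort_matrices"),
      demography = demography_tbl,
      summary = summary_tbl,
      ltre = ltre_results,
      stats = list(
        chi_square = chi,
        oviposition = ovi_summary$rates,
        contingency = ovi_summary$contingency,
        development = development,
        sex_ratio = sex_ratio,
        anova = anova_tbl
      ),
      manifest = list(
        seed = seed,
        treatment_seeds = purrr::map(data, "seed"),
        reference = reference,
        hash = rlang::hash(list(
          treatments = treatments, reference = reference, seed = seed,
          sex_ratio_scale = sex_ratio_scale,
          adult_survival_override = adult_survival_override
        ))
      )
    ),
    class = "cohort_pipeline"
  )
}

#' @export
print.cohort_pipeline <- function(x, ...) {
  cat("<cohort_pipeline> ", length(x$matrices), " treatment(s)\n", sep = "")
  print(dplyr::mutate(
    x$summary,
    dplyr::across(dplyr::where(is.numeric), ~ round(.x, 2))
  ))
  if (!is.null(x$ltre)) {
    for (nm in names(x$ltre)) {
      cat("LTRE ", nm, " vs ", x$manifest$reference, ": ", sep = "")
      cs <- class_summaries(x$ltre[[nm]])
      top <- cs[which.max(abs(cs$contribution)), ]
      cat(sprintf(
        "delta lambda = %.4f, largest contribution %s (%.4f)\n",
        x$ltre[[nm]]$delta_lambda_observed, top$term, top$contribution
      ))
    }
  }
  invisible(x)
}
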