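test_that("interval transition counts match a hand count", {
  counts <- tabulate_transitions(hand_census(), schema6)
  egg <- counts[counts$stage == "egg", ]
  expect_equal(egg$n_start, 10L)
  expect_equal(egg$n_stay, 4L)
  expect_equal(egg$n_advance, 4L)
  expect_equal(egg$n_die, 2L)
  expect_equal(egg$n_censored, 0L)
})

test_that("a multi-stage advance within one window counts as one advance", {
  census <- tibble::tibble(
    cohort_id = "c1", individual_id = "i1", day = c(0L, 6L),
    stage = c("egg", "prepupa"), status = "alive"
  )
  counts <- tabulate_transitions(census, schema6)
  expect_equal(counts$n_advance[counts$stage == "egg"], 1L)
  expect_equal(sum(counts$n_advance), 1L)
})

test_that("censored window entries stay out of denominators and zero denominators error", {
  census <- dplyr::bind_rows(
    tibble::tibble(
      cohort_id = "c1", individual_id = paste0("i", 1:3),
      day = 0L, stage = "egg", status = "alive"
    ),
    # one later individual anchors the horizon but enters no day-0 window
    tibble::tibble(
      cohort_id = "c1", individual_id = "i9",
      day = 6L, stage = "larva", status = "alive"
    )
  )
  counts <- tabulate_transitions(census, schema6)
  egg <- counts[counts$stage == "egg", ]
  expect_equal(egg$n_start, 3L)
  expect_equal(egg$n_censored, 3L)
  expect_equal(egg$n_stay + egg$n_advance + egg$n_die, 0L)
  expect_error(estimate_stage_probs(counts), "egg",
    class = "cohortdem_estimation_error"
  )
})

test_that("tabulation rejects empty or too-short censuses", {
  expect_error(
    tabulate_transitions(
      tibble::tibble(
        cohort_id = character(), individual_id = character(),
        day = integer(), stage = character(), status = character()
      ),
      schema6
    ),
    "no records"
  )
  short <- tibble::tibble(
    cohort_id = "c1", individual_id = "i1", day = c(0L, 3L),
    stage = "egg", status = "alive"
  )
  expect_error(tabulate_transitions(short, schema6), "shorter")
})

test_that("stage probabilities are pooled binomial fractions", {
  probs <- estimate_stage_probs(tabulate_transitions(hand_census(), schema6))
  expect_equal(probs$P[probs$stage == "egg"], 0.4)
  expect_equal(probs$G[probs$stage == "egg"], 0.4)

  mk <- function(stay, adv, die) {
    tibble::tibble(
      stage = c("a", "b"), n_start = c(stay + adv + die, 0L),
      n_stay = c(stay, 0L), n_advance = c(adv, 0L), n_die = c(die, 0L)
    )
  }
  total_mortality <- estimate_stage_probs(mk(0L, 0L, 5L))
  expect_equal(total_mortality$P[1], 0)
  expect_equal(total_mortality$G[1], 0)
  stasis_only <- estimate_stage_probs(mk(7L, 0L, 0L))
  expect_equal(stasis_only$P[1], 1)
  expect_equal(stasis_only$G[1], 0)
})

test_that("fertility is interval-scaled eggs per female-day, non-ovipositers included", {
  expect_equal(estimate_fertility(hand_oviposition(), schema6), 6 * 30 / 120)
  # linearity: doubling every egg count doubles fertility exactly
  doubled <- dplyr::mutate(hand_oviposition(), eggs = eggs * 2L)
  expect_equal(
    estimate_fertility(doubled, schema6),
    2 * estimate_fertility(hand_oviposition(), schema6)
  )
  # sex-ratio scaling is exactly linear
  expect_equal(
    estimate_fertility(hand_oviposition(), schema6, sex_ratio_scale = 0.5),
    0.5 * estimate_fertility(hand_oviposition(), schema6)
  )
  # no eggs at all
  none <- dplyr::mutate(hand_oviposition(), eggs = 0L)
  expect_equal(estimate_fertility(none, schema6), 0)
})

test_that("matrix assembly places P, G and fertility and applies the adult override", {
  m <- projection_matrix(
    P = c(0, 0, 0, 0, 0, 0.99), G = rep(1, 5), fertility = 10,
    schema = schema6
  )
  expect_equal(diag(m$A), c(rep(0, 5), 0.99), ignore_attr = TRUE)
  expect_equal(m$A[cbind(2:6, 1:5)], rep(1, 5))
  expect_equal(m$A[1, 6], 10)
  expect_equal(sum(m$A != 0), 7)

  # the override replaces an estimated adult stasis of 1.0
  over <- projection_matrix(
    P = c(rep(0.2, 5), 1.0), G = rep(0.5, 5), fertility = 2,
    schema = schema6, adult_survival_override = 0.99
  )
  expect_equal(over$A[6, 6], 0.99)

  two <- projection_matrix(
    P = c(0.1, 0.9), G = 0.5, fertility = 3, schema = schema2
  )
  expect_equal(unname(two$A), rbind(c(0.1, 3), c(0.5, 0.9)))

  expect_error(
    projection_matrix(
      P = c(0.6, rep(0.1, 5)), G = c(0.5, rep(0.1, 4)),
      fertility = 1, schema = schema6
    ),
    "exceeds 1",
    class = "cohortdem_validation_error"
  )
})

test_that("estimated matrices always satisfy the survival constraint", {
  for (sd in 1:5) {
    sim <- simulate_cohorts(control_config(seed = sd))
    A <- estimate_projection_matrix(
      sim$census, sim$oviposition, schema6,
      adult_survival_override = NULL
    )
    expect_true(all(A$P[1:5] + A$G <= 1 + 1e-12))
    expect_true(all(A$A >= 0))
  }
})
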