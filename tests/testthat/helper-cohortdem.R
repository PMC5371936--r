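# shared fixtures: tiny schemas, hand-built censuses, random valid matrices

schema6 <- cbb_schema()

schema2 <- stage_schema(c("juvenile", "adult"), interval_days = 6)

# the 2-stage matrix with known closed forms:
# lambda = (0.8 + sqrt(0.64 + 4 * 10 * 0.5)) / 2, R0 = 10 * 0.5 / (1 - 0.8)
closed_form_matrix <- function() {
  projection_matrix(P = c(0, 0.8), G = 0.5, fertility = 10, schema = schema2)
}
closed_form_lambda <- (0.8 + sqrt(0.64 + 20)) / 2
closed_form_R0 <- 25

# random valid 6-stage Lefkovitch matrix; G > 0 and F > 0 keep it irreducible
random_lefkovitch <- function(fertility_range = c(0.5, 20)) {
  P <- runif(6, 0.05, 0.6)
  G <- runif(5, 0.05, 1) * (1 - P[1:5])
  f <- runif(1, fertility_range[1], fertility_range[2])
  projection_matrix(P = P, G = G, fertility = f, schema = schema6)
}

# census of 10 eggs at day 0; by day 6: 4 still eggs, 4 larvae, 2 dead (day 3)
hand_census <- function() {
  dplyr::bind_rows(
    tibble::tibble(
      cohort_id = "c1", individual_id = paste0("i", 1:10),
      day = 0L, stage = "egg", status = "alive"
    ),
    tibble::tibble(
      cohort_id = "c1", individual_id = paste0("i", 1:4),
      day = 6L, stage = "egg", status = "alive"
    ),
    tibble::tibble(
      cohort_id = "c1", individual_id = paste0("i", 5:8),
      day = 6L, stage = "larva", status = "alive"
    ),
    tibble::tibble(
      cohort_id = "c1", individual_id = paste0("i", 9:10),
      day = 3L, stage = "egg", status = "dead"
    )
  )
}

# two females observed for 60 days each (days 0 and 59 anchor the window),
# 30 eggs in total
hand_oviposition <- function() {
  tibble::tibble(
    female_id = rep(c("f1", "f2"), each = 3),
    treatment = "control",
    day = rep(c(0L, 30L, 59L), 2),
    eggs = c(10L, 5L, 0L, 0L, 15L, 0L)
  )
}
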