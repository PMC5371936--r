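#' Configure the individual-based cohort simulator
#'
#' Defines the ground-truth daily process the simulator draws from: each
#' individual draws one duration per immature stage (gamma with the given
#' mean and coefficient of variation, so durations are tightly distributed
#' rather than memoryless), is exposed to a constant daily mortality hazard
#' while in each stage, and — in the separate oviposition experiment —
#' adult females oviposit with probability `p_oviposit` and, if they do,
#' lay a Poisson-distributed number of eggs each day.
#'
#' Defaults reproduce the experimental design of laboratory coffee berry
#' borer cohort studies: 5 cohorts of 20 eggs censused daily for 50 days,
#' and 50 adult females followed daily for 60 days.
#'
#' @param schema A [stage_schema()]; the last stage is reproductive and has
#'   no duration (absorbing until death or the end of follow-up).
#' @param stage_duration_mean Mean duration in days of each non-terminal
#'   stage (length `s - 1`).
#' @param duration_cv Coefficient of variation of stage durations
#'   (0 = deterministic durations).
#' @param daily_survival Daily survival probability per stage (length `s`).
#' @param fecundity_per_day Mean eggs per ovipositing female per day.
#' @param p_oviposit Probability that a female oviposits at all
#'   (zero-inflation of the fecundity schedule).
#' @param sex_ratio Female:male ratio among offspring (females per male).
#' @param n_cohorts,cohort_size Number of cohorts and eggs per cohort.
#' @param horizon_days Days of daily census follow-up after day 0.
#' @param n_females,oviposition_days Size and length of the oviposition
#'   experiment.
#' @param label Treatment label written into the oviposition table.
#' @param seed Integer seed; the same seed reproduces the output exactly.
#'   Each individual derives a private random stream from it, so enlarging
#'   a cohort never reshuffles existing trajectories.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(schema = cbb_schema(),
                              stage_duration_mean = c(
                                egg = 6.08, larva = 15.22, prepupa = 1.94,
                                pupa = 6.37, juvenile = 4.05
                              ),
                              duration_cv = 0.2,
                              daily_survival = c(
                                egg = 0.99, larva = 0.99, prepupa = 0.99,
                                pupa = 0.99, juvenile = 0.99, adult = 0.998
                              ),
                              fecundity_per_day = 18.83 / 60,
                              p_oviposit = 0.68,
                              sex_ratio = 24.1,
                              n_cohorts = 5,
                              cohort_size = 20,
                              horizon_days = 50,
                              n_females = 50,
                              oviposition_days = 60,
                              label = "treatment",
                              seed = 1L) {
  stopifnot(inherits(schema, "stage_schema"))
  s <- n_stages(schema)
  stage_duration_mean <- unname(as.double(stage_duration_mean))
  daily_survival <- unname(as.double(daily_survival))
  if (length(stage_duration_mean) != s - 1 || any(stage_duration_mean <= 0)) {
    abort(sprintf("`stage_duration_mean` needs %d positive values.", s - 1))
  }
  if (length(daily_survival) != s ||
    any(daily_survival <= 0) || any(daily_survival > 1)) {
    abort(sprintf("`daily_survival` needs %d probabilities in (0, 1].", s))
  }
  if (duration_cv < 0) abort("`duration_cv` must be non-negative.")
  if (fecundity_per_day < 0) abort("`fecundity_per_day` must be non-negative.")
  if (p_oviposit < 0 || p_oviposit > 1) abort("`p_oviposit` must be a probability.")
  if (sex_ratio <= 0) abort("`sex_ratio` must be positive.")
  if (horizon_days < 1) abort("`horizon_days` must be at least 1.")
  structure(
    list(
      schema = schema,
      stage_duration_mean = stage_duration_mean,
      duration_cv = duration_cv,
      daily_survival = daily_survival,
      fecundity_per_day = fecundity_per_day,
      p_oviposit = p_oviposit,
      sex_ratio = sex_ratio,
      n_cohorts = as.integer(n_cohorts),
      cohort_size = as.integer(cohort_size),
      horizon_days = as.integer(horizon_days),
      n_females = as.integer(n_females),
      oviposition_days = as.integer(oviposition_days),
      label = label,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config> '", x$label, "': ",
    x$n_cohorts, " cohorts x ", x$cohort_size, " eggs, ",
    x$horizon_days, "-day census; ",
    x$n_females, " females x ", x$oviposition_days, " days oviposition\n",
    "  fecundity ", signif(x$fecundity_per_day, 3), " eggs/day, P(oviposit) ",
    x$p_oviposit, ", sex ratio ", x$sex_ratio, ":1, seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

#' Preset simulator configurations
#'
#' Treatment-level presets matching the three laboratory diets: stage
#' durations from the observed developmental times per diet, fecundity and
#' oviposition probability from the 60-day oviposition experiment
#' (control 18.83 eggs/female over 60 days with 68% of females ovipositing;
#' tetracycline 3.45 eggs over 60 days, 38% ovipositing; penicillin 19.58
#' eggs, 66%), and offspring sex ratios of 24.1, 19.4 and 26.5 females per
#' male respectively.
#'
#' @param ... Overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
control_config <- function(...) {
  args <- list(
    stage_duration_mean = c(
      egg = 6.08, larva = 15.22, prepupa = 1.94,
      pupa = 6.37, juvenile = 4.05
    ),
    fecundity_per_day = 18.83 / 60,
    p_oviposit = 0.68,
    sex_ratio = 24.1,
    label = "control"
  )
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

#' @rdname control_config
#' @export
tetracycline_config <- function(...) {
  args <- list(
    stage_duration_mean = c(
      egg = 6.10, larva = 15.52, prepupa = 2.03,
      pupa = 6.82, juvenile = 4.67
    ),
    fecundity_per_day = 3.45 / 60,
    p_oviposit = 0.38,
    sex_ratio = 19.4,
    label = "tetracycline"
  )
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

#' @rdname control_config
#' @export
penicillin_config <- function(...) {
  args <- list(
    stage_duration_mean = c(
      egg = 6.07, larva = 15.45, prepupa = 1.87,
      pupa = 6.78, juvenile = 4.09
    ),
    fecundity_per_day = 19.58 / 60,
    p_oviposit = 0.66,
    sex_ratio = 26.5,
    label = "penicillin"
  )
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

# Lehmer-style derivation of a private seed per random stream, keeping
# everything below 2^31 - 1 and within exact double arithmetic
derive_seed <- function(seed, stream) {
  m <- 2147483647
  a <- 48271
  h <- (a * ((seed %% m) + 1) + stream) %% m
  h <- (a * h + 11) %% m
  as.integer(h)
}

# one individual's life history under the config; returns entry times of
# stages 2..s (cumulative durations) and the observed death day (Inf if it
# outlives the horizon). Continuous time: stage at census day d is the
# stage entered at or before d; daily survival p equals a hazard of -log(p).
draw_individual <- function(cfg) {
  s <- n_stages(cfg$schema)
  mu <- cfg$stage_duration_mean
  cv <- cfg$duration_cv
  if (cv == 0) {
    dur <- mu
  } else {
    shape <- 1 / cv^2
    dur <- rgamma(s - 1, shape = shape, rate = shape / mu)
  }
  entry <- c(0, cumsum(dur)) # entry age of stage 1..s
  haz <- -log(cfg$daily_survival)
  death_age <- Inf
  for (st in seq_len(s)) {
    stay <- if (st < s) entry[st + 1] - entry[st] else Inf
    if (haz[st] == 0) next
    life <- rexp(1, rate = haz[st])
    if (life < stay) {
      death_age <- entry[st] + life
      break
    }
  }
  female <- runif(1) < cfg$sex_ratio / (1 + cfg$sex_ratio)
  list(entry = entry, death_age = death_age, female = female)
}

#' Simulate cohort census and oviposition tables
#'
#' Runs the individual-based process of the configuration and emits (i) a
#' daily cohort census (days 0..`horizon_days`; a death is recorded as a
#' single `dead` row on the first census day after it occurs, with no
#' further records), (ii) an oviposition table with one row per female per
#' day, and (iii) the ground truth realised in this run. Output is fully
#' determined by the seed. Sex is recorded in the census for juvenile and
#' adult records only (the stages that can be sexed visually).
#'
#' @param cfg A [simulation_config()].
#' @param seed Optional override of `cfg$seed`.
#' @return A list with elements `census` (validated census tibble,
#'   integer ids), `oviposition` (validated oviposition tibble) and
#'   `truth` (list: the config plus realised mean durations and death
#'   counts per stage and the realised egg rate).
#' @examples
#' sim <- simulate_cohorts(control_config(seed = 42))
#' dplyr::count(sim$census, stage)
#' @export
simulate_cohorts <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  schema <- cfg$schema
  s <- n_stages(schema)
  n_total <- cfg$n_cohorts * cfg$cohort_size
  horizon <- cfg$horizon_days

  entry_mat <- matrix(0, n_total, s)
  death_age <- numeric(n_total)
  female <- logical(n_total)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()),
    add = TRUE
  )
  for (i in seq_len(n_total)) {
    set.seed(derive_seed(seed, i))
    ind <- draw_individual(cfg)
    entry_mat[i, ] <- ind$entry
    death_age[i] <- ind$death_age
    female[i] <- ind$female
  }

  # stage occupied when death occurred (recorded on the dead row)
  death_stage <- rep(NA_integer_, n_total)
  died <- is.finite(death_age)
  if (any(died)) {
    entry_next <- cbind(entry_mat[, -1, drop = FALSE], Inf)
    for (st in seq_len(s)) {
      in_stage <- died & death_age >= entry_mat[, st] &
        death_age < entry_next[, st]
      death_stage[in_stage] <- st
    }
  }

  death_day <- ifelse(died, floor(death_age) + 1, Inf)
  last_day <- pmin(death_day, horizon)
  n_days <- as.integer(last_day) + 1L

  row_id <- rep(seq_len(n_total), n_days)
  day <- sequence(n_days) - 1L
  stage_idx <- rep(1L, length(day))
  for (st in 2:s) {
    stage_idx <- stage_idx + (day >= rep(entry_mat[, st], n_days))
  }
  dd <- rep(death_day, n_days)
  is_dead_row <- is.finite(dd) & day == dd
  status <- ifelse(is_dead_row, "dead", "alive")
  stage_idx[is_dead_row] <- rep(death_stage, n_days)[is_dead_row]
  sex <- ifelse(
    stage_idx >= s - 1,
    ifelse(rep(female, n_days), "female", "male"),
    NA_character_
  )
  census <- tibble(
    cohort_id = (row_id - 1L) %/% cfg$cohort_size + 1L,
    individual_id = row_id,
    day = as.integer(day),
    stage = schema$stages[stage_idx],
    status = status,
    sex = sex
  )

  # oviposition experiment: independent females followed daily
  days <- seq_len(cfg$oviposition_days) - 1L
  ovi_list <- vector("list", cfg$n_females)
  for (f in seq_len(cfg$n_females)) {
    set.seed(derive_seed(seed, 1000000L + f))
    ovipositor <- runif(1) < cfg$p_oviposit
    eggs <- if (ovipositor && cfg$fecundity_per_day > 0) {
      rpois(length(days), cfg$fecundity_per_day)
    } else {
      integer(length(days))
    }
    ovi_list[[f]] <- tibble(
      female_id = f, treatment = cfg$label,
      day = days, eggs = as.integer(eggs)
    )
  }
  oviposition <- dplyr::bind_rows(ovi_list)

  truth <- list(
    config = cfg,
    realised_mean_duration = colMeans(
      entry_mat[, -1, drop = FALSE] - entry_mat[, -s, drop = FALSE]
    ),
    deaths_by_stage = setNames(
      tabulate(death_stage[died & death_day <= horizon], nbins = s),
      schema$stages
    ),
    realised_eggs_per_female = sum(oviposition$eggs) / cfg$n_females,
    prop_ovipositing = mean(
      tapply(oviposition$eggs, oviposition$female_id, sum) > 0
    )
  )
  list(
    census = validate_census(census, schema),
    oviposition = validate_oviposition(oviposition),
    truth = truth
  )
}

#' Large-sample ground-truth projection matrix for a configuration
#'
#' The operational ground truth for parameter-recovery experiments: the
#' projection matrix estimated from one very large simulated cohort (and a
#' correspondingly enlarged oviposition experiment) under the same
#' configuration. Small-cohort estimates should converge to this matrix as
#' cohort size grows.
#'
#' @param cfg A [simulation_config()].
#' @param n_large Individuals in the ground-truth cohort (>= 10^4).
#' @param n_females Females in the enlarged oviposition experiment.
#' @param seed Seed for the ground-truth run (defaults to `cfg$seed`).
#' @param adult_survival_override Passed to
#'   [estimate_projection_matrix()].
#' @return A [projection_matrix()].
#' @export
expected_matrix <- function(cfg, n_large = 100000L, n_females = 2000L,
                            seed = cfg$seed, adult_survival_override = 0.99) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (n_large < 10000) {
    abort("`n_large` must be at least 10^4 for a stable ground truth.")
  }
  big <- simulation_config(
    schema = cfg$schema,
    stage_duration_mean = cfg$stage_duration_mean,
    duration_cv = cfg$duration_cv,
    daily_survival = cfg$daily_survival,
    fecundity_per_day = cfg$fecundity_per_day,
    p_oviposit = cfg$p_oviposit,
    sex_ratio = cfg$sex_ratio,
    n_cohorts = 1L,
    cohort_size = as.integer(n_large),
    horizon_days = cfg$horizon_days,
    n_females = as.integer(n_females),
    oviposition_days = cfg$oviposition_days,
    label = cfg$label,
    seed = as.integer(seed)
  )
  sim <- simulate_cohorts(big)
  estimate_projection_matrix(
    sim$census, sim$oviposition, cfg$schema,
    adult_survival_override = adult_survival_override
  )
}
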