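test_that("chi-square of ovipositing females matches the published worked example", {
  # 38%, 68%, 66% of n = 50 females ovipositing per diet
  tab <- rbind(
    tetracycline = c(19, 31),
    control = c(34, 16),
    penicillin = c(33, 17)
  )
  res <- chi_square_independence(tab)
  expect_equal(round(res$statistic, 2), 11.50)
  expect_equal(res$df, 2)
  expect_lt(res$p_value, 0.01)
})

test_that("chi-square basics: proportional tables, 2x2 hand formula, errors", {
  prop <- rbind(c(10, 20), c(30, 60))
  expect_equal(chi_square_independence(prop)$statistic, 0)

  hand <- rbind(c(10, 20), c(20, 10))
  res <- chi_square_independence(hand)
  expect_equal(res$statistic, 20 / 3)
  expect_equal(res$df, 1)

  expect_error(chi_square_independence(rbind(c(0, 0), c(3, 4))), "margin")
  expect_error(chi_square_independence(matrix(5, 1, 2)), "at least 2")
})

test_that("chi-square is permutation invariant and scales linearly in counts", {
  set.seed(30)
  m <- matrix(rpois(12, 20) + 1, 3, 4)
  base <- chi_square_independence(m)$statistic
  expect_equal(
    chi_square_independence(m[sample(3), sample(4)])$statistic, base
  )
  expect_equal(chi_square_independence(m * 3L)$statistic, base * 3)
})

test_that("sex ratios average per-replicate ratios, excluding zero-male vials", {
  out <- sex_ratio_summary(tibble::tibble(females = c(20, 24), males = c(2, 3)))
  expect_equal(out$mean_ratio, 9) # (10 + 8) / 2
  out <- sex_ratio_summary(tibble::tibble(females = rep(12, 5), males = rep(2, 5)))
  expect_equal(out$se, 0)
  expect_warning(
    out <- sex_ratio_summary(
      tibble::tibble(females = c(10, 8), males = c(2, 0))
    ),
    "zero males"
  )
  expect_equal(out$n_used, 1)
  expect_equal(out$n_excluded, 1)
})

test_that("mean of ratios exceeds the pooled ratio on heterogeneous replicates", {
  set.seed(31)
  counts <- tibble::tibble(
    females = rpois(50, 22) + 1, males = rpois(50, 2) + 1
  )
  mean_of_ratios <- sex_ratio_summary(counts)$mean_ratio
  ratio_of_means <- sum(counts$females) / sum(counts$males)
  expect_gt(mean_of_ratios, ratio_of_means) # Jensen direction
})

test_that("developmental times recover deterministic simulator durations exactly", {
  cfg <- control_config(
    seed = 5, duration_cv = 0,
    stage_duration_mean = c(egg = 6, larva = 15, prepupa = 2, pupa = 6, juvenile = 4),
    daily_survival = rep(1, 6), n_cohorts = 2, cohort_size = 10
  )
  sim <- simulate_cohorts(cfg)
  out <- developmental_time_summary(sim$census, schema6)
  expect_equal(
    out$mean_days[match(
      c("egg", "larva", "prepupa", "pupa", "juvenile"), out$stage
    )],
    c(6, 15, 2, 6, 4)
  )
  expect_equal(out$mean_days[out$stage == "egg_to_adult"], 33)
  expect_equal(out$se[match("egg", out$stage)], 0)
})

test_that("hand-built census durations count census days in stage", {
  census <- tibble::tibble(
    cohort_id = "c1", individual_id = "i1", day = 0:7,
    stage = c(rep("egg", 6), rep("larva", 2)), status = "alive"
  )
  out <- developmental_time_summary(census, schema6)
  expect_equal(out$mean_days[out$stage == "egg"], 6)
  expect_true(is.na(out$se[out$stage == "egg"])) # single individual
  expect_true(is.na(out$mean_days[out$stage == "larva"])) # not completed
})

test_that("one-way ANOVA matches the textbook decomposition", {
  res <- one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(res$statistic, 13.5)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)

  same <- one_way_anova(list(a = c(1, 2), b = c(1, 2), c = c(1, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # random 3-group data against the sum-of-squares formula written out
  set.seed(32)
  g <- list(rnorm(6), rnorm(8, 1), rnorm(5, 2))
  res <- one_way_anova(g)
  x <- unlist(g)
  grand <- mean(x)
  ssb <- sum(lengths(g) * (vapply(g, mean, 0) - grand)^2)
  ssw <- sum(unlist(lapply(g, function(v) (v - mean(v))^2)))
  f_hand <- (ssb / 2) / (ssw / (length(x) - 3))
  expect_equal(res$statistic, f_hand)
  expect_equal(res$p_value, pf(f_hand, 2, length(x) - 3, lower.tail = FALSE))
})

test_that("ANOVA F is invariant to shifts and scalings of the data", {
  set.seed(33)
  g <- list(rnorm(5), rnorm(5, 0.5), rnorm(5, 1))
  f0 <- one_way_anova(g)$statistic
  expect_equal(one_way_anova(lapply(g, function(v) v + 100))$statistic, f0)
  expect_equal(one_way_anova(lapply(g, function(v) v * 7))$statistic, f0)
})

test_that("degenerate ANOVA with zero within-group variance reports p = 0", {
  expect_warning(
    res <- one_way_anova(list(a = c(1, 1), b = c(2, 2))),
    "infinite"
  )
  expect_equal(res$p_value, 0)
})

test_that("pairwise Welch comparisons return Holm-adjusted pairs", {
  set.seed(34)
  g <- list(a = rnorm(6), b = rnorm(6, 3), c = rnorm(6, 3))
  out <- pairwise_welch(g)
  expect_equal(nrow(out), 3)
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
  expect_lt(out$p_value[out$group1 == "b" & out$group2 == "a"], 0.05)
})

test_that("oviposition group summaries expose rates and the contingency table", {
  sim_c <- simulate_cohorts(control_config(seed = 41))
  sim_t <- simulate_cohorts(tetracycline_config(seed = 42))
  ovi <- dplyr::bind_rows(sim_c$oviposition, sim_t$oviposition)
  out <- oviposition_group_summary(ovi)
  expect_equal(nrow(out$rates), 2)
  expect_equal(dim(out$contingency), c(2, 2))
  expect_equal(unname(rowSums(out$contingency)), c(50, 50))
  ctrl <- out$rates[out$rates$treatment == "control", ]
  expect_true(ctrl$rate_ci_low < ctrl$eggs_per_female_day &&
    ctrl$eggs_per_female_day < ctrl$rate_ci_high)
  tet <- out$rates[out$rates$treatment == "tetracycline", ]
  expect_gt(ctrl$eggs_per_female, tet$eggs_per_female)
})
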