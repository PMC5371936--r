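test_that("projection iterates N[t+1] = A N[t] and keeps fixed points fixed", {
  A_id <- diag(3)
  traj <- project(A_id, c(2, 1, 5), steps = 4)
  expect_equal(
    dplyr::filter(traj, step == 4)$abundance,
    dplyr::filter(traj, step == 0)$abundance
  )

  flip <- matrix(c(0, 0.5, 2, 0), 2, 2) # [[0,2],[0.5,0]] by column
  traj <- project(flip, c(1, 0), steps = 2)
  expect_equal(dplyr::filter(traj, step == 1)$abundance, c(0, 0.5))
  expect_equal(dplyr::filter(traj, step == 2)$abundance, c(1, 0))

  expect_error(project(flip, c(-1, 0), steps = 1), "non-negative")
})

test_that("projected growth converges to the dominant eigenvalue", {
  set.seed(42)
  A <- random_lefkovitch()
  lam <- growth_rate(A)
  traj <- project(A, rep(1, 6), steps = 300)
  n_last <- dplyr::filter(traj, step == 300)$abundance
  n_prev <- dplyr::filter(traj, step == 299)$abundance
  expect_equal(sum(n_last) / sum(n_prev), lam, tolerance = 1e-6)
})

test_that("growth rate matches closed forms", {
  one <- stage_schema("adult", interval_days = 6)
  expect_equal(growth_rate(projection_matrix(0.5, double(), 0, one)), 0.5)

  flip <- matrix(c(0, 0.5, 2, 0), 2, 2)
  expect_equal(growth_rate(flip), 1) # sqrt(F * G)

  expect_equal(
    growth_rate(closed_form_matrix()), closed_form_lambda,
    tolerance = 1e-12
  )
})

test_that("power iteration agrees with the direct eigensolution", {
  set.seed(7)
  for (rep in 1:25) {
    A <- random_lefkovitch()
    expect_equal(
      growth_rate(A, method = "power"), growth_rate(A),
      tolerance = 1e-8
    )
  }
})

test_that("stable distribution and reproductive values have the standard normalisations", {
  flip <- matrix(c(0, 0.5, 2, 0), 2, 2)
  expect_equal(stable_distribution(flip), c(2 / 3, 1 / 3))

  set.seed(8)
  A <- random_lefkovitch()
  w <- stable_distribution(A)
  v <- reproductive_value(A)
  expect_equal(sum(w), 1)
  expect_equal(sum(v * w), 1)
  expect_true(all(w >= 0))
  # eigenvector property: A w = lambda w
  expect_equal(drop(A$A %*% w), growth_rate(A) * w, ignore_attr = TRUE)

  # reducible chain warns
  red <- projection_matrix(
    P = rep(0.2, 6), G = c(0.5, 0, 0.5, 0.5, 0.5), fertility = 5,
    schema = schema6
  )
  expect_warning(stable_distribution(red), "reducible")
})

test_that("sensitivities match finite differences and elasticities sum to one", {
  one <- stage_schema("adult", interval_days = 6)
  m1 <- projection_matrix(0.5, double(), 0, one)
  expect_equal(unname(sensitivity(m1)), matrix(1), tolerance = 1e-12)
  expect_equal(unname(elasticity(m1)), matrix(1), tolerance = 1e-12)

  set.seed(9)
  for (rep in 1:5) {
    A <- random_lefkovitch()
    S <- sensitivity(A)
    h <- 1e-6
    for (i in 1:6) {
      for (j in 1:6) {
        lam_oracle <- function(M) {
          ev <- eigen(M, only.values = TRUE)$values
          Re(ev[which.max(Re(ev))])
        }
        Ap <- Am <- A$A
        Ap[i, j] <- Ap[i, j] + h
        Am[i, j] <- Am[i, j] - h
        fd <- (lam_oracle(Ap) - lam_oracle(Am)) / (2 * h)
        expect_equal(S[i, j], fd, tolerance = 1e-4, ignore_attr = TRUE)
      }
    }
    expect_equal(sum(elasticity(A)), 1, tolerance = 1e-9)
    expect_true(all(elasticity(A) >= 0))
  }
})

test_that("net reproductive rate matches the fundamental-matrix closed form", {
  expect_equal(
    net_reproductive_rate(closed_form_matrix()), closed_form_R0,
    tolerance = 1e-12
  )
  sterile <- projection_matrix(
    P = c(0, 0.8), G = 0.5, fertility = 0, schema = schema2
  )
  expect_equal(net_reproductive_rate(sterile), 0)
  immortal <- projection_matrix(
    P = c(0, 1), G = 0.5, fertility = 10, schema = schema2
  )
  expect_error(net_reproductive_rate(immortal), "adult_survival_override",
    class = "cohortdem_estimation_error"
  )
})

test_that("R0 and lambda sit on the same side of 1", {
  set.seed(10)
  for (rep in 1:50) {
    A <- random_lefkovitch(fertility_range = c(0.01, 30))
    expect_equal(
      sign(net_reproductive_rate(A) - 1),
      sign(growth_rate(A) - 1)
    )
  }
})

test_that("generation time is the exact log ratio", {
  expect_equal(generation_time(2.5, 2.5), 1)
  expect_equal(generation_time(1.5, 1), 0)
  expect_equal(
    generation_time(closed_form_lambda, closed_form_R0),
    log(25) / log(closed_form_lambda)
  )
  expect_error(generation_time(1, 5), "undefined")
  expect_error(generation_time(0.5, -1), "positive")
})

test_that("demography bundles consistent parameters with interval-aware units", {
  d <- demography(closed_form_matrix())
  expect_equal(d$lambda, closed_form_lambda, tolerance = 1e-12)
  expect_equal(d$R0, 25, tolerance = 1e-12)
  expect_equal(d$T_days, d$T_intervals * 6)
  g <- glance(d)
  expect_equal(names(g), c("lambda", "R0", "T_intervals", "T_days"))
  td <- tidy(d)
  expect_equal(td$stage, c("juvenile", "adult"))
  expect_equal(sum(td$stable_stage), 1)
})

test_that("replicate summaries report means and standard errors over cohorts", {
  reps <- tibble::tibble(lambda = c(1.0, 1.2))
  out <- replicate_summary(reps)
  expect_equal(out$mean, 1.1)
  expect_equal(out$se, 0.1)

  same <- tibble::tibble(lambda = rep(1.3, 4), R0 = rep(20, 4))
  out <- replicate_summary(same)
  expect_equal(out$se, c(0, 0))

  # n = 5 against the direct sd/sqrt(n) formula
  set.seed(11)
  x <- rnorm(5, 1.1, 0.05)
  out <- replicate_summary(tibble::tibble(lambda = x))
  expect_equal(out$mean, mean(x))
  expect_equal(out$se, sd(x) / sqrt(5))

  expect_message(
    out <- replicate_summary(tibble::tibble(lambda = 1.1)),
    "undefined"
  )
  expect_equal(out$mean, 1.1)
  expect_true(is.na(out$se))
})
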