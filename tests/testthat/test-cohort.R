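test_that("identical seeds give bitwise-identical cohorts", {
  a <- simulate_cohort(cohort_spec(n_subjects = 12, rng_seed = 77))
  b <- simulate_cohort(cohort_spec(n_subjects = 12, rng_seed = 77))
  expect_identical(a, b)
  c <- simulate_cohort(cohort_spec(n_subjects = 12, rng_seed = 78))
  expect_false(identical(a$weights, c$weights))
})

test_that("generated connectomes are symmetric, non-negative, zero-diagonal", {
  co <- simulate_cohort(cohort_spec(n_subjects = 8, rng_seed = 2))
  for (s in 1:8) {
    w <- co$weights[, , s]
    expect_equal(w, t(w))
    expect_true(all(w >= 0))
    expect_true(all(diag(w) == 0))
  }
  dens <- mean(co$weights[, , 1][upper.tri(co$weights[, , 1])] > 0)
  expect_equal(dens, 0.25, tolerance = 0.01)
})

test_that("apathy scores are integers in [0,6] with the requested moments", {
  co <- simulate_cohort(cohort_spec(n_subjects = 5000, rng_seed = 4))
  a <- co$table$apathy
  expect_true(all(a == floor(a)))
  expect_true(all(a >= 0 & a <= 6))
  # moment-matched discretization: within 3 standard errors at this n
  se_mean <- 1.7 / sqrt(5000)
  se_sd <- 1.7 / sqrt(2 * 5000)
  expect_lt(abs(mean(a) - 2.9), 3 * se_mean)
  expect_lt(abs(sd(a) - 1.7), 3 * se_sd)
})

test_that("covariates follow the configured marginals and confound knob", {
  co <- simulate_cohort(cohort_spec(n_subjects = 8000, rng_seed = 6))
  tab <- co$table
  expect_equal(mean(tab$age), 70, tolerance = 0.5)
  expect_equal(sd(tab$age), 9.6, tolerance = 0.5)
  expect_lt(abs(mean(tab$hypertension) - 0.886), 0.015)
  expect_lt(abs(mean(tab$hypercholesterolemia) - 0.912), 0.015)
  expect_lt(abs(mean(tab$diabetes) - 0.193), 0.02)
  expect_lt(abs(mean(tab$smoking) - 0.526), 0.02)
  # independence by default
  expect_lt(abs(cor(tab$age, tab$apathy)), 0.05)
  # optional coupling
  co2 <- simulate_cohort(cohort_spec(n_subjects = 8000, age_apathy_r = 0.4,
                                     rng_seed = 6))
  expect_equal(cor(co2$table$age, co2$table$apathy), 0.4, tolerance = 0.05)
})

test_that("planted effect scales target-sub-network edges down with apathy", {
  spec0 <- cohort_spec(n_subjects = 10, effect_beta = 0, rng_seed = 11)
  spec1 <- cohort_spec(n_subjects = 10, effect_beta = 0.05, rng_seed = 11)
  co0 <- simulate_cohort(spec0)
  co1 <- simulate_cohort(spec1)
  tgt <- spec1$target_subnetwork
  out <- setdiff(seq_len(90), tgt)
  for (s in 1:10) {
    scale_s <- max(0, 1 - 0.05 * co1$table$apathy[s])
    expect_equal(co1$weights[tgt, tgt, s],
                 co0$weights[tgt, tgt, s] * scale_s, tolerance = 1e-12)
    expect_equal(co1$weights[out, out, s], co0$weights[out, out, s])
  }
})

test_that("null generator induces no reward-efficiency dependence", {
  # |r| < 0.2 at n = 114 in at least 95% of seeds under effect_beta = 0
  reward <- builtin_subnetworks()$reward
  rs <- vapply(1:200, function(seed) {
    co <- simulate_cohort(cohort_spec(effect_beta = 0, rng_seed = seed + 5000))
    eff <- vapply(seq_len(114), function(s) {
      global_efficiency(co$weights[, , s], reward)
    }, numeric(1))
    cor(eff, co$table$apathy)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.03)
  expect_gte(mean(abs(rs) < 0.2), 0.95)
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(target_subnetwork = c(1, 91)), "1..90")
  expect_error(cohort_spec(effect_beta = -1))
  expect_error(cohort_spec(edge_density = 0))
  expect_error(cohort_spec(systems = list(1:5, 200)), "1..90")
})

test_that("cohort CSV save/load round trips", {
  co <- tiny_cohort(n_subjects = 4, seed = 13)
  dir <- tempfile("cohort_io_")
  save_cohort(co, dir)
  back <- load_cohort(dir)
  expect_equal(back$weights, co$weights, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$table$apathy, co$table$apathy)
  expect_equal(back$table$subject_id, co$table$subject_id)
})

test_that("loading computes apathy from GDS items when score is absent", {
  co <- tiny_cohort(n_subjects = 3, seed = 14)
  dir <- tempfile("cohort_items_")
  save_cohort(co, dir)
  tab <- utils::read.csv(file.path(dir, "cohort.csv"))
  tab$apathy <- NULL
  # craft items giving scores 0, 3, 6
  tab$gds_stay_home <- c("no", "yes", "yes")
  tab$gds_avoid_gatherings <- c("no", "yes", "yes")
  tab$gds_dropped_activities <- c("no", "yes", "yes")
  tab$gds_life_exciting <- c("yes", "yes", "no")
  tab$gds_hard_new_projects <- c("no", "no", "yes")
  tab$gds_full_of_energy <- c("yes", "yes", "no")
  utils::write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE)
  back <- load_cohort(dir)
  expect_equal(back$table$apathy, c(0L, 3L, 6L))
})
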