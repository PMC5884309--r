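all_items <- function(resp) {
  as.list(stats::setNames(rep(resp, 6),
                          c("stay_home", "avoid_gatherings",
                            "dropped_activities", "life_exciting",
                            "hard_new_projects", "full_of_energy")))
}

test_that("apathy score counts apathetic poles with reverse scoring", {
  none <- all_items("no")
  none$life_exciting <- "yes"; none$full_of_energy <- "yes"
  expect_equal(apathy_score(none), 0)

  all_ap <- all_items("yes")
  all_ap$life_exciting <- "no"; all_ap$full_of_energy <- "no"
  expect_equal(apathy_score(all_ap), 6)

  one <- none
  one$stay_home <- "yes"
  expect_equal(apathy_score(one), 1)
})

test_that("apathy score refuses incomplete or malformed items", {
  items <- all_items("no")
  items$stay_home <- NULL
  expect_error(apathy_score(items), "stay_home")
  bad <- all_items("no")
  bad$avoid_gatherings <- "maybe"
  expect_error(apathy_score(bad), "'yes' or 'no'")
})

test_that("pearson matches the definitional covariance oracle", {
  set.seed(20)
  x <- rnorm(20); y <- 0.4 * x + rnorm(20)
  res <- pearson(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$df, 18)
  # cross-check t and p against cor.test
  ct <- cor.test(x, y)
  expect_equal(res$t, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)

  expect_equal(pearson(x, x)$r, 1)
  expect_equal(pearson(x, -2 * x + 5)$r, -1)
  expect_error(pearson(x, rep(1, 20)), "zero variance")
  expect_error(pearson(1:3, 1:3), "at least 4")
})

test_that("partial correlation equals the single-control closed form", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 50
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + rnorm(n)
    r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
    closed <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
    res <- partial_correlation(x, y, z)
    expect_equal(res$r, closed, tolerance = 1e-12)
    expect_equal(res$df, n - 3)
  }
})

test_that("partial correlation with no controls is exactly pearson", {
  set.seed(22)
  x <- rnorm(30); y <- rnorm(30)
  a <- pearson(x, y)
  for (ctl in list(NULL, data.frame())) {
    b <- partial_correlation(x, y, ctl)
    expect_identical(b$r, a$r)
    expect_identical(b$p, a$p)
    expect_identical(b$df, a$df)
  }
})

test_that("independent controls leave the correlation asymptotically alone", {
  set.seed(23)
  n <- 1e4
  x <- rnorm(n); y <- 0.3 * x + rnorm(n)
  ctl <- data.frame(a = rnorm(n), b = rnorm(n))
  expect_lt(abs(partial_correlation(x, y, ctl)$r - pearson(x, y)$r), 0.02)
})

test_that("rank-deficient controls are refused with the column named", {
  set.seed(24)
  x <- rnorm(40); y <- rnorm(40)
  ctl <- data.frame(z = rnorm(40))
  ctl$z_dup <- ctl$z * 2
  expect_error(partial_correlation(x, y, ctl), "z_dup")
  expect_error(partial_correlation(x, y, data.frame(x_copy = x, x2 = x)),
               "collinear")
})

test_that("correlations are invariant under affine rescaling", {
  set.seed(25)
  x <- rnorm(60); y <- rnorm(60); z <- rnorm(60)
  base <- partial_correlation(x, y, z)
  resc <- partial_correlation(3 * x - 7, -0.5 * y + 2, 100 * z + 4)
  expect_equal(abs(resc$r), abs(base$r), tolerance = 1e-12)
  expect_equal(resc$p, base$p, tolerance = 1e-12)
  # sign flips with the odd number of negative scalings on y
  expect_equal(resc$r, -base$r, tolerance = 1e-12)
})

test_that("p-values are uniform under the null", {
  set.seed(26)
  n <- 30
  ps <- vapply(1:2000, function(i) pearson(rnorm(n), rnorm(n))$p, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  ps2 <- vapply(1:2000, function(i) {
    partial_correlation(rnorm(n), rnorm(n), rnorm(n))$p
  }, numeric(1))
  ks2 <- suppressWarnings(ks.test(ps2, "punif"))
  expect_gt(ks2$p.value, 0.01)
})

test_that("specificity table reproduces its defining computations", {
  co <- simulate_cohort(cohort_spec(n_subjects = 100, rng_seed = 30,
                                    effect_beta = 0.05))
  m <- network_metrics(co)
  covars <- co$table[, c("age", "hypertension", "hypercholesterolemia",
                         "diabetes", "smoking")]
  tab <- specificity_table(m, co$table$apathy, covariates = covars)
  # 3 networks x (1 marginal + 2 partial + 1 covariate) x 2 metrics
  expect_equal(nrow(tab), 24)
  row <- tab[tab$network == "reward" & tab$control == "motor" &
               tab$metric == "efficiency", ]
  direct <- partial_correlation(m$reward_eff, co$table$apathy,
                                data.frame(motor = m$motor_eff))
  expect_equal(row$r, direct$r)
  expect_equal(row$p, direct$p)
  expect_equal(row$df, direct$df)
  marg <- tab[tab$network == "visual" & tab$control == "none" &
                tab$metric == "sum_of_weights", ]
  expect_equal(marg$r, pearson(m$visual_sum, co$table$apathy)$r)
  cov_row <- tab[tab$network == "reward" & tab$control == "covariates" &
                   tab$metric == "efficiency", ]
  expect_equal(cov_row$df, 100L - 2L - 5L)
})

test_that("single sub-network gives marginal rows only", {
  co <- tiny_cohort(n_subjects = 12, seed = 31)
  m <- network_metrics(co, list(front = subnetwork("front",
                                                   aal90_labels()[1:4])))
  m <- m[, c("subject_id", "front_eff", "front_sum")]
  colnames(m) <- c("subject_id", "front_eff", "front_sum")
  tab <- specificity_table(m, co$table$apathy)
  expect_equal(unique(tab$control), "none")
  expect_equal(nrow(tab), 2)
})
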