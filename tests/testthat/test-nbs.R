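full_mask <- function(n) {
  m <- matrix(TRUE, n, n); diag(m) <- FALSE; m
}

# cohort whose edges are iid weights, independent of any score
iid_weight_array <- function(n, S, seed) {
  set.seed(seed)
  w <- array(0, c(n, n, S))
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  for (s in seq_len(S)) {
    vals <- exp(rnorm(nrow(ut), 0, 0.3))
    m <- matrix(0, n, n)
    m[ut] <- vals; m[ut[, c(2, 1)]] <- vals
    w[, , s] <- m
  }
  w
}

test_that("edge statistics implement the r-to-t transform", {
  # r = 0.5 at n = 27 gives t = 2.8868 by the closed form
  n <- 5; S <- 27
  set.seed(1)
  scores <- rnorm(S)
  y <- as.numeric(scale(scores))
  # construct an edge whose weights correlate exactly 0.5 with scores
  noise <- as.numeric(scale(residuals(lm(rnorm(S) ~ y))))
  x <- 0.5 * y + sqrt(0.75) * noise
  w <- iid_weight_array(n, S, seed = 2)
  w[1, 2, ] <- w[2, 1, ] <- 5 + x
  t_mat <- edge_statistics(w, full_mask(n), scores)
  expect_equal(t_mat[1, 2], 0.5 * sqrt(25) / sqrt(0.75), tolerance = 1e-10)
  expect_equal(round(t_mat[1, 2], 4), 2.8868)
  expect_true(all(!is.na(t_mat[upper.tri(t_mat)])))
})

test_that("perfect correlation is capped and zero variance handled", {
  n <- 4; S <- 12
  scores <- seq_len(S) + 0
  w <- iid_weight_array(n, S, seed = 3)
  w[1, 2, ] <- w[2, 1, ] <- scores        # r = +1
  w[3, 4, ] <- w[4, 3, ] <- 1             # zero variance
  t_mat <- edge_statistics(w, full_mask(n), scores)
  expect_equal(t_mat[1, 2], 1e9)
  expect_equal(t_mat[3, 4], 0)
  expect_error(edge_statistics(w, full_mask(n), rep(1, S)), "zero variance")
})

test_that("masked-out edges carry no statistic", {
  n <- 4; S <- 15
  w <- iid_weight_array(n, S, seed = 4)
  mask <- full_mask(n)
  mask[1, 2] <- mask[2, 1] <- FALSE
  t_mat <- edge_statistics(w, mask, rnorm(S))
  expect_true(is.na(t_mat[1, 2]))
  expect_false(anyNA(t_mat[mask]))
})

test_that("null supra-threshold fraction matches the t distribution", {
  # two-tailed P(|t| >= 2.5) at df = 112 is 0.01385; with 435 independent
  # edges x 40 independent score draws the Monte-Carlo fraction should land
  # close to it
  n <- 30; S <- 114
  w <- iid_weight_array(n, S, seed = 5)
  expected <- 2 * pt(-2.5, df = S - 2)
  expect_equal(expected, 0.0138, tolerance = 0.01)
  set.seed(6)
  fr <- vapply(1:40, function(i) {
    t_mat <- edge_statistics(w, full_mask(n), rnorm(S))
    tv <- t_mat[upper.tri(t_mat)]
    mean(abs(tv) >= 2.5)
  }, numeric(1))
  expect_equal(mean(fr), expected, tolerance = 0.35)
})

test_that("component extraction handles the canonical cases", {
  n <- 8
  t_mat <- matrix(0, n, n)
  expect_equal(extract_components(t_mat, 2.5, "negative"), list())

  set_t <- function(m, i, j, v) { m[i, j] <- v; m[j, i] <- v; m }
  # 3-edge path a-b-c-d
  t_mat <- set_t(t_mat, 1, 2, -3)
  t_mat <- set_t(t_mat, 2, 3, -3)
  t_mat <- set_t(t_mat, 3, 4, -2.5)
  comps <- extract_components(t_mat, 2.5, "negative")
  expect_length(comps, 1)
  expect_equal(comps[[1]]$extent, 3)
  expect_equal(comps[[1]]$nodes, 1:4)
  # threshold is inclusive (>=) per tail
  expect_length(extract_components(t_mat, 2.5, "positive"), 0)

  # two disjoint triangles
  t2 <- matrix(0, n, n)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(5, 6), c(6, 7), c(5, 7))) {
    t2 <- set_t(t2, e[1], e[2], 4)
  }
  comps2 <- extract_components(t2, 2.5, "positive")
  expect_length(comps2, 2)
  expect_equal(vapply(comps2, `[[`, integer(1), "extent"), c(3L, 3L))
})

test_that("component extraction agrees with a flood-fill oracle", {
  set.seed(17)
  for (rep in 1:300) {
    n <- sample(4:15, 1)
    t_mat <- matrix(0, n, n)
    ut <- which(upper.tri(t_mat), arr.ind = TRUE)
    tv <- rnorm(nrow(ut), 0, 2.2)
    t_mat[ut] <- tv
    t_mat[ut[, c(2, 1)]] <- tv
    for (tail in c("negative", "positive")) {
      comps <- extract_components(t_mat, 2.5, tail)
      supra <- if (tail == "negative") tv <= -2.5 else tv >= 2.5
      oracle <- flood_fill_components(ut[supra, , drop = FALSE], n)
      expect_equal(length(comps), length(oracle))
      got_nodes <- lapply(comps, `[[`, "nodes")
      # same node sets (order-free) and consistent extents
      expect_setequal(lapply(got_nodes, paste, collapse = ","),
                      lapply(oracle, paste, collapse = ","))
      expect_equal(sum(vapply(comps, `[[`, integer(1), "extent")),
                   sum(supra))
    }
  }
})

test_that("negative and positive tails mirror under score sign flip", {
  co <- tiny_cohort(n_subjects = 24, seed = 21)
  mask <- group_edge_mask(co, 1)
  scores <- co$table$apathy + rnorm(24, 0, 0.01)
  t_a <- edge_statistics(co, mask, scores)
  t_b <- edge_statistics(co, mask, -scores)
  expect_equal(t_a, -t_b, tolerance = 1e-12)
  neg_a <- extract_components(t_a, 2, "negative")
  pos_b <- extract_components(t_b, 2, "positive")
  expect_equal(lapply(neg_a, `[[`, "nodes"), lapply(pos_b, `[[`, "nodes"))
})

test_that("permutation p-values are floored, monotone and reproducible", {
  co <- tiny_cohort(n_subjects = 30, seed = 23, effect_beta = 0.15)
  mask <- group_edge_mask(co, 1)
  cfg <- nbs_config(t_threshold = 2.5, n_permutations = 200, rng_seed = 5)
  res <- nbs(co, mask, co$table$apathy, cfg)
  res2 <- nbs(co, mask, co$table$apathy, cfg)
  expect_equal(res, res2)
  for (tl in names(res$components)) {
    comps <- res$components[[tl]]
    if (length(comps) == 0) next
    ps <- vapply(comps, `[[`, numeric(1), "p_fwer")
    exts <- vapply(comps, `[[`, integer(1), "extent")
    expect_true(all(ps >= 1 / 201 & ps <= 1))
    # monotone: larger extent, not larger p
    expect_true(all(diff(ps[order(-exts)]) >= 0))
    # p matches its definition against the stored null
    nm <- res$null_max_extents[[tl]]
    for (cc in comps) {
      expect_equal(cc$p_fwer, (1 + sum(nm >= cc$extent)) / 201)
    }
  }
})

test_that("an unbeatable observed component yields the permutation floor", {
  # an 8-node clique of edges perfectly anti-correlated with the scores is
  # always supra-threshold (t capped); at t_threshold = 5 a shuffled score
  # vector essentially never reaches threshold anywhere, so the observed
  # extent (28) exceeds every permutation maximum
  n <- 16; S <- 200
  w <- iid_weight_array(n, S, seed = 7)
  set.seed(8)
  scores <- rnorm(S)
  for (i in 1:7) for (j in (i + 1):8) {
    w[i, j, ] <- w[j, i, ] <- 10 - scores
  }
  res <- nbs(w, full_mask(n), scores,
             nbs_config(t_threshold = 5, n_permutations = 150,
                        tail = "negative", rng_seed = 3))
  comps <- res$components$negative
  expect_gt(length(comps), 0)
  expect_equal(comps[[1]]$extent, 28L)
  expect_equal(comps[[1]]$p_fwer, 1 / 151)
})

test_that("degenerate NBS inputs are rejected", {
  co <- tiny_cohort(n_subjects = 6, seed = 31)
  mask <- group_edge_mask(co, 1)
  expect_error(nbs(co, mask, co$table$apathy, nbs_config()), "at least 10")
  expect_error(nbs_config(n_permutations = 10), "n_permutations")
  expect_error(nbs_config(alpha = 1.2))
})

test_that("p-values are invariant to subject relabelling", {
  co <- tiny_cohort(n_subjects = 26, seed = 37, effect_beta = 0.12)
  mask <- group_edge_mask(co, 1)
  cfg <- nbs_config(n_permutations = 300, tail = "negative", rng_seed = 9)
  res1 <- nbs(co, mask, co$table$apathy, cfg)
  perm <- withr::with_seed(41, sample(26))
  co2 <- co
  co2$weights <- co$weights[, , perm]
  res2 <- nbs(co2, mask, co$table$apathy[perm], cfg)
  p1 <- vapply(res1$components$negative, `[[`, numeric(1), "p_fwer")
  p2 <- vapply(res2$components$negative, `[[`, numeric(1), "p_fwer")
  expect_equal(sort(vapply(res1$components$negative, `[[`, integer(1),
                           "extent")),
               sort(vapply(res2$components$negative, `[[`, integer(1),
                           "extent")))
  # identical observed statistics; p differs only through permutation noise
  expect_equal(sort(p1), sort(p2), tolerance = 0.05)
})
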