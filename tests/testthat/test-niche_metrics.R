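test_that("functional identity is the (weighted) centroid", {
  x <- rbind(c(1, 2, 3))
  expect_equal(unname(fide(x)), c(1, 2, 3))
  pair <- rbind(c(2, -1), c(-2, 1))
  expect_equal(unname(fide(pair)), c(0, 0))
  expect_equal(unname(fide(pair, weights = c(3, 1))), c(1, -0.5))
  expect_error(fide(pair, weights = c(0, 0)), "zero")
  expect_error(fide(pair, weights = c(-1, 2)), "nonnegative")
})

test_that("functional richness is a percentage of the pooled hull", {
  pooled <- square02
  expect_equal(fric(pooled, pooled), 100)
  expect_equal(fric(unit_square, pooled), 25)
  # d points in d dimensions span no volume
  expect_equal(fric(square02[1:2, ], pooled), 0)
  expect_error(fric(unit_square, cbind(0:3, 0)), "degenerate")
})

test_that("functional overlap matches the analytic square example", {
  expect_equal(fove(square02, square02 + 1), 1 / 7, tolerance = 1e-9)
  expect_equal(fove(square02, square02), 1)
  expect_equal(fove(square02, square02 + 10), 0)
  expect_error(fove(square02, square02[1:3, ] * 0), "zero-volume")
})

test_that("overlap is symmetric and invariant under common rigid motion", {
  set.seed(77)
  a <- matrix(rnorm(20 * 3), ncol = 3)
  b <- matrix(rnorm(20 * 3), ncol = 3) + 0.4
  f0 <- fove(a, b)
  expect_identical(fove(a, b), fove(b, a))
  q <- random_rotation(3)
  sh <- rnorm(3)
  expect_equal(fove(sweep(a %*% q, 2, sh, "+"), sweep(b %*% q, 2, sh, "+")),
               f0, tolerance = 1e-8)
  expect_gte(f0, 0)
  expect_lte(f0, 1)
})

test_that("PERMANOVA pseudo-F matches a hand-computed decomposition", {
  # groups {0, 1} and {10, 11} in 1-D: SS_between = 100, SS_within = 1,
  # F = (100 / 1) / (1 / 2) = 200
  coords <- matrix(c(0, 1, 10, 11), ncol = 1)
  labels <- c("a", "a", "b", "b")
  res <- permanova(coords, labels, n_perm = 0)
  expect_equal(res$pseudo_F, 200, tolerance = 1e-10)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 2L)
})

test_that("PERMANOVA agrees with an independent implementation", {
  set.seed(88)
  cl <- make_clusters(12, 3, shift = 1.5)
  ours <- permanova(cl$coords, cl$labels, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(dist(cl$coords) ~ g,
                        data = data.frame(g = cl$labels),
                        permutations = 99)
  expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-8)
})

test_that("PERMANOVA p-values behave under null and strong separation", {
  set.seed(99)
  # strong separation: minimal attainable p with the +1 convention
  cl <- make_clusters(15, 2, shift = 10)
  res <- permanova(cl$coords, cl$labels, n_perm = 999, seed = 2)
  expect_equal(res$p, 1 / 1000)
  # invariance to group relabeling
  relab <- c(g1 = "x", g2 = "y", g3 = "z")[cl$labels]
  res2 <- permanova(cl$coords, relab, n_perm = 99, seed = 5)
  res3 <- permanova(cl$coords, cl$labels, n_perm = 99, seed = 5)
  expect_equal(res2$pseudo_F, res3$pseudo_F)
  expect_equal(res2$p, res3$p)
  # invariance to global translation
  res4 <- permanova(sweep(cl$coords, 2, c(5, -3), "+"), cl$labels,
                    n_perm = 0)
  expect_equal(res4$pseudo_F, res3$pseudo_F, tolerance = 1e-10)
})

test_that("PERMANOVA rejects invalid groupings", {
  x <- matrix(rnorm(10), ncol = 2)
  expect_error(permanova(x, rep("a", 5)), "two groups")
  expect_error(permanova(x, c("a", "a", "a", "a", "b")), "fewer than 2")
})

test_that("bootstrap skips groups at or below the subsample size", {
  set.seed(111)
  pts <- list(
    big = matrix(rnorm(20 * 2), ncol = 2),
    small = matrix(rnorm(8 * 2), ncol = 2)
  )
  expect_message(
    res <- bootstrap_metric(pts, "fric", subsample_n = 8, n_reps = 20,
                            seed = 3),
    "small"
  )
  expect_true(is.na(res$ci_low[res$group_or_pair == "small"]))
  expect_false(is.na(res$ci_low[res$group_or_pair == "big"]))
})

test_that("single-replicate bootstrap collapses the interval", {
  set.seed(222)
  pts <- list(
    a = matrix(rnorm(15 * 2), ncol = 2),
    b = matrix(rnorm(15 * 2), ncol = 2)
  )
  res <- bootstrap_metric(pts, "fric", subsample_n = 10, n_reps = 1, seed = 4)
  expect_equal(res$ci_low, res$ci_high)
})

test_that("bootstrap is deterministic under a fixed seed", {
  set.seed(333)
  pts <- list(
    a = matrix(rnorm(18 * 3), ncol = 3),
    b = matrix(rnorm(16 * 3), ncol = 3) + 0.5
  )
  r1 <- bootstrap_metric(pts, "fove", subsample_n = 12, n_reps = 30, seed = 7)
  r2 <- bootstrap_metric(pts, "fove", subsample_n = 12, n_reps = 30, seed = 7)
  expect_identical(r1, r2)
  expect_true(all(r1$ci_low <= r1$ci_high))
})

test_that("niche_metrics bundles the group-level summary coherently", {
  dat <- generate_individuals(simulation_config(seed = 123))
  fs <- build_space(standardize_traits(compute_traits(dat)))
  nm <- niche_metrics(fs, n_perm = 99, seed = 9)
  expect_setequal(rownames(nm$fide), c("juvenile", "male", "female"))
  expect_true(all(nm$fric >= 0 & nm$fric <= 100))
  expect_equal(nrow(nm$fove), 3)
  expect_true(all(nm$fove$fove >= 0 & nm$fove$fove <= 1, na.rm = TRUE))
  expect_lt(nm$permanova$p, 0.05)  # default shift separates the groups
  # FIde equals the plain group centroid with unit weights
  juv <- fs$coordinates[fs$meta$group == "juvenile", ]
  expect_equal(unname(nm$fide["juvenile", ]), unname(colMeans(juv)),
               tolerance = 1e-10)
})
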