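test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_transects = 1), "at least 2")
  expect_error(simulation_config(group_sizes = c(juvenile = 0, male = 3)),
               "positive")
  expect_error(simulation_config(group_sizes = c(10, 20)), "named")
  expect_error(simulation_config(env_corr_temp = 1.2), "\\[-1, 1\\]")
  expect_error(simulation_config(trait_centroid_shift = -1), "nonnegative")
})

test_that("default generator reproduces the study-scale structure", {
  dat <- generate_individuals(simulation_config(seed = 5))
  expect_equal(nrow(dat), 111)
  expect_equal(as.integer(table(dat$group)[c("juvenile", "male", "female")]),
               c(40L, 30L, 41L))
  # stage-defining body-size threshold
  expect_true(all(dat$SVL[dat$group == "juvenile"] < 40))
  expect_true(all(dat$SVL[dat$group != "juvenile"] > 40))
  # all raw measurements positive, mass nonnegative
  expect_true(all(as.matrix(dat[setdiff(MORPHO_VARS, "M")]) > 0))
  expect_true(all(dat$M >= 0))
  expect_true(all(dat$transect %in% sprintf("T%02d", 1:11)))
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 99)
  expect_identical(generate_individuals(cfg), generate_individuals(cfg))
  expect_identical(generate_environments(cfg), generate_environments(cfg))
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1, d2)
  # different seeds give different draws
  expect_false(identical(
    generate_individuals(simulation_config(seed = 1)),
    generate_individuals(simulation_config(seed = 2))
  ))
})

test_that("realized environment correlations converge to the configuration", {
  env <- generate_environments(simulation_config(seed = 7), n_transects = 2000)
  expect_lt(abs(cor(env$SGT, env$ST) - 0.958), 0.02)
  expect_lt(abs(cor(env$BSC, env$CGC) - (-0.907)), 0.06) # logit-mapped
  # uncorrelated pair stays near zero
  expect_lt(abs(cor(env$AT, env$slope)), 0.06)
  # configured independence removes the cover association
  env0 <- generate_environments(
    simulation_config(seed = 8, env_corr_cover = 0), n_transects = 2000
  )
  expect_lt(abs(cor(env0$BSC, env0$CGC)), 0.06)
  # bounds respected
  expect_true(all(env$BSC >= 0 & env$BSC <= 100))
  expect_true(all(env$CGC >= 0 & env$CGC <= 100))
  expect_true(all(env$aspect >= 0 & env$aspect < 360))
})

test_that("count generator honours the log-linear model", {
  env <- generate_environments(simulation_config(seed = 11), n_transects = 400)
  # intercept-only: mean close to the configured baseline
  y0 <- generate_counts(env, c("(Intercept)" = log(5)), seed = 1)
  expect_lt(abs(mean(y0) - 5), 3 * sqrt(5 / 400))
  # unknown predictor name is rejected
  expect_error(generate_counts(env, c(XX = 1), seed = 1), "XX")
  # determinism
  cf <- c("(Intercept)" = log(4), ST = 0.5)
  expect_identical(generate_counts(env, cf, seed = 2),
                   generate_counts(env, cf, seed = 2))
})

test_that("a known coefficient is recovered from generated counts", {
  env <- generate_environments(simulation_config(seed = 13), n_transects = 200)
  y <- generate_counts(env, c("(Intercept)" = log(5), ST = 1), seed = 3)
  f <- fit_glm(y, data.frame(ST = as.numeric(scale(env$ST))))
  est <- f$coefficients
  expect_lt(abs(est$estimate[est$term == "ST"] - 1),
            2 * est$se[est$term == "ST"])
})

test_that("zero centroid shift makes the groups exchangeable", {
  # under the null configuration the PERMANOVA on trait space should
  # reject at close to the nominal rate
  set.seed(17)
  n_sim <- 120
  rej <- 0
  for (i in seq_len(n_sim)) {
    dat <- generate_individuals(
      simulation_config(
        seed = 20000 + i, trait_centroid_shift = 0,
        group_sizes = c(juvenile = 15, male = 15, female = 15)
      )
    )
    tm <- standardize_traits(compute_traits(dat))
    fs <- build_space(tm)
    p <- permanova(fs$coordinates, fs$meta$group, n_perm = 99,
                   seed = i)$p
    if (p <= 0.05) rej <- rej + 1
  }
  rate <- rej / n_sim
  # 0.05 +- 3.5 binomial SE at 120 simulations
  expect_gt(rate, 0.05 - 3.5 * sqrt(0.05 * 0.95 / n_sim))
  expect_lt(rate, 0.05 + 3.5 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("the integrated dataset keeps tables consistent", {
  dat <- simulate_dataset(simulation_config(seed = 31))
  counts <- table(dat$individuals$transect, dat$individuals$group)
  for (g in c("juvenile", "male", "female")) {
    got <- dat$transects[[paste0("n_", g)]]
    names(got) <- dat$transects$transect
    for (tr in rownames(counts)) {
      expect_equal(unname(got[tr]), unname(counts[tr, g]))
    }
  }
  expect_equal(sum(dat$transects$n_juvenile), 40)
  expect_equal(sum(dat$transects$n_male), 30)
  expect_equal(sum(dat$transects$n_female), 41)
})
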