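test_that("AICc arithmetic is exact", {
  expect_equal(aicc(-10, 3, 11), 20 + 6 + 24 / 7, tolerance = 1e-10)
  expect_equal(aicc(-10, 0, 11), 20)                       # k = 0 limit
  expect_equal(aicc(-10, 3, 1e9), -2 * -10 + 6, tolerance = 1e-6) # -> AIC
  expect_error(aicc(-10, 10, 11), "n must exceed")
})

test_that("normality screen flags the right distributions", {
  set.seed(12)
  env <- data.frame(AT = rnorm(100), SH = exp(rnorm(100, sd = 1.5)))
  res <- normality_screen(env, vars = c("AT", "SH"))
  expect_true(res$normal[res$variable == "AT"])
  expect_false(res$normal[res$variable == "SH"])
  const <- data.frame(AT = rep(1, 10))
  rc <- normality_screen(const, vars = "AT")
  expect_true(is.na(rc$normal))
  expect_error(normality_screen(data.frame(AT = c(1, 2)), vars = "AT"),
               "at least 3")
})

test_that("correlation screen collapses collinear pairs by preference", {
  set.seed(23)
  n <- 40
  st <- rnorm(n)
  env <- data.frame(
    AT = rnorm(n), ST = st, SGT = st + rnorm(n, sd = 0.05),
    CGC = runif(n, 20, 60)
  )
  env$BSC <- 95 - env$CGC + rnorm(n, sd = 1)
  res <- correlation_screen(env, vars = names(env),
                            prefer = c("ST", "CGC"))
  expect_true(all(c("ST", "CGC") %in% res$kept))
  expect_setequal(res$dropped, c("SGT", "BSC"))
  # duplicated column: |r| = 1, one member dropped
  env2 <- data.frame(AT = rnorm(n))
  env2$ST <- env2$AT
  res2 <- correlation_screen(env2, vars = c("AT", "ST"), prefer = "ST")
  expect_equal(res2$kept, "ST")
  # independent variables survive
  env3 <- as.data.frame(matrix(rnorm(n * 4), ncol = 4))
  names(env3) <- c("AT", "AH", "ST", "SH")
  res3 <- correlation_screen(env3, vars = names(env3), prefer = "ST")
  expect_length(res3$dropped, 0)
  expect_error(correlation_screen(env3, vars = names(env3), prefer = "XX"),
               "XX")
})

test_that("screen switches between Pearson and Spearman as prescribed", {
  set.seed(34)
  n <- 60
  env <- data.frame(AT = rnorm(n), SH = exp(rnorm(n, sd = 1.4)),
                    ST = rnorm(n))
  ns <- normality_screen(env, vars = names(env))
  res <- correlation_screen(env, vars = names(env), prefer = "ST",
                            normality = ns)
  expect_equal(res$method["AT", "ST"], "pearson")
  expect_equal(res$method["AT", "SH"], "spearman")
})

test_that("Poisson GLM recovers closed-form and simulated coefficients", {
  counts <- rep(7L, 20)
  f <- fit_glm(counts, data.frame(row.names = seq_len(20)))
  expect_equal(f$coefficients$estimate[1], log(7), tolerance = 1e-8)
  expect_equal(f$k, 1)
  set.seed(45)
  n <- 500
  x <- scale(matrix(rnorm(2 * n), ncol = 2))
  colnames(x) <- c("a", "b")
  mu <- exp(1 + 0.5 * x[, 1] - 0.3 * x[, 2])
  y <- rpois(n, mu)
  f2 <- fit_glm(y, as.data.frame(x))
  est <- setNames(f2$coefficients$estimate, f2$coefficients$term)
  se <- setNames(f2$coefficients$se, f2$coefficients$term)
  expect_lt(abs(est["a"] - 0.5), 3 * se["a"])
  expect_lt(abs(est["b"] + 0.3), 3 * se["b"])
  expect_error(fit_glm(y[1:3], as.data.frame(x[1:3, ])), "too few")
})

test_that("all-subsets enumeration is complete and ranked", {
  set.seed(56)
  n <- 60
  x <- as.data.frame(matrix(rnorm(3 * n), ncol = 3))
  names(x) <- c("a", "b", "c")
  y <- rpois(n, exp(1 + 1.2 * scale(x$a)))
  mt <- all_subsets(y, x)
  expect_equal(nrow(mt$table), 8)                    # 2^3
  expect_true(!is.unsorted(mt$table$AICc[mt$table$ok]))
  expect_equal(sum(mt$table$weight, na.rm = TRUE), 1, tolerance = 1e-8)
  expect_equal(mt$table$delta[1], 0)
  # the informative predictor appears in the top-ranked model, and every
  # model omitting it is far behind (a runner-up adding a noise term to
  # the true model can legitimately sit within 2 AICc, so an unambiguous
  # single winner is not guaranteed even at strong effects)
  expect_true(grepl("a", mt$table$terms[1]))
  without_a <- !vapply(mt$subsets, function(s) 1L %in% s, logical(1))
  expect_true(all(mt$table$delta[without_a] > 2))
})

test_that("pure-noise predictors leave the intercept-only model competitive", {
  set.seed(67)
  hits <- 0
  for (r in 1:10) {
    n <- 40
    x <- as.data.frame(matrix(rnorm(2 * n), ncol = 2))
    names(x) <- c("a", "b")
    y <- rpois(n, 5)
    mt <- all_subsets(y, x)
    d0 <- mt$table$delta[mt$table$terms == "(intercept)"]
    if (d0 <= 2) hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("Akaike weights follow the exponential-delta form", {
  # delta = {0, 2, 4} -> weights proportional to {1, e^-1, e^-2}
  w <- exp(-c(0, 2, 4) / 2)
  w <- w / sum(w)
  set.seed(78)
  # weights invariant to a constant shift in logLik: direct identity check
  ll <- c(-10, -11, -12)  # equal k, n -> deltas {0, 2, 4}
  a <- vapply(ll, aicc, numeric(1), k = 2, n = 30)
  d <- a - min(a)
  expect_equal(d, c(0, 2, 4), tolerance = 1e-10)
  wa <- exp(-d / 2) / sum(exp(-d / 2))
  expect_equal(wa, w, tolerance = 1e-12)
  a2 <- vapply(ll + 100, aicc, numeric(1), k = 2, n = 30)
  d2 <- a2 - min(a2)
  expect_equal(exp(-d2 / 2) / sum(exp(-d2 / 2)), w, tolerance = 1e-12)
})

test_that("model averaging handles the degenerate scopes exactly", {
  set.seed(89)
  n <- 50
  x <- as.data.frame(matrix(rnorm(2 * n), ncol = 2))
  names(x) <- c("a", "b")
  y <- rpois(n, exp(1 + scale(x$a)))
  mt <- all_subsets(y, x)
  # scope of one model returns that model's coefficients
  best_fit <- mt$models[[1]]$coefficients
  avg2 <- model_average(mt, scope = "delta2")
  if (sum(mt$table$delta[mt$table$ok] <= 2) == 1) {
    for (tm in best_fit$term) {
      expect_equal(avg2$estimate[avg2$term == tm],
                   best_fit$estimate[best_fit$term == tm], tolerance = 1e-10)
      expect_equal(avg2$se[avg2$term == tm],
                   best_fit$se[best_fit$term == tm], tolerance = 1e-10)
    }
  }
  # full average: every predictor and the intercept get a row
  avg <- model_average(mt, scope = "all")
  expect_setequal(avg$term, c("(Intercept)", "a", "b"))
  # coefficient of a predictor absent from every model in scope is shrunk
  # towards zero relative to its conditional estimate
  expect_lt(abs(avg$estimate[avg$term == "b"]),
            abs(coef(glm(y ~ ., data = cbind(data.frame(y = y), scale(x)),
                         family = poisson()))["b"]) + 1)
})

test_that("two models with equal AICc share the weight equally", {
  # symmetric design: duplicate predictor under two names
  set.seed(90)
  n <- 50
  a <- rnorm(n)
  x <- data.frame(a = a, b = a)        # identical columns
  y <- rpois(n, exp(1 + 0.8 * scale(a)))
  mt <- suppressWarnings(all_subsets(y, x))
  ok <- mt$table[mt$table$ok, ]
  wa <- ok$weight[ok$terms == "a"]
  wb <- ok$weight[ok$terms == "b"]
  expect_equal(wa, wb, tolerance = 1e-6)
})

test_that("hierarchical partitioning reproduces its defining identities", {
  set.seed(91)
  n <- 60
  # single predictor: I is its full goodness of fit, J = 0
  x1 <- data.frame(a = rnorm(n))
  y <- rnorm(n, 2 + x1$a)
  hp1 <- hierarchical_partition(y, x1, family = "gaussian")
  r2 <- summary(lm(y ~ ., data = cbind(data.frame(y = y), x1)))$r.squared
  expect_equal(hp1$I, r2, tolerance = 1e-10)
  expect_equal(hp1$J, 0, tolerance = 1e-10)
  # exactly orthogonal predictors: I equals the marginal R^2, J = 0
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), ncol = 2))))[, 2:3]
  x2 <- data.frame(a = q[, 1], b = q[, 2])
  y2 <- rnorm(n, 1 + 2 * q[, 1] - q[, 2])
  hp2 <- hierarchical_partition(y2, x2, family = "gaussian",
                                standardize = FALSE)
  m_a <- summary(lm(y2 ~ a, data = cbind(data.frame(y2 = y2), x2)))$r.squared
  m_b <- summary(lm(y2 ~ b, data = cbind(data.frame(y2 = y2), x2)))$r.squared
  expect_equal(hp2$I, c(m_a, m_b), tolerance = 1e-8)
  expect_equal(hp2$J, c(0, 0), tolerance = 1e-8)
  # independent contributions always rebuild the full-model fit
  x3 <- as.data.frame(matrix(rnorm(n * 3), ncol = 3))
  x3$V2 <- x3$V2 + 0.8 * x3$V1          # correlated design
  y3 <- rnorm(n, x3$V1 + 0.5 * x3$V3)
  hp3 <- hierarchical_partition(y3, x3, family = "gaussian")
  expect_equal(sum(hp3$I), attr(hp3, "gof_full"), tolerance = 1e-8)
  expect_equal(sum(hp3$I_pct), 100, tolerance = 1e-8)
})

test_that("hierarchical partitioning matches a brute-force Shapley oracle", {
  set.seed(92)
  n <- 50
  x <- as.data.frame(matrix(rnorm(n * 3), ncol = 3))
  x$V2 <- x$V2 + 0.6 * x$V1
  y <- rnorm(n, 1.5 * x$V1 - x$V2 + 0.3 * x$V3)
  xs <- as.data.frame(scale(x))
  gof <- function(sel) {
    if (!length(sel)) return(0)
    d <- cbind(data.frame(y = y), xs[, sel, drop = FALSE])
    summary(lm(y ~ ., data = d))$r.squared
  }
  oracle <- hp_bruteforce(gof, 3)
  hp <- hierarchical_partition(y, x, family = "gaussian")
  expect_equal(hp$I, oracle, tolerance = 1e-8)
})

test_that("partitioning works on count responses via deviance explained", {
  set.seed(93)
  n <- 80
  x <- as.data.frame(matrix(rnorm(n * 3), ncol = 3))
  names(x) <- c("a", "b", "c")
  y <- rpois(n, exp(1 + 0.6 * scale(x$a) - 0.4 * scale(x$b)))
  hp <- hierarchical_partition(y, x, family = "poisson")
  expect_equal(sum(hp$I), attr(hp, "gof_full"), tolerance = 1e-8)
  expect_gt(hp$I[hp$predictor == "a"], hp$I[hp$predictor == "c"])
})
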