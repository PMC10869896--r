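#' Microhabitat variable names expected in a transect table
#'
#' Air temperature (AT, deg C), air humidity (AH, %), surface ground
#' temperature (SGT, deg C), soil temperature (ST, deg C), soil humidity
#' (SH, %), slope (degrees), aspect (degrees, treated as a linear variable),
#' illuminance (Illu, lux), rock coverage (RC, %), bare soil coverage
#' (BSC, %), clumping grass coverage (CGC, %).
#' @export
ENV_VARS <- c("AT", "AH", "SGT", "ST", "SH", "slope", "aspect", "Illu",
              "RC", "BSC", "CGC")

#' Shapiro-Wilk normality screen of microhabitat variables
#'
#' @param env data frame of transects.
#' @param vars variables to test (default [ENV_VARS] intersected with the
#'   columns present).
#' @param alpha significance level; a variable is flagged normal when its
#'   Shapiro-Wilk p-value is at least `alpha`.
#' @return data frame with `variable`, `W`, `p`, `normal`; constant
#'   variables are flagged non-testable (`NA` statistics).
#' @export
normality_screen <- function(env, vars = NULL, alpha = 0.05) {
  env <- as.data.frame(env)
  if (is.null(vars)) vars <- intersect(ENV_VARS, names(env))
  if (!length(vars)) stop("no variables to screen")
  miss <- setdiff(vars, names(env))
  if (length(miss)) stop("variable(s) absent from env: ", paste(miss, collapse = ", "))
  if (nrow(env) < 3) stop("Shapiro-Wilk test needs at least 3 observations")
  out <- lapply(vars, function(v) {
    x <- env[[v]]
    if (length(unique(x)) < 2) {
      return(data.frame(variable = v, W = NA_real_, p = NA_real_, normal = NA))
    }
    s <- shapiro.test(x)
    data.frame(variable = v, W = unname(s$statistic), p = s$p.value,
               normal = s$p.value >= alpha)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Collinearity screen of microhabitat variables
#'
#' Computes all pairwise correlations, using Spearman's rank correlation
#' when either member of a pair failed the normality screen and Pearson's
#' correlation otherwise.  Pairs with `|r| >= threshold` and `p < 0.05`
#' are collapsed to a single member: the one named in `prefer` if exactly
#' one of the pair is, otherwise the first of the pair in column order.
#' Pairs are processed in decreasing `|r|`, so chained collinearity is
#' resolved greedily.
#'
#' @param env data frame of transects.
#' @param vars candidate variables (default [ENV_VARS] present in `env`).
#' @param threshold absolute correlation above which a pair is collapsed
#'   (default 0.9).
#' @param prefer character vector of variables to keep when they conflict
#'   with another; defaults to soil temperature over surface ground
#'   temperature and clumping grass over bare soil coverage.
#' @param normality optional result of [normality_screen()]; computed
#'   internally when missing.
#' @return list with `kept`, `dropped`, the full correlation matrix `r`,
#'   the matrix of `method`s used per pair, and a `decisions` data frame.
#' @export
correlation_screen <- function(env, vars = NULL, threshold = 0.9,
                               prefer = c("ST", "CGC"), normality = NULL) {
  env <- as.data.frame(env)
  if (is.null(vars)) vars <- intersect(ENV_VARS, names(env))
  miss <- setdiff(vars, names(env))
  if (length(miss)) stop("variable(s) absent from env: ", paste(miss, collapse = ", "))
  bad_pref <- setdiff(prefer, vars)
  if (length(bad_pref)) {
    stop("prefer names variable(s) not under screening: ",
         paste(bad_pref, collapse = ", "))
  }
  if (is.null(normality)) normality <- normality_screen(env, vars)
  is_normal <- setNames(normality$normal, normality$variable)
  p <- length(vars)
  r <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  pm <- r
  meth <- matrix(NA_character_, p, p, dimnames = list(vars, vars))
  diag(r) <- 1
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      m <- if (isTRUE(is_normal[vars[i]]) && isTRUE(is_normal[vars[j]])) {
        "pearson"
      } else {
        "spearman"
      }
      ct <- suppressWarnings(
        cor.test(env[[vars[i]]], env[[vars[j]]], method = m, exact = FALSE)
      )
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      pm[i, j] <- pm[j, i] <- ct$p.value
      meth[i, j] <- meth[j, i] <- m
    }
  }
  pairs <- which(upper.tri(r) & abs(r) >= threshold & pm < 0.05, arr.ind = TRUE)
  if (nrow(pairs)) {
    pairs <- pairs[order(-abs(r[pairs])), , drop = FALSE]
  }
  kept <- vars
  decisions <- list()
  for (k in seq_len(nrow(pairs))) {
    a <- vars[pairs[k, 1]]
    b <- vars[pairs[k, 2]]
    if (!(a %in% kept) || !(b %in% kept)) next
    in_pref <- c(a, b) %in% prefer
    keep <- if (sum(in_pref) == 1) c(a, b)[in_pref] else a
    drop <- setdiff(c(a, b), keep)
    kept <- setdiff(kept, drop)
    decisions[[length(decisions) + 1]] <- data.frame(
      kept = keep, dropped = drop, r = r[a, b], p = pm[a, b],
      method = meth[a, b], stringsAsFactors = FALSE
    )
  }
  decisions <- if (length(decisions)) do.call(rbind, decisions) else
    data.frame(kept = character(0), dropped = character(0), r = numeric(0),
               p = numeric(0), method = character(0))
  list(
    kept = kept, dropped = setdiff(vars, kept), r = r, p_values = pm,
    method = meth, decisions = decisions
  )
}

#' Fit a count GLM of captures on standardized microhabitat predictors
#'
#' Poisson log-link by default; a negative binomial alternative
#' (`MASS::glm.nb`) is available for overdispersed counts.  Predictors are
#' expected to be standardized (mean 0, SD 1) so coefficient magnitudes
#' are comparable and AICc differences stable; a warning is emitted when
#' they are not.
#'
#' @param counts nonnegative integer response, one per transect.
#' @param predictors data frame or matrix of standardized predictors (may
#'   have zero columns for an intercept-only model).
#' @param family `"poisson"` or `"negbin"`.
#' @param strict error when the iterative fit fails to converge (default).
#'   With `strict = FALSE` a non-converged fit is returned anyway, which
#'   is the permissive behaviour hierarchical partitioning needs for
#'   near-saturated subsets at very small sample sizes.
#' @return list with the coefficient table (`estimate`, `se`, `z`, `p`),
#'   `logLik`, `k` (number of estimated parameters, including the negative
#'   binomial shape when used), `deviance`, `null_deviance`, `family`, and
#'   the fitted `model` object.
#' @export
fit_glm <- function(counts, predictors, family = c("poisson", "negbin"),
                    strict = TRUE) {
  family <- match.arg(family)
  predictors <- as.data.frame(predictors)
  n <- length(counts)
  if (nrow(predictors) > 0 && nrow(predictors) != n) {
    stop("counts and predictors have different lengths")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  k_pred <- ncol(predictors)
  n_min <- if (strict) k_pred + 2 else k_pred + 1
  if (n < n_min) {
    stop("too few observations: need n >= ", n_min, ", got ", n)
  }
  if (k_pred > 0) {
    mu <- vapply(predictors, mean, numeric(1))
    s <- vapply(predictors, sd, numeric(1))
    if (any(abs(mu) > 1e-6) || any(abs(s - 1) > 1e-3)) {
      warning("predictors do not look standardized (mean 0, SD 1)")
    }
  }
  dat <- cbind(data.frame(.y = counts), predictors)
  fml <- if (k_pred > 0) {
    stats::as.formula(paste(".y ~", paste(names(predictors), collapse = " + ")))
  } else {
    stats::as.formula(".y ~ 1")
  }
  fit <- if (family == "poisson") {
    glm(fml, data = dat, family = poisson(), control = stats::glm.control(maxit = 100))
  } else {
    MASS::glm.nb(fml, data = dat, control = stats::glm.control(maxit = 100))
  }
  if (strict && !fit$converged) {
    stop("GLM did not converge (", family, ", k = ", k_pred, ")")
  }
  if (fit$rank < k_pred + 1) stop("degenerate design: rank-deficient predictor matrix")
  sm <- summary(fit)$coefficients
  coefs <- data.frame(
    term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
    z = sm[, 3], p = sm[, 4], row.names = NULL, stringsAsFactors = FALSE
  )
  k <- k_pred + 1 + (family == "negbin")
  list(
    coefficients = coefs,
    logLik = as.numeric(logLik(fit)),
    k = k,
    deviance = fit$deviance,
    null_deviance = fit$null.deviance,
    family = family,
    model = fit
  )
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param logLik model log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size; must exceed `k + 1`.
#' @return the AICc value.
#' @examples
#' aicc(-10, 3, 11) # 20 + 6 + 24/7
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1 (n = ", n, ", k = ", k, ")")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' All-subsets GLM enumeration ranked by AICc
#'
#' Fits every subset of the candidate predictors (including the
#' intercept-only model), ranks the models by AICc and computes Akaike
#' weights `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` over the
#' models that could be fitted and scored.  The best model is declared
#' unambiguous only when the runner-up sits more than 2 AICc units away;
#' otherwise the table is flagged `"ambiguous"` and model averaging is the
#' recommended summary.
#'
#' Member fits that fail (non-convergence, undefined AICc at very small
#' `n`) are retained in the table but flagged, excluded from the weights,
#' and reported in `failed`.
#'
#' @param counts response counts, one per transect.
#' @param predictors data frame of standardized candidate predictors
#'   (at most 12, since all `2^p` subsets are fitted).
#' @param family passed to [fit_glm()].
#' @param standardize z-score the predictors before fitting (default TRUE).
#' @return object of class `model_table`: list with `table` (one row per
#'   subset: `terms`, `k`, `logLik`, `AICc`, `delta`, `weight`, `ok`),
#'   `models` (per-subset coefficient tables), `best` (predictor subset or
#'   `NULL`), `decision` (`"best"` or `"ambiguous"`), `failed`, `n`,
#'   `family`, and the predictor data actually used.
#' @export
all_subsets <- function(counts, predictors, family = c("poisson", "negbin"),
                        standardize = TRUE) {
  family <- match.arg(family)
  predictors <- as.data.frame(predictors)
  p <- ncol(predictors)
  if (p > 12) stop("at most 12 predictors supported (2^p enumeration), got ", p)
  if (standardize && p > 0) {
    predictors <- as.data.frame(scale(predictors))
  }
  n <- length(counts)
  subsets <- lapply(0:(2^p - 1), function(mask) {
    which(bitwAnd(mask, bitwShiftL(1, seq_len(p) - 1)) != 0)
  })
  rows <- vector("list", length(subsets))
  models <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    sel <- subsets[[i]]
    terms <- if (length(sel)) paste(names(predictors)[sel], collapse = "+") else "(intercept)"
    res <- tryCatch(
      {
        f <- fit_glm(counts, predictors[, sel, drop = FALSE], family = family)
        list(ok = TRUE, fit = f, aicc = aicc(f$logLik, f$k, n))
      },
      error = function(e) list(ok = FALSE, msg = conditionMessage(e))
    )
    if (res$ok) {
      rows[[i]] <- data.frame(
        terms = terms, k = res$fit$k, logLik = res$fit$logLik,
        AICc = res$aicc, ok = TRUE, stringsAsFactors = FALSE
      )
      models[[i]] <- res$fit
    } else {
      rows[[i]] <- data.frame(
        terms = terms, k = length(sel) + 1 + (family == "negbin"),
        logLik = NA_real_, AICc = NA_real_, ok = FALSE, stringsAsFactors = FALSE
      )
      models[[i]] <- list(error = res$msg)
    }
  }
  tab <- do.call(rbind, rows)
  tab$subset <- subsets
  ord <- order(tab$AICc)
  tab <- tab[ord, ]
  models <- models[ord]
  failed <- tab$terms[!tab$ok]
  if (length(failed)) {
    message("all_subsets: ", length(failed), " model(s) could not be scored")
  }
  if (!any(tab$ok)) stop("no candidate model could be fitted")
  tab$delta <- tab$AICc - min(tab$AICc, na.rm = TRUE)
  w <- exp(-tab$delta / 2)
  w[!tab$ok] <- NA
  tab$weight <- w / sum(w, na.rm = TRUE)
  ok_idx <- which(tab$ok)
  decision <- "ambiguous"
  if (length(ok_idx) >= 2) {
    if (tab$delta[ok_idx[2]] > 2) decision <- "best"
  } else if (length(ok_idx) == 1) {
    decision <- "best"
  }
  best <- if (decision == "best") tab$subset[[ok_idx[1]]] else NULL
  structure(
    list(
      table = tab[, c("terms", "k", "logLik", "AICc", "delta", "weight", "ok")],
      subsets = tab$subset,
      models = models,
      best = if (!is.null(best)) names(predictors)[best] else NULL,
      decision = decision,
      failed = failed,
      n = n,
      family = family,
      predictors = predictors,
      counts = counts
    ),
    class = "model_table"
  )
}

#' @export
print.model_table <- function(x, n = 6, ...) {
  cat("All-subsets GLM table (", x$family, "), n = ", x$n, ", ",
      nrow(x$table), " models\n", sep = "")
  print(utils::head(cbind(x$table[, c("terms", "k", "AICc", "delta", "weight")]), n))
  cat("decision:", x$decision,
      if (!is.null(x$best)) paste0("(best: ", paste(x$best, collapse = "+"), ")"),
      "\n")
  invisible(x)
}

#' Akaike model averaging of an all-subsets table
#'
#' Full ("zero") model averaging in the Burnham-Anderson sense: a model
#' not containing a predictor contributes a coefficient of 0, averaged
#' coefficients are `sum_i w_i beta_i` with renormalized Akaike weights
#' over the chosen scope, and unconditional standard errors are
#' `sum_i w_i sqrt(se_i^2 + (beta_i - beta_bar)^2)`.  Two-sided p-values
#' use the normal approximation.
#'
#' @param mt a `model_table` from [all_subsets()].
#' @param scope which models enter the average: `"all"` converged models,
#'   `"delta2"` (AICc within 2 of the best), or `"cum95"` (smallest set
#'   with cumulative weight at least 0.95).
#' @return data frame with `term`, `estimate`, `se`, `z`, `p` for the
#'   intercept and every predictor.
#' @export
model_average <- function(mt, scope = c("all", "delta2", "cum95")) {
  scope <- match.arg(scope)
  stopifnot(inherits(mt, "model_table"))
  ok <- which(mt$table$ok)
  sel <- switch(scope,
    all = ok,
    delta2 = ok[mt$table$delta[ok] <= 2],
    cum95 = {
      cw <- cumsum(mt$table$weight[ok])
      ok[seq_len(which(cw >= 0.95)[1])]
    }
  )
  if (!length(sel)) stop("empty model-averaging scope")
  w <- mt$table$weight[sel]
  w <- w / sum(w)
  terms <- c("(Intercept)", names(mt$predictors))
  est_mat <- matrix(0, length(sel), length(terms), dimnames = list(NULL, terms))
  se_mat <- est_mat
  for (i in seq_along(sel)) {
    cf <- mt$models[[sel[i]]]$coefficients
    est_mat[i, cf$term] <- cf$estimate
    se_mat[i, cf$term] <- cf$se
  }
  est <- colSums(w * est_mat)
  se <- vapply(seq_along(terms), function(j) {
    sum(w * sqrt(se_mat[, j]^2 + (est_mat[, j] - est[j])^2))
  }, numeric(1))
  z <- ifelse(se > 0, est / se, NA_real_)
  data.frame(
    term = terms, estimate = unname(est), se = se, z = z,
    p = 2 * pnorm(abs(z), lower.tail = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Hierarchical partitioning of predictor contributions
#'
#' Chevan-Sutherland hierarchical partitioning: all `2^p` models are
#' fitted and, for each predictor, the improvement in goodness of fit from
#' adding it is averaged first within and then across hierarchy levels,
#' giving its independent contribution `I`.  The joint contribution is
#' `J = R(\{j\}) - I_j`, the part of the predictor's single-variable fit
#' shared with other predictors.  The independent contributions always sum
#' exactly to the full model's goodness of fit.
#'
#' Goodness of fit is the deviance-explained fraction
#' `1 - deviance(S) / deviance(null)` for count GLMs and `R^2` for
#' `family = "gaussian"`.
#'
#' @param response counts (or a continuous response for `"gaussian"`).
#' @param predictors data frame of predictors (at most 12).
#' @param family `"poisson"`, `"negbin"` or `"gaussian"`.
#' @param standardize z-score predictors first (default TRUE).
#' @return object of class `hier_part`: data frame with `predictor`, `I`
#'   (independent contribution, goodness-of-fit units), `I_pct`
#'   (percentage of the summed independent contributions), `J` (joint),
#'   plus attributes `gof_full` and `gof` (the subset goodness-of-fit
#'   lookup used).
#' @export
hierarchical_partition <- function(response, predictors,
                                   family = c("poisson", "negbin", "gaussian"),
                                   standardize = TRUE) {
  family <- match.arg(family)
  predictors <- as.data.frame(predictors)
  p <- ncol(predictors)
  if (p < 1) stop("need at least one predictor")
  if (p > 12) stop("at most 12 predictors supported, got ", p)
  if (standardize) predictors <- as.data.frame(scale(predictors))
  gof <- numeric(2^p)
  for (mask in 0:(2^p - 1)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1, seq_len(p) - 1)) != 0)
    gof[mask + 1] <- tryCatch(
      subset_gof(response, predictors, sel, family),
      error = function(e) {
        stop("fit failed for subset {",
             paste(names(predictors)[sel], collapse = ","), "}: ",
             conditionMessage(e))
      }
    )
  }
  full <- gof[2^p]
  I <- numeric(p)
  for (j in seq_len(p)) {
    bit_j <- bitwShiftL(1, j - 1)
    level_sum <- numeric(p)      # mean improvement by hierarchy level
    level_cnt <- numeric(p)
    for (mask in 0:(2^p - 1)) {
      if (bitwAnd(mask, bit_j) != 0) next
      sz <- sum(bitwAnd(mask, bitwShiftL(1, seq_len(p) - 1)) != 0)
      gain <- gof[mask + bit_j + 1] - gof[mask + 1]
      level_sum[sz + 1] <- level_sum[sz + 1] + gain
      level_cnt[sz + 1] <- level_cnt[sz + 1] + 1
    }
    lv <- level_cnt > 0
    I[j] <- mean(level_sum[lv] / level_cnt[lv])
  }
  marg <- vapply(seq_len(p), function(j) gof[bitwShiftL(1, j - 1) + 1], numeric(1))
  out <- data.frame(
    predictor = names(predictors), I = I,
    I_pct = 100 * I / sum(I), J = marg - I,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "gof_full") <- full
  attr(out, "gof") <- gof
  class(out) <- c("hier_part", "data.frame")
  out
}

subset_gof <- function(response, predictors, sel, family) {
  x <- predictors[, sel, drop = FALSE]
  if (family == "gaussian") {
    if (!length(sel)) return(0)
    fit <- lm(response ~ ., data = cbind(data.frame(response = response), x))
    return(summary(fit)$r.squared)
  }
  if (!length(sel)) return(0)
  f <- suppressWarnings(
    fit_glm(response, x, family = if (family == "negbin") "negbin" else "poisson",
            strict = FALSE)
  )
  1 - f$deviance / f$null_deviance
}
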