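#' DCA gradient length and linear-vs-unimodal model recommendation
#'
#' Runs a detrended correspondence analysis (detrending by segments,
#' Hill-Gauch, via [vegan::decorana()]) and reports the axis-1 gradient
#' length, i.e. the range of the site scores in standard-deviation units
#' of turnover.  A gradient shorter than 3 SD indicates responses are
#' close to linear over the sampled range, so redundancy analysis (RDA) is
#' recommended; longer gradients favour canonical correspondence analysis.
#'
#' Correspondence analysis needs nonnegative input, while standardized
#' traits are centred; each column is therefore shifted so its minimum is
#' zero before the DCA.  A matrix whose rows are identical collapses to a
#' zero matrix under this shift: there is no gradient at all, and length 0
#' (RDA) is returned directly.
#'
#' @param x numeric matrix (individuals x traits, or sites x species).
#' @param n_segments number of detrending segments (default 26).
#' @return object of class `dca_result`: list with
#'   `axis1_gradient_length`, `recommendation` (`"RDA"` or `"CCA"`),
#'   `n_segments` and the underlying `decorana` fit (`NULL` in the
#'   degenerate no-gradient case).
#' @export
dca_gradient_length <- function(x, n_segments = 26) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite values in matrix")
  shifted <- sweep(x, 2, apply(x, 2, min))
  keep <- colSums(shifted) > 0
  if (!any(keep)) {
    return(structure(
      list(axis1_gradient_length = 0, recommendation = "RDA",
           n_segments = n_segments, decorana = NULL),
      class = "dca_result"
    ))
  }
  shifted <- shifted[, keep, drop = FALSE]
  zero_rows <- which(rowSums(shifted) == 0)
  if (length(zero_rows)) {
    stop("degenerate matrix: all-zero row(s) after min-shift: ",
         paste(zero_rows, collapse = ", "))
  }
  dd <- vegan::decorana(shifted, mk = n_segments)
  sc <- vegan::scores(dd, display = "sites", choices = 1)
  len <- diff(range(sc))
  structure(
    list(
      axis1_gradient_length = len,
      recommendation = if (len < 3) "RDA" else "CCA",
      n_segments = n_segments,
      decorana = dd
    ),
    class = "dca_result"
  )
}

#' @export
print.dca_result <- function(x, ...) {
  cat(sprintf(
    "DCA axis-1 gradient length: %.3f SD -> %s recommended\n",
    x$axis1_gradient_length, x$recommendation
  ))
  invisible(x)
}

#' Redundancy analysis of traits on microhabitat variables
#'
#' Constrained ordination: traits are regressed on the environmental
#' predictors by multivariate least squares and the fitted values are
#' eigendecomposed, so each canonical axis is the direction of trait
#' variation best explained by the environment.  Canonical eigenvalues are
#' reported as percentages of the total trait variance.  Scores are scaled
#' for a correlation ("type 2") triplot: trait and environment arrows are
#' the Pearson correlations of each variable with the axis scores, so the
#' cosine of the angle between two arrows approximates the correlation
#' between the variables they represent.
#'
#' @param traits standardized trait matrix (or `trait_matrix` object),
#'   individuals x traits.
#' @param env data frame or matrix of environment values per individual
#'   (standardized internally); must be of full column rank.
#' @param n_perm permutations for the overall significance test
#'   (default 999); 0 skips the test.
#' @param seed optional integer seed for the permutation test.
#' @return object of class `rda_result`: `canonical_eigenvalues`,
#'   `pct_of_total`, `total_variance`, `constrained_variance`,
#'   `residual_variance`, `axis_scores` (individuals x axes, linear
#'   combinations of the environment), `env_scores` and `trait_scores`
#'   (correlation arrows), and `perm_test` (list `F`, `p`, `n_perm`).
#' @export
rda_traits_env <- function(traits, env, n_perm = 999, seed = NULL) {
  if (inherits(traits, "trait_matrix")) {
    if (!isTRUE(traits$standardized)) stop("traits must be standardized")
    traits <- traits$traits
  }
  y <- as.matrix(traits)
  x <- as.matrix(as.data.frame(env))
  if (nrow(y) != nrow(x)) stop("traits and env describe different individuals")
  n <- nrow(y)
  q <- ncol(x)
  y <- scale(y, center = TRUE, scale = FALSE)
  x <- scale(x) # z-score predictors
  if (any(!is.finite(x))) {
    stop("constant or non-finite env column(s): ",
         paste(colnames(x)[apply(x, 2, function(v) any(!is.finite(v)))],
               collapse = ", "))
  }
  qr_x <- qr(x)
  if (qr_x$rank < q) {
    dep <- colnames(x)[-qr_x$pivot[seq_len(qr_x$rank)]]
    stop("env matrix is rank deficient; linearly dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  if (n <= q + 1) stop("need more individuals than predictors plus one")
  yhat <- qr.fitted(qr_x, y)
  sv <- svd(yhat / sqrt(n - 1))
  lam <- sv$d^2
  nz <- lam > max(lam[1], 1) * 1e-12
  lam <- lam[nz]
  axes <- sv$v[, nz, drop = FALSE]
  total <- sum(y^2) / (n - 1)
  site <- yhat %*% axes
  colnames(site) <- paste0("RDA", seq_len(ncol(site)))
  rownames(site) <- rownames(y)
  safe_cor <- function(a, b) {
    out <- suppressWarnings(cor(a, b))
    out[!is.finite(out)] <- 0
    out
  }
  trait_sc <- safe_cor(y, site)
  env_sc <- safe_cor(x, site)
  perm <- if (n_perm > 0) {
    rda_permutation_test(y, x, n_perm = n_perm, seed = seed)
  } else {
    list(F = rda_pseudo_f(y, x), p = NA_real_, n_perm = 0L)
  }
  structure(
    list(
      canonical_eigenvalues = lam,
      pct_of_total = 100 * lam / total,
      total_variance = total,
      constrained_variance = sum(lam),
      residual_variance = total - sum(lam),
      axis_scores = site,
      trait_scores = trait_sc,
      env_scores = env_sc,
      n = n, q = q,
      perm_test = perm
    ),
    class = "rda_result"
  )
}

#' Permutation test of the overall RDA constraint
#'
#' Pseudo-F is `(constrained variance / q) / (residual variance /
#' (n - q - 1))`; the rows of the environment matrix are permuted
#' `n_perm` times and the p-value uses the `(1 + exceedances) /
#' (1 + n_perm)` convention.
#'
#' @param traits centred/standardized trait matrix.
#' @param env environment matrix (standardized internally).
#' @param n_perm number of permutations (default 999, must be >= 1).
#' @param seed optional integer seed.
#' @return list with `F`, `p`, `n_perm`.
#' @export
rda_permutation_test <- function(traits, env, n_perm = 999, seed = NULL) {
  if (inherits(traits, "trait_matrix")) traits <- traits$traits
  y <- scale(as.matrix(traits), center = TRUE, scale = FALSE)
  x <- scale(as.matrix(as.data.frame(env)))
  if (any(!is.finite(x))) stop("constant or non-finite env column(s)")
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(y)
  f_obs <- rda_pseudo_f(y, x)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (rda_pseudo_f(y, x[sample.int(n), , drop = FALSE]) >= f_obs) {
      exceed <- exceed + 1L
    }
  }
  list(F = f_obs, p = (1 + exceed) / (1 + n_perm), n_perm = as.integer(n_perm))
}

rda_pseudo_f <- function(y, x) {
  n <- nrow(y)
  q <- qr(x)$rank
  yhat <- qr.fitted(qr(x), y)
  ss_fit <- sum(yhat^2)
  ss_res <- sum((y - yhat)^2)
  (ss_fit / q) / (ss_res / (n - q - 1))
}

#' Marginal permutation significance of each environment variable
#'
#' Tests each variable alone against the trait matrix with
#' [rda_permutation_test()]; variables with `p < alpha` are flagged for
#' retention in a triplot.
#'
#' @param traits standardized trait matrix.
#' @param env environment data frame.
#' @param n_perm permutations per variable.
#' @param alpha retention threshold (default 0.05).
#' @param seed optional integer seed (a per-variable child seed is derived
#'   from it).
#' @return data frame with `variable`, `F`, `p`, `significant`.
#' @export
rda_term_significance <- function(traits, env, n_perm = 999, alpha = 0.05,
                                  seed = NULL) {
  env <- as.data.frame(env)
  out <- lapply(seq_along(env), function(j) {
    s <- if (is.null(seed)) NULL else child_seed(seed, names(env)[j])
    pt <- rda_permutation_test(traits, env[, j, drop = FALSE],
                               n_perm = n_perm, seed = s)
    data.frame(variable = names(env)[j], F = pt$F, p = pt$p,
               significant = pt$p < alpha)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.rda_result <- function(x, ...) {
  k <- min(2, length(x$pct_of_total))
  cat(sprintf(
    "RDA: %d canonical axes; first %d explain %.2f%% of total trait variance\n",
    length(x$canonical_eigenvalues), k, sum(x$pct_of_total[seq_len(k)])
  ))
  if (!is.na(x$perm_test$p)) {
    cat(sprintf("  overall permutation test: F = %.3f, p = %.4g (%d permutations)\n",
                x$perm_test$F, x$perm_test$p, x$perm_test$n_perm))
  }
  invisible(x)
}

#' Canonical correspondence analysis (not implemented)
#'
#' The DCA gate ([dca_gradient_length()]) selects RDA for short gradients,
#' which is the regime this package targets; CCA is intentionally not
#' provided.
#'
#' @param ... ignored.
#' @export
cca_traits_env <- function(...) {
  stop("CCA is not implemented: for short (< 3 SD) gradients the DCA gate ",
       "recommends RDA; use rda_traits_env()")
}
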