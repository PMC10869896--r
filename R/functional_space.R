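#' Build a PCA functional space from standardized traits
#'
#' Eigendecomposes the trait correlation matrix (equivalently, PCA of the
#' standardized traits) and retains every axis with eigenvalue greater than
#' 1 (Kaiser criterion, with a `1e-12` guard so ties at exactly 1 are
#' kept).  Individuals' scores on the retained axes define the functional
#' space in which convex-hull niche metrics are measured.
#'
#' Axis signs are arbitrary in any eigendecomposition; here each axis is
#' oriented so that the trait with the largest absolute correlation with
#' the axis correlates positively, making outputs reproducible across
#' platforms.
#'
#' @param tm a standardized `trait_matrix` (see [standardize_traits()]).
#' @return an object of class `functional_space` with elements
#'   `eigenvalues` (all axes, nonincreasing), `explained_pct` (percentages,
#'   summing to 100 over all axes), `retained_axes`, `coordinates`
#'   (individuals x retained axes), `loadings` (Pearson correlations
#'   between traits and retained axes), `loadings_p` (two-sided correlation
#'   test p-values) and the individual `meta` table.
#' @examples
#' dat <- simulate_dataset(simulation_config(seed = 1))
#' fs <- build_space(standardize_traits(compute_traits(dat$individuals)))
#' fs$retained_axes
#' @export
build_space <- function(tm) {
  stopifnot(inherits(tm, "trait_matrix"))
  if (!isTRUE(tm$standardized)) stop("build_space() expects a standardized trait matrix")
  z <- tm$traits
  n <- nrow(z)
  p <- ncol(z)
  if (n < p + 1) stop("need at least ", p + 1, " individuals for ", p, " traits")
  r <- cor(z)
  if (!all(is.finite(r))) stop("correlation matrix contains non-finite entries")
  eg <- eigen(r, symmetric = TRUE)
  if (min(eg$values) < -1e-8) stop("correlation matrix is not positive semi-definite")
  rank_tol <- 1e-10
  if (sum(eg$values > rank_tol) < 2) stop("trait correlation matrix is singular")
  values <- pmax(eg$values, 0)
  retained <- sum(values > 1 - 1e-12)
  vec <- eg$vectors[, seq_len(retained), drop = FALSE]
  scores <- z %*% vec
  # sign convention: dominant trait of each axis loads positively
  load <- vec %*% diag(sqrt(values[seq_len(retained)]), retained)
  for (k in seq_len(retained)) {
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) {
      vec[, k] <- -vec[, k]
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  dimnames(load) <- list(colnames(z), paste0("PC", seq_len(retained)))
  colnames(scores) <- paste0("PC", seq_len(retained))
  rownames(scores) <- rownames(z)
  tstat <- load * sqrt((n - 2) / pmax(1 - load^2, .Machine$double.eps))
  pval <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  structure(
    list(
      eigenvalues = values,
      explained_pct = 100 * values / sum(values),
      retained_axes = retained,
      coordinates = scores,
      loadings = load,
      loadings_p = pval,
      meta = tm$meta
    ),
    class = "functional_space"
  )
}

#' Pearson correlations between traits and functional-space axes
#'
#' Recomputes the trait-axis correlation table directly from the data (for
#' correlation-matrix PCA this equals eigenvector times the square root of
#' the eigenvalue, which is how [build_space()] fills its `loadings`).
#'
#' @param space a `functional_space`.
#' @param tm the standardized `trait_matrix` the space was built from.
#' @return matrix of Pearson correlations, traits x retained axes.
#' @export
trait_axis_correlations <- function(space, tm) {
  stopifnot(inherits(space, "functional_space"), inherits(tm, "trait_matrix"))
  if (!identical(rownames(tm$traits), rownames(space$coordinates))) {
    stop("individuals in the trait matrix and functional space do not match")
  }
  cor(tm$traits, space$coordinates)
}

#' @export
print.functional_space <- function(x, ...) {
  cat("Functional space:", x$retained_axes, "retained axes (eigenvalue > 1) of",
      length(x$eigenvalues), "\n")
  ev <- x$eigenvalues[seq_len(x$retained_axes)]
  cat(sprintf(
    "  %s: eigenvalue %.3f, %.2f%% of variance\n",
    paste0("PC", seq_along(ev)), ev, x$explained_pct[seq_along(ev)]
  ), sep = "")
  invisible(x)
}
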