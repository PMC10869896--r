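#' Functional identity: (abundance-weighted) mean position in trait space
#'
#' @param coords numeric matrix, individuals x axes.
#' @param weights optional nonnegative weights, one per individual; unit
#'   weights by default so every individual counts once.
#' @return named numeric vector, one mean per axis.
#' @export
fide <- function(coords, weights = NULL) {
  coords <- as.matrix(coords)
  if (is.null(weights)) weights <- rep(1, nrow(coords))
  if (length(weights) != nrow(coords)) stop("one weight per individual required")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) <= 0) stop("weights must not all be zero")
  drop(crossprod(coords, weights) / sum(weights))
}

#' Functional richness of a group as a percentage of the pooled hull
#'
#' The convex-hull volume of the group's points divided by the convex-hull
#' volume of all individuals pooled, times 100.  Expressing group richness
#' relative to the population's occupied space is the standard functional
#' space convention; the absolute volume is available via [hull_volume()].
#'
#' @param group_points points of the focal group (rows x axes).
#' @param pooled_points points of all individuals; its hull must have
#'   positive volume.
#' @return percentage in `[0, 100]`.
#' @export
fric <- function(group_points, pooled_points) {
  vp <- hull_volume(pooled_points)
  if (vp <= 0) stop("pooled convex hull is degenerate (zero volume)")
  100 * hull_volume(group_points) / vp
}

#' Functional overlap of two groups (Jaccard ratio of hull volumes)
#'
#' `FOve = V(A niche B) / (V(A) + V(B) - V(A niche B))`: the volume of the
#' intersection of the two groups' convex hulls over the volume of their
#' union (by inclusion-exclusion).  Lies in `[0, 1]`; 1 for identical
#' hulls, 0 for disjoint ones, and exactly symmetric in its arguments.
#'
#' @param a,b point matrices of the two groups; both hulls must have
#'   positive volume.
#' @return overlap ratio in `[0, 1]`.
#' @examples
#' s1 <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
#' fove(s1, s1 + 1) # 1/7
#' @export
fove <- function(a, b) {
  va <- hull_volume(a)
  vb <- hull_volume(b)
  if (va <= 0 || vb <= 0) stop("zero-volume input hull; FOve is undefined")
  vi <- hull_intersection_volume(a, b)
  vu <- va + vb - vi
  max(0, min(1, vi / vu))
}

#' One-way PERMANOVA on functional-space coordinates
#'
#' Permutational multivariate analysis of variance on Euclidean distances:
#' the observed pseudo-F, `(SS_between / (g - 1)) / (SS_within / (n - g))`,
#' is compared with its distribution under random permutation of the group
#' labels.  The p-value uses the `(1 + exceedances) / (1 + n_perm)`
#' convention and is therefore never exactly zero.
#'
#' @param coords numeric matrix of coordinates (individuals x axes).
#' @param labels group labels, one per row of `coords`; at least two
#'   groups, each with at least two members.
#' @param n_perm number of label permutations (default 999).
#' @param seed optional integer seed for reproducible permutations.
#' @return list with `pseudo_F`, `p`, `n_perm`, and the degrees of freedom
#'   `df_between`, `df_within`.
#' @export
permanova <- function(coords, labels, n_perm = 999, seed = NULL) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  n <- nrow(coords)
  if (length(labels) != n) stop("one label per row of coords required")
  cnt <- table(labels)
  if (length(cnt) < 2) stop("need at least two groups")
  if (any(cnt < 2)) {
    stop("group(s) with fewer than 2 members: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  }
  if (n_perm < 0) stop("n_perm must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  d2 <- as.matrix(dist(coords))^2
  ss_total <- sum(d2) / (2 * n)
  g <- length(cnt)
  lab_int <- as.integer(factor(labels))
  ng <- tabulate(lab_int, g)   # invariant under permutation of labels
  f_stat <- function(lab) {
    m <- rowsum(d2, lab)
    s <- rowsum(t(m), lab)
    ss_w <- sum(diag(s) / (2 * ng))
    ss_b <- ss_total - ss_w
    (ss_b / (g - 1)) / (ss_w / (n - g))
  }
  f_obs <- f_stat(lab_int)
  if (n_perm == 0) {
    return(list(pseudo_F = f_obs, p = NA_real_, n_perm = 0L,
                df_between = g - 1L, df_within = n - g))
  }
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (f_stat(lab_int[sample.int(n)]) >= f_obs) exceed <- exceed + 1L
  }
  list(
    pseudo_F = f_obs,
    p = (1 + exceed) / (1 + n_perm),
    n_perm = as.integer(n_perm),
    df_between = g - 1L,
    df_within = n - g
  )
}

#' Subsample bootstrap confidence intervals for FRic or FOve
#'
#' Repeatedly subsamples `subsample_n` individuals (without replacement by
#' default) from each eligible group, recomputes the metric, and reports
#' the 2.5th and 97.5th percentiles across replicates.  Groups whose size
#' is at or below `subsample_n` cannot be strictly subsampled and are
#' skipped with a notice (their interval is reported as `NA`), mirroring
#' the dashes such studies print for the minimum-size group.
#'
#' For `metric = "fric"` the denominator is the fixed pooled hull of all
#' individuals; for `metric = "fove"` both groups of each eligible pair are
#' subsampled.
#'
#' @param points_by_group named list of coordinate matrices, one per group.
#' @param metric `"fric"` or `"fove"`.
#' @param subsample_n number of individuals drawn per group.
#' @param n_reps number of bootstrap replicates (default 10000).
#' @param seed optional integer seed.
#' @param replace draw with replacement instead of subsampling.
#' @param keep_reps also return the replicate values (attribute `reps`).
#' @param pooled_volume precomputed convex-hull volume of all points
#'   pooled (the fixed FRic denominator); computed internally when `NULL`.
#' @return data frame with one row per group (fric) or unordered pair
#'   (fove): `group_or_pair`, `subsample_n`, `n_reps`, `ci_low`, `ci_high`.
#' @export
bootstrap_metric <- function(points_by_group, metric = c("fric", "fove"),
                             subsample_n, n_reps = 10000, seed = NULL,
                             replace = FALSE, keep_reps = FALSE,
                             pooled_volume = NULL) {
  metric <- match.arg(metric)
  stopifnot(is.list(points_by_group), length(names(points_by_group)) > 0)
  if (n_reps < 1) stop("n_reps must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  sizes <- vapply(points_by_group, nrow, integer(1))
  eligible <- names(sizes)[if (replace) sizes >= subsample_n else sizes > subsample_n]
  skipped <- setdiff(names(sizes), eligible)
  if (length(skipped)) {
    message(
      "bootstrap_metric: group(s) at or below subsample_n skipped: ",
      paste(skipped, collapse = ", ")
    )
  }
  v_pool <- if (is.null(pooled_volume)) {
    hull_volume(do.call(rbind, points_by_group))
  } else {
    pooled_volume
  }
  if (v_pool <= 0) stop("pooled convex hull is degenerate (zero volume)")
  draw <- function(m) {
    m[sample.int(nrow(m), subsample_n, replace = replace), , drop = FALSE]
  }
  rows <- list()
  reps_out <- list()
  if (metric == "fric") {
    for (gname in names(sizes)) {
      if (!gname %in% eligible) {
        rows[[gname]] <- data.frame(
          group_or_pair = gname, subsample_n = subsample_n,
          n_reps = NA_integer_, ci_low = NA_real_, ci_high = NA_real_
        )
        next
      }
      vals <- vapply(
        seq_len(n_reps),
        function(i) 100 * hull_volume(draw(points_by_group[[gname]])) / v_pool,
        numeric(1)
      )
      qs <- quantile(vals, c(0.025, 0.975), names = FALSE)
      rows[[gname]] <- data.frame(
        group_or_pair = gname, subsample_n = subsample_n,
        n_reps = as.integer(n_reps), ci_low = qs[1], ci_high = qs[2]
      )
      if (keep_reps) reps_out[[gname]] <- vals
    }
  } else {
    gn <- names(sizes)
    for (i in seq_along(gn)) {
      for (j in seq_along(gn)) {
        if (j <= i) next
        pair <- paste(gn[i], gn[j], sep = ":")
        if (!(gn[i] %in% eligible && gn[j] %in% eligible)) {
          rows[[pair]] <- data.frame(
            group_or_pair = pair, subsample_n = subsample_n,
            n_reps = NA_integer_, ci_low = NA_real_, ci_high = NA_real_
          )
          next
        }
        vals <- vapply(
          seq_len(n_reps),
          function(r) {
            a <- draw(points_by_group[[gn[i]]])
            b <- draw(points_by_group[[gn[j]]])
            va <- hull_volume(a)
            vb <- hull_volume(b)
            if (va <= 0 || vb <= 0) return(0)
            fove(a, b)
          },
          numeric(1)
        )
        qs <- quantile(vals, c(0.025, 0.975), names = FALSE)
        rows[[pair]] <- data.frame(
          group_or_pair = pair, subsample_n = subsample_n,
          n_reps = as.integer(n_reps), ci_low = qs[1], ci_high = qs[2]
        )
        if (keep_reps) reps_out[[pair]] <- vals
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_reps) attr(out, "reps") <- reps_out
  out
}

#' All niche metrics for a functional space
#'
#' Convenience wrapper computing, for every group in the space: functional
#' identity ([fide()]), functional richness as a share of the pooled hull
#' ([fric()]), all pairwise functional overlaps ([fove()]) and a PERMANOVA
#' on group positions ([permanova()]).  Groups whose hulls are degenerate
#' in the retained space get `FRic = 0` and their overlaps are `NA`.
#'
#' @param space a `functional_space` from [build_space()].
#' @param weights optional abundance weights for [fide()].
#' @param n_perm permutations for the PERMANOVA.
#' @param seed optional integer seed for the PERMANOVA.
#' @return list with elements `fide` (matrix group x axes), `fric` (named
#'   vector, %), `fove` (data frame of unordered pairs), `permanova`.
#' @export
niche_metrics <- function(space, weights = NULL, n_perm = 999, seed = NULL) {
  stopifnot(inherits(space, "functional_space"))
  coords <- space$coordinates
  groups <- space$meta$group
  by_group <- split_coords(coords, groups)
  fide_m <- t(vapply(
    names(by_group),
    function(g) {
      w <- if (is.null(weights)) NULL else weights[groups == g]
      fide(by_group[[g]], w)
    },
    numeric(ncol(coords))
  ))
  v_pool <- hull_volume(coords)
  if (v_pool <= 0) stop("pooled convex hull is degenerate (zero volume)")
  vols <- vapply(by_group, hull_volume, numeric(1))
  fric_v <- 100 * vols / v_pool
  gn <- names(by_group)
  pairs <- if (length(gn) >= 2) combn(gn, 2) else matrix(character(0), 2, 0)
  fove_df <- data.frame(
    group_a = pairs[1, ], group_b = pairs[2, ],
    fove = vapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]
      b <- pairs[2, k]
      if (vols[a] <= 0 || vols[b] <= 0) return(NA_real_)
      fove(by_group[[a]], by_group[[b]])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  perm <- permanova(coords, groups, n_perm = n_perm, seed = seed)
  list(fide = fide_m, fric = fric_v, fove = fove_df, permanova = perm)
}

split_coords <- function(coords, groups) {
  lapply(split(seq_len(nrow(coords)), groups), function(i) {
    coords[i, , drop = FALSE]
  })
}
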