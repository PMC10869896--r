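# fixtures and independent oracles shared across the test files; all data
# is generated in code at test time

unit_square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
square02 <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
simplex3 <- rbind(c(0, 0, 0), diag(3))

# Monte-Carlo rejection estimate of a hull volume (and optionally of the
# intersection with a second hull), with its standard error
mc_hull_volume <- function(points, n_samples = 1e6, other = NULL, chunk = 2e5) {
  d <- ncol(points)
  all_pts <- rbind(points, other)
  lo <- apply(all_pts, 2, min)
  hi <- apply(all_pts, 2, max)
  vbox <- prod(hi - lo)
  h1 <- hull_hrep(points)
  h2 <- if (!is.null(other)) hull_hrep(other) else NULL
  hit1 <- 0
  hit12 <- 0
  done <- 0
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    x <- vapply(seq_len(d), function(j) runif(m, lo[j], hi[j]), numeric(m))
    in1 <- points_in_hull(x, h1)
    hit1 <- hit1 + sum(in1)
    if (!is.null(h2)) hit12 <- hit12 + sum(in1 & points_in_hull(x, h2))
    done <- done + m
  }
  p1 <- hit1 / n_samples
  out <- list(
    volume = p1 * vbox,
    se = vbox * sqrt(p1 * (1 - p1) / n_samples)
  )
  if (!is.null(h2)) {
    p12 <- hit12 / n_samples
    out$intersection <- p12 * vbox
    out$intersection_se <- vbox * sqrt(p12 * (1 - p12) / n_samples)
  }
  out
}

# random rigid rotation matrix in d dimensions
random_rotation <- function(d) {
  q <- qr.Q(qr(matrix(rnorm(d * d), d)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# small hand-built morphometric table
make_records <- function(n = 12, seed = 1) {
  set.seed(seed)
  data.frame(
    id = sprintf("L%02d", seq_len(n)),
    transect = sprintf("T%02d", rep_len(1:3, n)),
    group = rep_len(c("juvenile", "male", "female"), n),
    M = runif(n, 2, 8),
    IO = runif(n, 4, 6), MW = runif(n, 6, 8), HL = runif(n, 11, 13),
    HH = runif(n, 6, 8), HW = runif(n, 8, 10), FLL = runif(n, 20, 26),
    HLL = runif(n, 30, 40), TAL = runif(n, 35, 60), AMW = runif(n, 12, 18),
    SVL = runif(n, 45, 65),
    stringsAsFactors = FALSE
  )
}

# independent brute-force hierarchical partitioning oracle: Shapley-weight
# form, enumerating subsets with combn (a different code path from the
# package's level-averaging)
hp_bruteforce <- function(gof_fun, p) {
  I <- numeric(p)
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    for (sz in 0:(p - 1)) {
      subs <- if (sz == 0) list(integer(0)) else
        asplit(combn(others, sz), 2)
      w <- factorial(sz) * factorial(p - sz - 1) / factorial(p)
      for (s in subs) {
        I[j] <- I[j] + w * (gof_fun(sort(c(s, j))) - gof_fun(sort(s)))
      }
    }
  }
  I
}

# gaussian clusters for PERMANOVA simulations
make_clusters <- function(n_per_group, d, shift = 0, g = 3) {
  x <- matrix(rnorm(n_per_group * g * d), ncol = d)
  labels <- rep(paste0("g", seq_len(g)), each = n_per_group)
  for (i in seq_len(g)) {
    x[labels == paste0("g", i), 1] <-
      x[labels == paste0("g", i), 1] + (i - 1) * shift
  }
  list(coords = x, labels = labels)
}
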