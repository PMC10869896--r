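test_that("hull volume matches analytic values", {
  expect_equal(hull_volume(unit_square), 1, tolerance = 1e-12)
  expect_equal(hull_volume(simplex3), 1 / 6, tolerance = 1e-12)
  # interior points change nothing
  expect_equal(hull_volume(rbind(unit_square, c(0.5, 0.5), c(0.2, 0.8))), 1,
               tolerance = 1e-12)
  # 4-cube from its corners
  corners4 <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))
  expect_equal(hull_volume(corners4), 1, tolerance = 1e-9)
})

test_that("degenerate point sets have zero volume", {
  expect_equal(hull_volume(rbind(c(0, 0), c(1, 1))), 0)            # too few
  expect_equal(hull_volume(cbind(0:5, 2 * (0:5))), 0)              # collinear
  flat <- cbind(matrix(rnorm(20), 10, 2), 1)                       # planar in 3D
  expect_equal(hull_volume(flat), 0)
})

test_that("invalid input is rejected", {
  expect_error(hull_volume(matrix(1:6, ncol = 1)), "2 columns")
  expect_error(hull_volume(rbind(c(0, NA), c(1, 1), c(0, 1))), "finite")
  expect_error(hull_intersection_volume(unit_square, simplex3), "dimension")
  expect_error(
    hull_intersection_volume(cbind(0:5, 2 * (0:5)), unit_square),
    "degenerate"
  )
})

test_that("hull volume agrees with a Monte-Carlo oracle in 2-4 dimensions", {
  set.seed(101)
  for (d in 2:4) {
    x <- matrix(rnorm(30 * d), ncol = d)
    mc <- mc_hull_volume(x, n_samples = 2e5)
    expect_lt(abs(hull_volume(x) - mc$volume), 3 * mc$se)
  }
})

test_that("intersection volume is exact on analytic overlaps", {
  expect_equal(hull_intersection_volume(square02, square02 + 1), 1,
               tolerance = 1e-12)
  expect_equal(hull_intersection_volume(square02, square02), 4,
               tolerance = 1e-12)
  # nested: small square inside big square
  small <- unit_square * 0.5 + 0.25
  expect_equal(hull_intersection_volume(square02, small), 0.25,
               tolerance = 1e-12)
  # disjoint
  expect_equal(hull_intersection_volume(square02, square02 + 5), 0)
  # 3D cubes offset by half an edge
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(hull_intersection_volume(cube, cube + 0.5), 0.125,
               tolerance = 1e-10)
})

test_that("intersection obeys set bounds and matches Monte Carlo", {
  set.seed(202)
  for (d in 2:4) {
    a <- matrix(rnorm(25 * d), ncol = d)
    b <- matrix(rnorm(25 * d), ncol = d) + 0.5
    vi <- hull_intersection_volume(a, b)
    expect_gte(vi, 0)
    expect_lte(vi, min(hull_volume(a), hull_volume(b)) + 1e-9)
    mc <- mc_hull_volume(a, n_samples = 2e5, other = b)
    expect_lt(abs(vi - mc$intersection), 3 * mc$intersection_se + 1e-6)
  }
})

test_that("hull metrics are invariant under rigid motions", {
  set.seed(303)
  x <- matrix(rnorm(20 * 3), ncol = 3)
  y <- matrix(rnorm(20 * 3), ncol = 3) + 0.3
  v0 <- hull_volume(x)
  i0 <- hull_intersection_volume(x, y)
  for (rep in 1:3) {
    q <- random_rotation(3)
    shift <- rnorm(3)
    xr <- sweep(x %*% q, 2, shift, "+")
    yr <- sweep(y %*% q, 2, shift, "+")
    expect_equal(hull_volume(xr), v0, tolerance = 1e-9)
    expect_equal(hull_intersection_volume(xr, yr), i0, tolerance = 1e-8)
  }
})

test_that("hull H-representation contains exactly the hull points", {
  set.seed(404)
  x <- matrix(rnorm(40 * 3), ncol = 3)
  h <- hull_hrep(x)
  expect_true(all(points_in_hull(x, h)))
  # points far outside are excluded
  expect_false(any(points_in_hull(x + 100, h)))
  # centroid is inside
  expect_true(points_in_hull(t(colMeans(x)), h))
})

test_that("hull vertices are the minimal generating subset", {
  set.seed(505)
  x <- matrix(rnorm(40 * 3), ncol = 3)
  v <- hull_vertices(x)
  expect_true(length(v) >= 4)
  expect_equal(hull_volume(x[v, , drop = FALSE]), hull_volume(x),
               tolerance = 1e-10)
  # non-vertex points sit inside the vertex hull
  inside <- setdiff(seq_len(nrow(x)), v)
  if (length(inside)) {
    expect_true(all(points_in_hull(x[inside, , drop = FALSE],
                                   x[v, , drop = FALSE])))
  }
})

test_that("subset hulls never exceed superset hulls", {
  set.seed(606)
  x <- matrix(rnorm(30 * 4), ncol = 4)
  for (rep in 1:5) {
    idx <- sample(30, 15)
    expect_lte(hull_volume(x[idx, ]), hull_volume(x) + 1e-12)
  }
})
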