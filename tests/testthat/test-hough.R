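test_that("parameter grids discretize as specified", {
  g <- parameter_grid(c(0.1, -0.5), c(0.7, 0.5), 0.02)
  expect_identical(g$ncell, c(30L, 50L))
  expect_error(parameter_grid(c(0, 0), c(1, -1)), "upper > lower")
  expect_error(parameter_grid(c(0, 0), c(1, 1), side = 0), "side")
})

test_that("vote agrees exactly with the brute-force oracle (canal)", {
  set.seed(11)
  p <- three_convexity_params(0.35, 0.15)
  pts <- sample_curve(p, 120)
  pts <- pts + matrix(rnorm(240, sd = 0.004), ncol = 2)  # off-curve jitter
  pts <- rbind(pts, cbind(runif(80, -0.6, 0.6), runif(80, -0.6, 0.6)))
  g <- parameter_grid(c(0.1, -0.5), c(0.7, 0.5), 0.02)   # 1500 cells
  acc <- vote(edge_point_set(pts), g, "three_convexity")
  expect_identical(acc$counts, oracle_vote_canal(pts, g))
})

test_that("vote agrees exactly with the brute-force oracle (ellipse)", {
  set.seed(12)
  e <- ellipse_params(0.3, 0.18, 0.02, -0.04)
  pts <- sample_curve(e, 140)
  pts <- pts + matrix(rnorm(280, sd = 0.004), ncol = 2)
  pts <- rbind(pts, cbind(runif(60, -0.5, 0.5), runif(60, -0.5, 0.5)))
  g <- parameter_grid(c(0.2, 0.08, -0.1, -0.1), c(0.4, 0.28, 0.1, 0.1),
                      0.02)                               # 10^4 cells
  acc <- vote(edge_point_set(pts), g, "ellipse")
  expect_identical(acc$counts, oracle_vote_ellipse(pts, g))
})

test_that("a single on-curve point votes for its cell; empty sets do not", {
  # one-cell grid centered at (a, b, c, d) and the point at its x-vertex
  g1 <- parameter_grid(c(0.29, 0.17, 0.01, -0.05), c(0.31, 0.19, 0.03, -0.03),
                       0.02)
  acc <- vote(edge_point_set(matrix(c(0.02 + 0.30, -0.04), 1)), g1, "ellipse")
  expect_identical(as.integer(acc$counts), 1L)
  empty <- vote(edge_point_set(matrix(numeric(0), ncol = 2)), g1, "ellipse")
  expect_true(all(empty$counts == 0L))
  expect_error(find_peak(empty), class = "no_curve_found")
  g2 <- parameter_grid(c(0.1, -0.5), c(0.7, 0.5))
  expect_error(vote(edge_point_set(matrix(1, 1, 2)), g2, "ellipse"),
               "dimensionality")
})

test_that("adding edge points never decreases any accumulator cell", {
  set.seed(13)
  g <- parameter_grid(c(0.1, -0.5), c(0.7, 0.5), 0.02)
  pts1 <- cbind(runif(60, -0.6, 0.6), runif(60, -0.6, 0.6))
  pts2 <- rbind(pts1, cbind(runif(30, -0.6, 0.6), runif(30, -0.6, 0.6)))
  a1 <- vote(edge_point_set(pts1), g, "three_convexity")
  a2 <- vote(edge_point_set(pts2), g, "three_convexity")
  expect_true(all(a2$counts >= a1$counts))
})

test_that("find_peak breaks ties at the lexicographically lowest index", {
  g <- parameter_grid(c(0, 0), c(0.2, 0.2), 0.02)
  counts <- matrix(0L, 10, 10)
  counts[3, 4] <- 7L
  counts[2, 7] <- 7L
  acc <- structure(list(counts = counts, grid = g,
                        family = "three_convexity", n_points = 14L),
                   class = "accumulator")
  pk <- find_peak(acc)
  expect_identical(pk$index, c(2L, 7L))
  expect_identical(pk$votes, 7L)
  counts2 <- counts; counts2[2, 7] <- 0L
  acc$counts <- counts2
  expect_identical(find_peak(acc)$index, c(3L, 4L))
})

test_that("noise-free curves on cell centers are recovered exactly", {
  # canal: a = 0.35, b = 0.15 are cell centers of the default grid
  g <- parameter_grid(c(0.1, -0.5), c(0.7, 0.5), 0.02)
  p <- three_convexity_params(0.35, 0.15)
  pts <- edge_point_set(sample_curve(p, 200))
  pk <- find_peak(vote(pts, g, "three_convexity"), pts)
  expect_equal(pk$params, c(0.35, 0.15), tolerance = 1e-12)

  # ellipse on cell centers of its grid
  ge <- parameter_grid(c(0.2, 0.08, -0.1, -0.1), c(0.4, 0.28, 0.1, 0.1), 0.02)
  e <- ellipse_params(0.31, 0.17, 0.01, -0.05)
  ptse <- edge_point_set(sample_curve(e, 200))
  pke <- find_peak(vote(ptse, ge, "ellipse"), ptse)
  expect_equal(pke$params, c(0.31, 0.17, 0.01, -0.05), tolerance = 1e-12)
})

test_that("off-center parameters are recovered within one cell", {
  g <- parameter_grid(c(0.1, -0.5), c(0.7, 0.5), 0.02)
  p <- three_convexity_params(0.352, 0.143)
  pts <- edge_point_set(sample_curve(p, 200))
  pk <- find_peak(vote(pts, g, "three_convexity"), pts)
  expect_lte(max(abs(pk$params - c(0.352, 0.143))), 0.02 + 1e-12)

  ge <- parameter_grid(c(0.2, 0.08, -0.1, -0.1), c(0.4, 0.28, 0.1, 0.1), 0.02)
  e <- ellipse_params(0.30, 0.18, 0.02, -0.04)
  ptse <- edge_point_set(sample_curve(e, 200))
  pke <- find_peak(vote(ptse, ge, "ellipse"), ptse)
  expect_lte(max(abs(pke$params - c(0.30, 0.18, 0.02, -0.04))), 0.02 + 1e-12)
})

test_that("peaks survive 20% uniform clutter within one cell", {
  set.seed(21)
  g <- parameter_grid(c(0.1, -0.5), c(0.7, 0.5), 0.02)
  p <- three_convexity_params(0.35, 0.15)
  pts <- rbind(sample_curve(p, 150),
               cbind(runif(30, -0.6, 0.6), runif(30, -0.6, 0.6)))
  eps <- edge_point_set(pts)
  pk <- find_peak(vote(eps, g, "three_convexity"), eps)
  expect_lte(max(abs(pk$params - c(0.35, 0.15))), 0.02 + 1e-12)

  ge <- parameter_grid(c(0.2, 0.08, -0.1, -0.1), c(0.4, 0.28, 0.1, 0.1), 0.02)
  e <- ellipse_params(0.31, 0.17, 0.01, -0.05)
  ptse <- rbind(sample_curve(e, 150),
                cbind(runif(30, -0.4, 0.4), runif(30, -0.4, 0.4)))
  epse <- edge_point_set(ptse)
  pke <- find_peak(vote(epse, ge, "ellipse"), epse)
  expect_lte(max(abs(pke$params - c(0.31, 0.17, 0.01, -0.05))), 0.02 + 1e-12)
})

test_that("detectors enforce minimum evidence", {
  g <- parameter_grid(c(0.1, -0.5), c(0.7, 0.5), 0.02)
  expect_error(detect_canal(edge_point_set(matrix(1, 3, 2)), g),
               class = "no_curve_found")
  ge <- parameter_grid(c(0.02, 0.02, -0.1, -0.1), c(0.4, 0.4, 0.1, 0.1), 0.02)
  expect_error(detect_cord(edge_point_set(matrix(numeric(0), ncol = 2)), ge),
               class = "no_curve_found")
  # circular canal: recovered b within one cell of 0
  circ <- three_convexity_params(0.35, 0)
  fit <- detect_canal(edge_point_set(sample_curve(circ, 150)), g)
  expect_lte(abs(fit$params$b), 0.02)
  # circular cord: recovered semi-axes within one cell of each other
  ce <- ellipse_params(0.11, 0.11, 0.01, -0.01)
  fite <- detect_cord(edge_point_set(sample_curve(ce, 150)), ge)
  expect_lte(abs(fite$params$a - fite$params$b), 0.02 + 1e-12)
})
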