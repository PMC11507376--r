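# Density-grid reading, smoothing and sampling.

test_that("MRC round trip preserves a 1x1x1 map and geometry", {
  f <- tempfile(fileext = ".mrc")
  g <- densityGrid(array(7.0, c(1, 1, 1)), voxelSize = 0.86,
                   origin = c(1.5, -2, 3))
  writeMRC(g, f)
  g2 <- readMRC(f)
  expect_equal(gridDims(g2), c(1L, 1L, 1L))
  expect_equal(as.numeric(gridValues(g2)), 7.0)
  expect_equal(voxelSize(g2), rep(0.86, 3), tolerance = 1e-6)
  expect_equal(gridOrigin(g2), c(1.5, -2, 3), tolerance = 1e-6)
  expect_false(isSmoothed(g2))
})

test_that("axis-permuted MRC files are restored to canonical order", {
  set.seed(11)
  # integer values are exactly representable in 32-bit float
  vals <- array(as.numeric(sample(0:100, 8 * 6 * 4, TRUE)), c(8, 6, 4))
  g <- densityGrid(vals, voxelSize = c(1, 1.5, 2), origin = c(-3, 4, 5))
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(2, 1, 3), c(3, 2, 1))
  for (p in perms) {
    f <- tempfile(fileext = ".mrc")
    writeMRC(g, f, axisOrder = p)
    g2 <- readMRC(f)
    # oracle: explicit index permutation of the file-order array
    fileArr <- aperm(vals, p)
    expect_identical(dim(fileArr)[order(p)], dim(gridValues(g2)))
    expect_equal(gridValues(g2), vals, tolerance = 0)
    expect_equal(gridOrigin(g2), c(-3, 4, 5), tolerance = 1e-6)
    unlink(f)
  }
})

test_that("start-index origin fallback is honored when ORIGIN is zero", {
  f <- tempfile(fileext = ".mrc")
  g <- densityGrid(array(1.0, c(2, 2, 2)), voxelSize = 2, origin = c(0, 0, 0))
  writeMRC(g, f)
  # patch NXSTART/NYSTART/NZSTART (words 5-7) in the written header
  con <- file(f, "r+b")
  seek(con, 16, rw = "write")
  writeBin(c(3L, -1L, 2L), con, size = 4)
  close(con)
  g2 <- readMRC(f)
  expect_equal(gridOrigin(g2), c(3, -1, 2) * 2, tolerance = 1e-6)
})

test_that("corrupt headers are rejected with the offending field named", {
  f <- tempfile(fileext = ".mrc")
  writeMRC(densityGrid(array(0, c(2, 2, 2))), f)
  con <- file(f, "r+b")
  seek(con, 64, rw = "write")          # MAPC..MAPS words
  writeBin(c(1L, 1L, 3L), con, size = 4)
  close(con)
  expect_error(readMRC(f), "MAPC")
  expect_error(readMRC(tempfile()), "not found")
})

test_that("smoothing matches the brute-force truncated mean exhaustively", {
  set.seed(42)
  for (d in list(c(7, 7, 7), c(9, 9, 9), c(5, 8, 3))) {
    vals <- array(rnorm(prod(d)), d)
    g <- smoothMap(densityGrid(vals), window = 5)
    expect_equal(gridValues(g), bruteSmooth(vals, 5), tolerance = 1e-12)
    expect_true(isSmoothed(g))
  }
  # a lone spike spreads uniformly over its full window cube
  spike <- array(0, c(11, 11, 11))
  spike[6, 6, 6] <- 125
  s <- gridValues(smoothMap(densityGrid(spike), 5))
  expect_equal(s[4:8, 4:8, 4:8], array(1, c(5, 5, 5)), tolerance = 1e-12)
  expect_equal(s[3, 6, 6], 0)
})

test_that("smoothing keeps constants, bounds, window-1 identity and affinity", {
  set.seed(1)
  vals <- array(rnorm(6 * 7 * 8), c(6, 7, 8))
  g <- densityGrid(vals)
  expect_equal(gridValues(smoothMap(g, 1)), vals)      # window 1 = identity
  cg <- densityGrid(array(4.2, c(5, 5, 5)))
  expect_equal(gridValues(smoothMap(cg, 5)), array(4.2, c(5, 5, 5)))
  s <- gridValues(smoothMap(g, 5))
  expect_gte(min(s), min(vals))
  expect_lte(max(s), max(vals))
  # commutes with affine value scaling
  a <- 2.5; b <- -1.25
  s2 <- gridValues(smoothMap(densityGrid(a * vals + b), 5))
  expect_equal(s2, a * s + b, tolerance = 1e-10)
})

test_that("even or non-positive windows and re-smoothing are refused", {
  g <- densityGrid(array(0, c(4, 4, 4)))
  expect_error(smoothMap(g, 4), "odd")
  expect_error(smoothMap(g, 0), "odd")
  expect_error(smoothMap(smoothMap(g, 3), 3), "already smoothed")
})

test_that("nearest-voxel sampling matches index arithmetic on random points", {
  set.seed(7)
  d <- c(9, 8, 7)
  vals <- array(rnorm(prod(d)), d)
  voxel <- c(0.9, 1.1, 0.7)
  origin <- c(-2, 3, 1)
  g <- densityGrid(vals, voxelSize = voxel, origin = origin)
  lo <- origin - voxel / 2
  hi <- origin + (d - 0.5) * voxel
  pts <- cbind(runif(1000, lo[1], hi[1]), runif(1000, lo[2], hi[2]),
               runif(1000, lo[3], hi[3]))
  got <- sampleAt(g, pts)
  want <- apply(pts, 1, function(p) bruteNearest(vals, voxel, origin, p))
  expect_equal(as.numeric(got), want)
  expect_false(any(attr(got, "outOfBounds")))
  # exact cell centers return the cell value
  expect_equal(as.numeric(sampleAt(g, origin + (c(3, 4, 5) - 1) * voxel)),
               vals[3, 4, 5])
})

test_that("out-of-bounds points sample 0.0 and are tallied", {
  g <- densityGrid(array(5, c(3, 3, 3)))
  v <- sampleAt(g, rbind(c(1, 1, 1), c(100, 0, 0)))
  expect_equal(as.numeric(v), c(5, 0))
  expect_equal(attr(v, "outOfBounds"), c(FALSE, TRUE))
  expect_error(sampleAt(g, c(NA, 0, 0)), "finite")
})

test_that("trilinear sampling interpolates linear fields exactly", {
  # value = 2x + 3y - z sampled on cell centers is reproduced in the interior
  d <- c(6, 6, 6)
  idx <- expand.grid(i = 1:6, j = 1:6, k = 1:6)
  vals <- array(2 * idx$i + 3 * idx$j - idx$k, d)
  g <- densityGrid(vals)                     # voxel 1, origin 0
  pts <- cbind(runif(50, 1, 4), runif(50, 1, 4), runif(50, 1, 4))
  got <- sampleAt(g, pts, mode = "trilinear")
  want <- 2 * (pts[, 1] + 1) + 3 * (pts[, 2] + 1) - (pts[, 3] + 1)
  expect_equal(as.numeric(got), want, tolerance = 1e-10)
})
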