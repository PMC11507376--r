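# Kabsch superposition and common-frame alignment.

test_that("identical coordinate sets give the identity transform", {
  set.seed(1)
  p <- matrix(rnorm(30), 10)
  tr <- kabsch(p, p)
  expect_equal(tr@rotation, diag(3), tolerance = 1e-10)
  expect_equal(tr@translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(tr@fitRMSD, 0, tolerance = 1e-10)
  expect_equal(tr@nFitAtoms, 10L)
})

test_that("known rigid transforms are recovered over 100 seeds", {
  worst <- 0
  for (s in 1:100) {
    set.seed(s)
    p <- matrix(rnorm(30, sd = 5), 10)
    R <- randomRotation()
    t3 <- rnorm(3, sd = 10)
    q <- sweep(p %*% t(R), 2, t3, "+")
    tr <- kabsch(p, q)
    expect_equal(tr@rotation, R, tolerance = 1e-8)
    expect_equal(tr@translation, t3, tolerance = 1e-7)
    worst <- max(worst, tr@fitRMSD)
  }
  expect_lt(worst, 1e-9)
})

test_that("the fitted rotation is globally optimal among sampled rotations", {
  set.seed(4)
  p <- matrix(rnorm(12), 4)
  q <- matrix(rnorm(12), 4) * 0.5 + p     # noisy partner
  best <- kabsch(p, q)@fitRMSD

  rmsdGiven <- function(R) {
    # optimal translation for a fixed rotation aligns the centroids
    moved <- p %*% t(R)
    moved <- sweep(moved, 2, colMeans(q) - colMeans(moved), "+")
    sqrt(mean(rowSums((moved - q)^2)))
  }
  # coarse Euler grid plus random rotations; Kabsch must beat them all
  angles <- seq(0, 350, by = 10) * pi / 180
  betas <- seq(0, 180, by = 10) * pi / 180
  gridMin <- Inf
  for (a in angles) for (b in betas) for (g in angles[seq(1, 36, 3)]) {
    Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
    Rz2 <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3)
    gridMin <- min(gridMin, rmsdGiven(Rz %*% Ry %*% Rz2))
  }
  randMin <- min(vapply(1:2000, function(i) rmsdGiven(randomRotation()),
                        numeric(1)))
  expect_lte(best, gridMin + 1e-12)
  expect_lte(best, randMin + 1e-12)
})

test_that("degenerate inputs are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch(line, line + 1), "collinear")
  expect_error(kabsch(matrix(rnorm(6), 2), matrix(rnorm(6), 2)), "at least 3")
  expect_error(kabsch(matrix(rnorm(9), 3), matrix(rnorm(12), 4)),
               "differ in length")
})

test_that("reflections are excluded: mirrored sets never yield det -1", {
  set.seed(9)
  p <- matrix(rnorm(30), 10)
  q <- p
  q[, 1] <- -q[, 1]                      # mirror image
  tr <- kabsch(p, q)
  expect_equal(det(tr@rotation), 1, tolerance = 1e-10)
  expect_gt(tr@fitRMSD, 0.1)             # cannot fit a mirror with a rotation
})

test_that("a displaced complex is aligned back onto the reference exactly", {
  spec <- syntheticSpec(seed = 12)
  cx <- makeToyComplex(spec)
  ref <- anchorAsReference(cx)

  # already in frame: identity transform, coordinates unchanged
  al0 <- alignComplexToReference(cx, ref, "C")
  expect_equal(al0@meta$alignment$fitRMSD, 0, tolerance = 1e-6)
  expect_equal(coords(mobileModel(al0)), coords(mobileModel(cx)),
               tolerance = 1e-6)

  # known displacement is undone to 1e-6 A
  known <- rigidTransform(randomRotation(), c(8, -5, 12))
  moved <- applyTransform(cx, known)
  back <- alignComplexToReference(moved, ref, "C")
  expect_lt(max(abs(coords(mobileModel(back)) - coords(mobileModel(cx)))),
            1e-6)
  expect_lt(max(abs(coords(anchorModel(back)) - coords(anchorModel(cx)))),
            1e-6)
  expect_equal(cofactorDistance(back), cofactorDistance(cx), tolerance = 1e-9)

  # aligning twice is idempotent
  again <- alignComplexToReference(back, ref, "C")
  expect_lt(max(abs(coords(mobileModel(again)) - coords(mobileModel(back)))),
            1e-6)

  # fit RMSD is invariant to any rigid pre-transform
  pre <- applyTransform(cx, rigidTransform(randomRotation(), c(-20, 3, 7)))
  alPre <- alignComplexToReference(pre, ref, "C")
  expect_equal(alPre@meta$alignment$fitRMSD, al0@meta$alignment$fitRMSD,
               tolerance = 1e-6)
})

test_that("alignment fails cleanly without heme or shared residues", {
  cx <- makeToyComplex(syntheticSpec(seed = 13))
  ref <- anchorAsReference(cx)
  noFe <- atomTable(ref)
  noFe <- toyModel(noFe[toupper(noFe$element) != "FE", ])
  expect_error(alignComplexToReference(cx, noFe, "C"), "no heme Fe")
  expect_error(alignComplexToReference(cx, ref, "Z"), "not found")
})

test_that("pairwise metrics in the common frame are alignment-order invariant", {
  spec <- syntheticSpec(seed = 20)
  cx <- makeToyComplex(spec)
  ref <- anchorAsReference(cx)
  poses <- list(perturbPose(cx, 10, 3, seed = 1),
                perturbPose(cx, 25, 6, seed = 2))
  scramble <- list(rigidTransform(randomRotation(), c(5, 5, -5)),
                   rigidTransform(randomRotation(), c(-9, 2, 4)))
  aligned1 <- lapply(poses, alignComplexToReference, reference = ref,
                     referenceChain = "C")
  aligned2 <- lapply(seq_along(poses), function(i)
    alignComplexToReference(applyTransform(poses[[i]], scramble[[i]]), ref, "C"))
  expect_equal(rmsdCalpha(aligned1[[1]], aligned1[[2]]),
               rmsdCalpha(aligned2[[1]], aligned2[[2]]), tolerance = 1e-6)
  expect_equal(comDistance(aligned1[[1]], aligned1[[2]]),
               comDistance(aligned2[[1]], aligned2[[2]]), tolerance = 1e-6)
})
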