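# Seeded synthetic data: toy two-body complexes, simulated Gaussian-kernel
# density maps, and rigid-body-perturbed pose ensembles. Every generator is
# a pure function of (spec, seed): random streams are created per call and
# the caller's RNG state is left untouched.
#
# The toy mobile protein is a self-avoiding smoothed random walk of C-alpha
# pseudo-atoms at the canonical 3.8 A spacing — enough geometric realism for
# pairing, alignment and scoring tests without a force field. Defaults
# emulate the study system: a 99-residue mobile copper protein (mature
# plastocyanin length), an anchored heme protein, 0.86 A voxels, and a Cu-Fe
# separation in the functional (< 15 A) range.

#' Specification for the synthetic generators
#'
#' @param nResiduesMobile mobile-protein residue count (default 99).
#' @param nResiduesAnchor anchor-protein residue count (default 60).
#' @param voxelSize map voxel edge in Angstrom (default 0.86).
#' @param kernelSigma Gaussian kernel width per atom in Angstrom (default 1.5).
#' @param noiseSigma additive Gaussian map noise, map units (default 0).
#' @param seed integer RNG seed (default 1).
#' @return a named list with class `"SyntheticSpec"`.
#' @export
syntheticSpec <- function(nResiduesMobile = 99L, nResiduesAnchor = 60L,
                          voxelSize = 0.86, kernelSigma = 1.5,
                          noiseSigma = 0, seed = 1L) {
  if (nResiduesMobile < 3L || nResiduesAnchor < 3L) {
    stopf("residue counts must be >= 3")
  }
  if (voxelSize <= 0) stopf("'voxelSize' must be > 0")
  if (kernelSigma < 0 || noiseSigma < 0) stopf("sigmas must be >= 0")
  structure(list(nResiduesMobile = as.integer(nResiduesMobile),
                 nResiduesAnchor = as.integer(nResiduesAnchor),
                 voxelSize = voxelSize, kernelSigma = kernelSigma,
                 noiseSigma = noiseSigma, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

# self-avoiding smoothed random walk with fixed step length
.randomWalkChain <- function(n, step = 3.8, minSep = 3.0) {
  pos <- matrix(0, n, 3)
  dir <- randomUnitVector()
  for (i in 2:n) {
    placed <- FALSE
    for (try in 1:200) {
      cand <- dir + 0.6 * stats::rnorm(3)
      cand <- cand / sqrt(sum(cand^2))
      p <- pos[i - 1, ] + step * cand
      if (i <= 2 || min(sqrt(rowSums(sweep(pos[1:(i - 2), , drop = FALSE],
                                           2, p)^2))) >= minSep) {
        pos[i, ] <- p
        dir <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {      # give up on self-avoidance for this step
      pos[i, ] <- pos[i - 1, ] + step * dir
    }
  }
  pos
}

.chainAtoms <- function(coordsMat, chain, startResno = 1L) {
  n <- nrow(coordsMat)
  data.frame(
    elety = rep("CA", n), element = rep("C", n), resid = rep("ALA", n),
    chain = rep(chain, n), resno = seq.int(startResno, length.out = n),
    x = coordsMat[, 1], y = coordsMat[, 2], z = coordsMat[, 3],
    stringsAsFactors = FALSE)
}

#' Generate a toy two-body complex
#'
#' Mobile protein: a C-alpha pseudo-atom chain (chain A) plus one Cu atom
#' near its center. Anchor protein: a second chain (chain C) plus one heme
#' Fe. The mobile body is placed so the Cu sits 8-14 A from the Fe — inside
#' the functional electron-transfer range. Deterministic for a fixed seed.
#'
#' @param spec a [syntheticSpec()].
#' @return a [ComplexModel-class] labelled with the seed.
#' @export
makeToyComplex <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withSeed(spec$seed, {
    ancXYZ <- .randomWalkChain(spec$nResiduesAnchor)
    ancXYZ <- sweep(ancXYZ, 2, colMeans(ancXYZ))
    anc <- .chainAtoms(ancXYZ, "C")
    # heme Fe just off the anchor chain's middle residue
    feXYZ <- ancXYZ[spec$nResiduesAnchor %/% 2L, ] + c(0, 0, 2.5)
    anc <- rbind(anc, data.frame(
      elety = "FE", element = "FE", resid = "HEC", chain = "C",
      resno = spec$nResiduesAnchor + 1L,
      x = feXYZ[1], y = feXYZ[2], z = feXYZ[3], stringsAsFactors = FALSE))

    mobXYZ <- .randomWalkChain(spec$nResiduesMobile)
    mobXYZ <- sweep(mobXYZ, 2, colMeans(mobXYZ))
    cuLocal <- mobXYZ[spec$nResiduesMobile %/% 2L, ] * 0.5  # interior point
    # place the mobile body so Cu lands at Fe + d * direction, d in [8, 14]
    d <- stats::runif(1, 8, 14)
    shift <- feXYZ + d * randomUnitVector() - cuLocal
    mobXYZ <- sweep(mobXYZ, 2, shift, "+")
    cuXYZ <- cuLocal + shift
    mob <- .chainAtoms(mobXYZ, "A")
    mob <- rbind(mob, data.frame(
      elety = "CU", element = "CU", resid = "CU", chain = "A",
      resno = spec$nResiduesMobile + 1L,
      x = cuXYZ[1], y = cuXYZ[2], z = cuXYZ[3], stringsAsFactors = FALSE))

    new("ComplexModel",
        anchor = .makeStructureModel(anc, 1L, "toy anchor"),
        mobile = .makeStructureModel(mob, 1L, "toy mobile"),
        cuIdx = nrow(mob), feIdx = nrow(anc),
        label = sprintf("toy seed=%d", spec$seed),
        meta = list(spec = spec))
  })
}

#' Simulate a density map from a complex pose
#'
#' Each cell value is the sum over all atoms of a spherical Gaussian kernel
#' of width `kernelSigma` evaluated at the cell center, plus seeded additive
#' Gaussian noise of width `noiseSigma`. The box extends at least
#' 3 * `kernelSigma` (and at least 2 A) beyond every atom. No atomic form
#' factors, B-factors or CTF: this is a geometric stand-in, not a physical
#' image model.
#'
#' @param complex a [ComplexModel-class] (the "true" pose).
#' @param spec a [syntheticSpec()]; `voxelSize`, `kernelSigma`, `noiseSigma`
#'   and `seed` are used.
#' @return an unsmoothed [DensityGrid-class].
#' @export
simulateDensity <- function(complex, spec = syntheticSpec()) {
  stopifnot(is(complex, "ComplexModel"), inherits(spec, "SyntheticSpec"))
  pts <- rbind(coords(complex@anchor), coords(complex@mobile))
  pad <- max(3 * spec$kernelSigma, 2)
  lo <- apply(pts, 2, min) - pad
  hi <- apply(pts, 2, max) + pad
  vx <- spec$voxelSize
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / vx)) + 1L)
  origin <- lo
  vals <- array(0, dims)

  if (spec$kernelSigma > 0) {
    # local support of 8 sigma: the neglected tail is < exp(-32) ~ 1e-14,
    # below numerical noise
    r <- ceiling(8 * spec$kernelSigma / vx)
    ax <- lapply(1:3, function(k) origin[k] + (seq_len(dims[k]) - 1) * vx)
    for (t in seq_len(nrow(pts))) {
      p <- pts[t, ]
      ci <- round((p - origin) / vx) + 1
      i1 <- pmax(1, ci - r)
      i2 <- pmin(dims, ci + r)
      gx <- exp(-(ax[[1]][i1[1]:i2[1]] - p[1])^2 / (2 * spec$kernelSigma^2))
      gy <- exp(-(ax[[2]][i1[2]:i2[2]] - p[2])^2 / (2 * spec$kernelSigma^2))
      gz <- exp(-(ax[[3]][i1[3]:i2[3]] - p[3])^2 / (2 * spec$kernelSigma^2))
      block <- outer(outer(gx, gy), gz)
      vals[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3]] <-
        vals[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3]] + block
    }
  } else {
    # zero-width kernel: unit mass into each atom's nearest cell
    for (t in seq_len(nrow(pts))) {
      ci <- pmin(dims, pmax(1, round((pts[t, ] - origin) / vx) + 1))
      vals[ci[1], ci[2], ci[3]] <- vals[ci[1], ci[2], ci[3]] + 1
    }
  }
  if (spec$noiseSigma > 0) {
    noise <- withSeed(spec$seed, stats::rnorm(length(vals), 0, spec$noiseSigma))
    vals <- vals + array(noise, dims)
  }
  densityGrid(vals, voxelSize = vx, origin = origin, smoothed = FALSE)
}

#' Rigid-body perturbation of a pose
#'
#' Rotates the mobile body (protein + Cu) about its geometric center by
#' `angleDeg` degrees around a uniformly random axis, then translates it by
#' `shift` Angstrom along a random direction. The anchor is untouched.
#' Deterministic per seed.
#'
#' @param complex a [ComplexModel-class].
#' @param angleDeg rotation magnitude in degrees (>= 0).
#' @param shift translation magnitude in Angstrom (>= 0).
#' @param seed integer RNG seed.
#' @return the perturbed [ComplexModel-class].
#' @export
perturbPose <- function(complex, angleDeg, shift, seed = 1L) {
  stopifnot(is(complex, "ComplexModel"))
  if (angleDeg < 0 || shift < 0) stopf("magnitudes must be >= 0")
  withSeed(seed, {
    m <- coords(complex@mobile)
    ctr <- colMeans(m)
    # exact short-circuits keep zero-magnitude perturbations bit-identical
    moved <- m
    if (angleDeg > 0) {
      R <- rotationAboutAxis(randomUnitVector(), angleDeg)
      moved <- sweep(sweep(moved, 2, ctr) %*% t(R), 2, ctr, "+")
    }
    if (shift > 0) {
      moved <- sweep(moved, 2, shift * randomUnitVector(), "+")
    }
    out <- complex
    out@mobile@atoms$x <- moved[, 1]
    out@mobile@atoms$y <- moved[, 2]
    out@mobile@atoms$z <- moved[, 3]
    out@label <- sprintf("%s +%.0fdeg/%.1fA", complex@label, angleDeg, shift)
    out@meta$perturbation <- list(angleDeg = angleDeg, shift = shift,
                                  seed = seed)
    out
  })
}

#' Generate a seeded pose ensemble
#'
#' Member 1 is the unperturbed pose; members 2..n are seeded perturbations
#' with rotation angles drawn uniformly from [`angleScale`/2, `angleScale`]
#' degrees and shifts from [`shiftScale`/2, `shiftScale`] Angstrom: a
#' comparable-magnitude scatter around the base pose (members displaced in
#' random directions, none nested arbitrarily close to the base).
#'
#' @param complex the base [ComplexModel-class].
#' @param n ensemble size (>= 1).
#' @param angleScale maximum rotation angle, degrees.
#' @param shiftScale maximum translation, Angstrom.
#' @param seed integer RNG seed.
#' @return list of [ComplexModel-class] members (length `n`).
#' @export
makeEnsemble <- function(complex, n, angleScale = 20, shiftScale = 5,
                         seed = 1L) {
  stopifnot(is(complex, "ComplexModel"))
  if (n < 1L) stopf("'n' must be >= 1")
  pars <- withSeed(seed, data.frame(
    angle = stats::runif(n, angleScale / 2, angleScale),
    shift = stats::runif(n, shiftScale / 2, shiftScale),
    subseed = sample.int(.Machine$integer.max - 1L, n)))
  out <- vector("list", n)
  out[[1L]] <- complex
  for (i in seq_len(n)[-1]) {
    out[[i]] <- perturbPose(complex, pars$angle[i], pars$shift[i],
                            seed = pars$subseed[i])
  }
  out
}
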