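# Least-squares rigid superposition (Kabsch) and the common-frame alignment
# convention: every pose is aligned onto the reference heme protein using the
# anchor atoms surrounding the reference heme iron, and all pairwise pose
# metrics are then computed in that single frame without per-pair refitting.

#' Kabsch least-squares superposition
#'
#' Finds the proper rigid transform (rotation + translation, reflections
#' excluded) minimizing the RMSD between `mobile` and `ref` paired point
#' sets.
#'
#' @param mobile n x 3 coordinate matrix.
#' @param ref n x 3 coordinate matrix, paired row-by-row with `mobile`.
#' @return a [Transform-class]; apply it with [applyTransform()].
#' @examples
#' p <- matrix(rnorm(30), 10)
#' kabsch(p, p)  # identity, fit RMSD 0
#' @export
kabsch <- function(mobile, ref) {
  mobile <- as.matrix(mobile)
  ref <- as.matrix(ref)
  if (ncol(mobile) != 3L || ncol(ref) != 3L) {
    stopf("coordinate sets must be n x 3 matrices")
  }
  n <- nrow(mobile)
  if (nrow(ref) != n) stopf("paired coordinate sets differ in length: %d vs %d",
                            n, nrow(ref))
  if (n < 3L) stopf("superposition needs at least 3 atom pairs (got %d)", n)

  cm <- colMeans(mobile)
  cr <- colMeans(ref)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(ref, 2, cr)
  sv <- svd(P)
  if (sv$d[2] <= 1e-10 * max(sv$d[1], 1e-12)) {
    stopf("degenerate (collinear) mobile coordinate set; rotation is undefined")
  }
  sv <- svd(Q)
  if (sv$d[2] <= 1e-10 * max(sv$d[1], 1e-12)) {
    stopf("degenerate (collinear) reference coordinate set; rotation is undefined")
  }

  H <- crossprod(P, Q)              # sum_i p_i q_i^T
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cr - R %*% cm)
  moved <- mobile %*% t(R)
  moved <- sweep(moved, 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((moved - ref)^2)))
  new("Transform", rotation = R, translation = tr, fitRMSD = rmsd,
      nFitAtoms = as.integer(n))
}

.identityTransform <- function() {
  new("Transform", rotation = diag(3), translation = c(0, 0, 0),
      fitRMSD = 0, nFitAtoms = 0L)
}

#' @rdname applyTransform
setMethod("applyTransform", "matrix", function(x, transform) {
  sweep(x %*% t(transform@rotation), 2, transform@translation, "+")
})

#' @rdname applyTransform
setMethod("applyTransform", "StructureModel", function(x, transform) {
  m <- applyTransform(coords(x), transform)
  x@atoms$x <- m[, 1]
  x@atoms$y <- m[, 2]
  x@atoms$z <- m[, 3]
  x
})

#' @rdname applyTransform
setMethod("applyTransform", "ComplexModel", function(x, transform) {
  x@anchor <- applyTransform(x@anchor, transform)
  x@mobile <- applyTransform(x@mobile, transform)
  x
})

# reference fit set: all heavy atoms of the reference-chain residues that
# have any atom within `hemeRadius` of the reference heme Fe
.referenceFitAtoms <- function(reference, referenceChain, hemeRadius) {
  a <- reference@atoms
  ch <- a[a$chain == referenceChain, , drop = FALSE]
  if (!nrow(ch)) stopf("reference chain '%s' not found", referenceChain)
  feRows <- which(toupper(ch$element) == "FE")
  if (!length(feRows)) {
    stopf("reference chain '%s' contains no heme Fe atom", referenceChain)
  }
  fe <- as.numeric(ch[feRows[1L], c("x", "y", "z")])
  heavy <- ch[toupper(ch$element) != "H", , drop = FALSE]
  d2 <- (heavy$x - fe[1])^2 + (heavy$y - fe[2])^2 + (heavy$z - fe[3])^2
  resKeep <- unique(heavy$resno[d2 <= hemeRadius^2])
  fit <- heavy[heavy$resno %in% resKeep, , drop = FALSE]
  fit[order(fit$resno, fit$elety), , drop = FALSE]
}

#' Align a complex pose into the common reference frame
#'
#' Fits one rigid transform between the pose's anchor protein and the
#' reference chain, using all heavy atoms of the reference-chain residues
#' that come within `hemeRadius` of the reference heme Fe, paired by residue
#' number + atom name (with a sequence-alignment residue remap as fallback
#' for anchors with a different numbering or sequence). The whole complex —
#' both proteins and both cofactors — is then moved by that single
#' transform; the transform and its fit RMSD are recorded in the pose's
#' provenance (`meta$alignment`).
#'
#' @param complex a [ComplexModel-class].
#' @param reference a [StructureModel-class] holding the reference frame.
#' @param referenceChain chain ID of the heme protein in `reference`.
#' @param hemeRadius Angstrom radius around the reference heme Fe that
#'   defines the fit residue set (default 8).
#' @param pairingMode `"auto"`, `"resno"` or `"align"` (see package docs).
#' @return the aligned [ComplexModel-class].
#' @export
alignComplexToReference <- function(complex, reference, referenceChain,
                                    hemeRadius = 8,
                                    pairingMode = c("auto", "resno", "align")) {
  pairingMode <- match.arg(pairingMode)
  stopifnot(is(complex, "ComplexModel"), is(reference, "StructureModel"))
  if (!is.numeric(hemeRadius) || hemeRadius <= 0) {
    stopf("'hemeRadius' must be > 0")
  }
  fitRef <- .referenceFitAtoms(reference, referenceChain, hemeRadius)
  anc <- complex@anchor@atoms
  anc <- anc[toupper(anc$element) != "H", , drop = FALSE]

  pairByKey <- function(ancTab, refTab) {
    keyA <- paste(ancTab$resno, toupper(ancTab$elety))
    keyR <- paste(refTab$resno, toupper(refTab$elety))
    common <- intersect(keyR, keyA)
    ia <- match(common, keyA)
    ir <- match(common, keyR)
    list(mob = as.matrix(ancTab[ia, c("x", "y", "z")]),
         ref = as.matrix(refTab[ir, c("x", "y", "z")]))
  }

  pr <- if (pairingMode == "align") list(mob = matrix(0, 0, 3)) else
    pairByKey(anc, fitRef)
  if (nrow(pr$mob) < 3L && pairingMode != "resno") {
    # remap anchor residue numbers onto the reference numbering via a global
    # sequence alignment, then re-pair by (mapped resno, atom name)
    refChain <- .makeStructureModel(
      reference@atoms[reference@atoms$chain == referenceChain, , drop = FALSE],
      reference@modelIndex, "reference chain")
    map <- .residueNumberMap(complex@anchor, refChain)
    anc2 <- anc
    anc2$resno <- map[as.character(anc$resno)]
    anc2 <- anc2[!is.na(anc2$resno), , drop = FALSE]
    pr <- pairByKey(anc2, fitRef)
  }
  if (nrow(pr$mob) < 3L) {
    stopf("pose '%s': only %d anchor atoms pair with the reference fit set within %.3g A of the heme; cannot superpose",
          complex@label, nrow(pr$mob), hemeRadius)
  }
  tr <- kabsch(pr$mob, pr$ref)
  out <- applyTransform(complex, tr)
  out@meta$alignment <- list(transform = tr, fitRMSD = tr@fitRMSD,
                             nFitAtoms = tr@nFitAtoms,
                             hemeRadius = hemeRadius,
                             referenceChain = referenceChain)
  out
}

# map anchor residue numbers -> reference residue numbers by aligning the
# one-letter C-alpha sequences
.residueNumberMap <- function(anchor, refChain) {
  caA <- selectCalpha(anchor)
  caR <- selectCalpha(refChain)
  rnA <- attr(caA, "resno")
  rnR <- attr(caR, "resno")
  seqA <- .calphaSequence(anchor)
  seqR <- .calphaSequence(refChain)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqR),
    type = "global", substitutionMatrix = .identityMatrix(),
    gapOpening = 5, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  map <- integer(0)
  nmA <- character(0)
  ca <- 0L; cb <- 0L
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ca <- ca + 1L
    if (pb[k] != "-") cb <- cb + 1L
    if (pa[k] != "-" && pb[k] != "-") {
      map <- c(map, rnR[cb])
      nmA <- c(nmA, as.character(rnA[ca]))
    }
  }
  stats::setNames(map, nmA)
}
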