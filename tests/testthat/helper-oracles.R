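# Independent oracles and small fixture builders shared across the suite.
# Oracles are deliberately naive (triple loops, exhaustive search) and stay
# independent of the code paths they check.

# truncated-mean moving average by explicit triple loop
bruteSmooth <- function(values, window) {
  d <- dim(values)
  h <- window %/% 2
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    xs <- max(1, i - h):min(d[1], i + h)
    ys <- max(1, j - h):min(d[2], j + h)
    zs <- max(1, k - h):min(d[3], k + h)
    out[i, j, k] <- mean(values[xs, ys, zs])
  }
  out
}

# nearest-voxel lookup by independent index arithmetic
bruteNearest <- function(values, voxel, origin, point) {
  idx <- round((point - origin) / voxel) + 1
  d <- dim(values)
  if (any(idx < 1) || any(idx > d)) return(0)
  values[idx[1], idx[2], idx[3]]
}

# random proper rotation matrix (QR-based, det corrected)
randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigidTransform <- function(rotation, translation) {
  new("Transform", rotation = rotation, translation = as.numeric(translation),
      fitRMSD = 0, nFitAtoms = 0L)
}

# tiny hand-built peptide-plus-cofactor model
toyModel <- function(atoms) {
  atoms$mass <- edcscore:::elementMass(atoms$element)
  new("StructureModel", atoms = atoms, modelIndex = 1L, sourceId = "toy")
}

atomRow <- function(elety, element, resid, chain, resno, x, y, z) {
  data.frame(elety = elety, element = element, resid = resid, chain = chain,
             resno = resno, x = x, y = y, z = z, stringsAsFactors = FALSE)
}

# a minimal valid complex: 4-residue mobile chain A + Cu, 4-residue anchor
# chain C + Fe, at controllable separation
miniComplex <- function(cuPos = c(3, 4, 0), fePos = c(0, 0, 0)) {
  mob <- do.call(rbind, lapply(1:4, function(i)
    atomRow("CA", "C", "ALA", "A", i, 10 + 3.8 * i, 1, 2)))
  mob <- rbind(mob, atomRow("CU", "CU", "CU", "A", 5,
                            cuPos[1], cuPos[2], cuPos[3]))
  anc <- do.call(rbind, lapply(1:4, function(i)
    atomRow("CA", "C", "GLY", "C", i, -10 - 3.8 * i, -1, -2)))
  anc <- rbind(anc, atomRow("FE", "FE", "HEC", "C", 5,
                            fePos[1], fePos[2], fePos[3]))
  new("ComplexModel", anchor = toyModel(anc), mobile = toyModel(mob),
      cuIdx = 5L, feIdx = 5L, label = "mini", meta = list())
}

# reference StructureModel = the anchor body of a complex (the common-frame
# target used throughout the synthetic tests)
anchorAsReference <- function(complex) {
  new("StructureModel", atoms = atomTable(anchorModel(complex)),
      modelIndex = 1L, sourceId = "reference")
}

# combine a complex back into a single model (for write/split round trips)
complexAsModel <- function(complex, sourceId = "combined") {
  new("StructureModel",
      atoms = rbind(atomTable(anchorModel(complex)),
                    atomTable(mobileModel(complex))),
      modelIndex = 1L, sourceId = sourceId)
}
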