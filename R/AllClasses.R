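#' @import methods
NULL

#' DensityGrid: a 3-D scalar density field with voxel geometry
#'
#' Holds an electron-density grid in canonical x,y,z axis order together with
#' its voxel size and physical origin. The origin is the Cartesian position
#' (in Angstrom) of the *center* of the first cell, i.e. cell `[1,1,1]` in R's
#' 1-based indexing. Values are kept in the units of the source map and are
#' never rescaled on read. The `smoothed` flag records whether the values have
#' been moving-average filtered; EDC scoring refuses unsmoothed grids.
#'
#' @slot values 3-D numeric array of finite map values, canonical x,y,z order.
#' @slot voxelSize numeric(3), Angstrom per cell along x, y, z; all > 0.
#' @slot origin numeric(3), Angstrom position of the center of cell [1,1,1].
#' @slot smoothed logical(1), TRUE after [smoothMap()].
#'
#' @seealso [readMRC()], [smoothMap()], [sampleAt()]
#' @export
setClass("DensityGrid",
  slots = c(
    values = "array",
    voxelSize = "numeric",
    origin = "numeric",
    smoothed = "logical"
  )
)

setValidity("DensityGrid", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("'values' must be a 3-D array")
  if (any(dim(v) < 1L)) return("all grid dimensions must be >= 1")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0)) {
    return("'voxelSize' must be 3 positive finite numbers")
  }
  if (length(object@origin) != 3L || any(!is.finite(object@origin))) {
    return("'origin' must be 3 finite numbers")
  }
  if (any(!is.finite(v))) return("all grid values must be finite")
  if (length(object@smoothed) != 1L || is.na(object@smoothed)) {
    return("'smoothed' must be TRUE or FALSE")
  }
  TRUE
})

#' StructureModel: one atomic model
#'
#' One coordinate set of an atomic structure (one MODEL of a multi-model PDB
#' entry, or a single-model file). Atoms are stored as a data.frame with
#' columns `elety` (atom name), `element`, `resid` (3-letter residue name),
#' `chain`, `resno`, `x`, `y`, `z` (Angstrom) and `mass` (a.m.u.).
#'
#' @slot atoms data.frame of atoms as described above.
#' @slot modelIndex integer(1), 1-based model number within the source entry.
#' @slot sourceId character(1), free-text provenance (e.g. file and model).
#'
#' @seealso [readStructure()], [selectCalpha()], [centerOfMass()]
#' @export
setClass("StructureModel",
  slots = c(
    atoms = "data.frame",
    modelIndex = "integer",
    sourceId = "character"
  )
)

.ATOM_COLS <- c("elety", "element", "resid", "chain", "resno",
                "x", "y", "z", "mass")

setValidity("StructureModel", function(object) {
  a <- object@atoms
  if (nrow(a) < 1L) return("a StructureModel must contain at least one atom")
  miss <- setdiff(.ATOM_COLS, names(a))
  if (length(miss)) {
    return(paste("atom table lacks column(s):", paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(as.matrix(a[, c("x", "y", "z")])))) {
    return("all atom coordinates must be finite")
  }
  if (any(!is.finite(a$mass)) || any(a$mass <= 0)) {
    return("all atom masses must be positive")
  }
  if (any(!nzchar(a$element))) return("all atoms must carry an element symbol")
  if (length(object@modelIndex) != 1L || is.na(object@modelIndex) ||
      object@modelIndex < 1L) {
    return("'modelIndex' must be a single integer >= 1")
  }
  TRUE
})

#' ComplexModel: one pose of a two-protein complex
#'
#' A rigid pose of the mobile (copper-carrying, plastocyanin-role) protein
#' against the anchored (heme-carrying, cytochrome f-role) protein. The Cu
#' cofactor lives in the mobile atom table and the heme Fe in the anchor
#' table; `cuIdx`/`feIdx` are their row indices, so rigid transforms applied
#' to either body carry the cofactors along.
#'
#' @slot anchor StructureModel, the anchored heme protein (includes Fe).
#' @slot mobile StructureModel, the mobile copper protein (includes Cu).
#' @slot cuIdx integer(1), row of the Cu atom in `mobile@atoms`.
#' @slot feIdx integer(1), row of the heme Fe atom in `anchor@atoms`.
#' @slot label character(1), free-text pose label.
#' @slot meta list, provenance (source paths, alignment transform, fit RMSD).
#'
#' @seealso [splitComplex()], [alignComplexToReference()], [cofactorDistance()]
#' @export
setClass("ComplexModel",
  slots = c(
    anchor = "StructureModel",
    mobile = "StructureModel",
    cuIdx = "integer",
    feIdx = "integer",
    label = "character",
    meta = "list"
  ),
  prototype = prototype(label = "", meta = list())
)

setValidity("ComplexModel", function(object) {
  ma <- object@mobile@atoms
  aa <- object@anchor@atoms
  if (length(object@cuIdx) != 1L || object@cuIdx < 1L ||
      object@cuIdx > nrow(ma)) {
    return("'cuIdx' must index a row of the mobile atom table")
  }
  if (length(object@feIdx) != 1L || object@feIdx < 1L ||
      object@feIdx > nrow(aa)) {
    return("'feIdx' must index a row of the anchor atom table")
  }
  if (toupper(ma$element[object@cuIdx]) != "CU") {
    return("the atom at 'cuIdx' must have element Cu")
  }
  if (toupper(aa$element[object@feIdx]) != "FE") {
    return("the atom at 'feIdx' must have element Fe")
  }
  shared <- intersect(unique(ma$chain), unique(aa$chain))
  if (length(shared)) {
    return(paste("anchor and mobile atom sets must be disjoint; shared",
                 "chain(s):", paste(shared, collapse = ", ")))
  }
  TRUE
})

#' Transform: a proper rigid-body transform from least-squares superposition
#'
#' Maps a point x to `rotation %*% x + translation`. The rotation is a proper
#' orthogonal matrix (determinant +1; reflections are excluded during the
#' fit). `fitRMSD` and `nFitAtoms` record the quality and size of the
#' superposition that produced it.
#'
#' @slot rotation 3x3 proper orthogonal matrix.
#' @slot translation numeric(3), Angstrom.
#' @slot fitRMSD numeric(1), RMSD over the fitted atom pairs (Angstrom).
#' @slot nFitAtoms integer(1), number of fitted pairs.
#'
#' @seealso [kabsch()], [applyTransform()]
#' @export
setClass("Transform",
  slots = c(
    rotation = "matrix",
    translation = "numeric",
    fitRMSD = "numeric",
    nFitAtoms = "integer"
  )
)

setValidity("Transform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("'rotation' must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8) {
    return("'rotation' must be orthogonal (R'R = I within 1e-8)")
  }
  if (abs(det(R) - 1) > 1e-8) {
    return("'rotation' must be proper (det = +1 within 1e-8)")
  }
  if (length(object@translation) != 3L ||
      any(!is.finite(object@translation))) {
    return("'translation' must be 3 finite numbers")
  }
  if (object@fitRMSD < 0) return("'fitRMSD' must be >= 0")
  TRUE
})

#' ComparisonTable: pairwise pose comparison matrix
#'
#' The per-pose and pairwise summary of a set of complex poses sitting in one
#' common reference frame: per pose the Cu-Fe distance, EDC score and
#' out-of-map C-alpha fraction (the table's diagonal), and for each pose pair
#' the mobile-protein center-of-mass distance (upper triangle) and C-alpha
#' RMSD (lower triangle). Distances in Angstrom, EDC in map units. Full
#' precision is stored; rounding happens only in the writers.
#'
#' @slot labels character vector of pose labels, row/column order.
#' @slot cuFe numeric, per-pose Cu-Fe distance (Angstrom).
#' @slot edc numeric, per-pose EDC score (map units).
#' @slot oobFraction numeric, per-pose fraction of C-alpha outside the map.
#' @slot comDist symmetric numeric matrix of center-of-mass distances.
#' @slot rmsd symmetric numeric matrix of C-alpha RMSDs.
#'
#' @seealso [buildComparisonTable()], [writeComparisonCSV()]
#' @export
setClass("ComparisonTable",
  slots = c(
    labels = "character",
    cuFe = "numeric",
    edc = "numeric",
    oobFraction = "numeric",
    comDist = "matrix",
    rmsd = "matrix"
  )
)

setValidity("ComparisonTable", function(object) {
  n <- length(object@labels)
  if (length(object@cuFe) != n || length(object@edc) != n ||
      length(object@oobFraction) != n) {
    return("per-pose vectors must match the number of labels")
  }
  for (nm in c("comDist", "rmsd")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(n, n))) return(paste0("'", nm, "' must be ", n, "x", n))
    if (n && max(abs(m - t(m))) > 1e-9) return(paste0("'", nm, "' must be symmetric"))
    if (n && any(m < -1e-12)) return(paste0("'", nm, "' entries must be >= 0"))
  }
  if (any(object@cuFe < 0)) return("Cu-Fe distances must be >= 0")
  if (any(object@oobFraction < 0 | object@oobFraction > 1)) {
    return("out-of-bounds fractions must lie in [0, 1]")
  }
  TRUE
})

#' Ensemble: an ordered set of complex poses with RMSD geometry
#'
#' Stores ensemble members (poses of one complex in a common frame), their
#' pairwise mobile C-alpha RMSD matrix, and the index of the central
#' structure: the member with minimum average RMSD to all other members.
#'
#' @slot members list of [ComplexModel-class] poses.
#' @slot rmsdMatrix symmetric n x n matrix of pairwise C-alpha RMSDs (Angstrom).
#' @slot centralIndex integer(1), 1-based index of the central structure.
#'
#' @seealso [makeEnsembleObject()], [centralStructure()], [spreadStats()]
#' @export
setClass("Ensemble",
  slots = c(
    members = "list",
    rmsdMatrix = "matrix",
    centralIndex = "integer"
  )
)

setValidity("Ensemble", function(object) {
  n <- length(object@members)
  if (n < 1L) return("an Ensemble needs at least one member")
  m <- object@rmsdMatrix
  if (!all(dim(m) == c(n, n))) return("'rmsdMatrix' must be n x n")
  if (max(abs(diag(m))) > 1e-9) return("'rmsdMatrix' diagonal must be zero")
  if (max(abs(m - t(m))) > 1e-9) return("'rmsdMatrix' must be symmetric")
  ci <- object@centralIndex
  if (length(ci) != 1L || ci < 1L || ci > n) {
    return("'centralIndex' must index a member")
  }
  TRUE
})
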