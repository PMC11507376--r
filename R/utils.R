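# Accessors, show methods, and small shared helpers.

#' Accessors for DensityGrid
#'
#' @param x a [DensityGrid-class].
#' @return `gridValues`: the 3-D value array; `gridDims`: integer(3) cell
#'   counts; `voxelSize`/`gridOrigin`: numeric(3) in Angstrom; `isSmoothed`:
#'   logical(1).
#' @name DensityGrid-accessors
#' @aliases gridValues gridDims voxelSize gridOrigin isSmoothed
NULL

#' @rdname DensityGrid-accessors
setMethod("gridValues", "DensityGrid", function(x) x@values)
#' @rdname DensityGrid-accessors
setMethod("gridDims", "DensityGrid", function(x) dim(x@values))
#' @rdname DensityGrid-accessors
setMethod("voxelSize", "DensityGrid", function(x) x@voxelSize)
#' @rdname DensityGrid-accessors
setMethod("gridOrigin", "DensityGrid", function(x) x@origin)
#' @rdname DensityGrid-accessors
setMethod("isSmoothed", "DensityGrid", function(x) x@smoothed)

#' Accessors for StructureModel
#'
#' @param x a [StructureModel-class].
#' @return `atomTable`: the atom data.frame; `coords`: an n x 3 coordinate
#'   matrix in Angstrom.
#' @name StructureModel-accessors
#' @aliases atomTable coords
NULL

#' @rdname StructureModel-accessors
setMethod("atomTable", "StructureModel", function(x) x@atoms)
#' @rdname StructureModel-accessors
setMethod("coords", "StructureModel", function(x) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
})

#' Accessors for ComplexModel
#'
#' @param x a [ComplexModel-class].
#' @return `anchorModel`/`mobileModel`: the two [StructureModel-class]
#'   bodies; `cuAtom`/`feAtom`: one-row data.frames for the cofactor atoms;
#'   `poseLabel`: character(1).
#' @name ComplexModel-accessors
#' @aliases anchorModel mobileModel cuAtom feAtom poseLabel
NULL

#' @rdname ComplexModel-accessors
setMethod("anchorModel", "ComplexModel", function(x) x@anchor)
#' @rdname ComplexModel-accessors
setMethod("mobileModel", "ComplexModel", function(x) x@mobile)
#' @rdname ComplexModel-accessors
setMethod("cuAtom", "ComplexModel", function(x) x@mobile@atoms[x@cuIdx, , drop = FALSE])
#' @rdname ComplexModel-accessors
setMethod("feAtom", "ComplexModel", function(x) x@anchor@atoms[x@feIdx, , drop = FALSE])
#' @rdname ComplexModel-accessors
setMethod("poseLabel", "ComplexModel", function(x) x@label)
#' @rdname ComplexModel-accessors
#' @param value replacement label.
setMethod("poseLabel<-", "ComplexModel", function(x, value) {
  x@label <- as.character(value)
  x
})

#' Accessors for Ensemble
#'
#' @param x an [Ensemble-class].
#' @return `members`: list of [ComplexModel-class]; `rmsdMatrixOf`: the
#'   pairwise C-alpha RMSD matrix (Angstrom); `centralIndex`: 1-based index
#'   of the central structure.
#' @name Ensemble-accessors
#' @aliases members rmsdMatrixOf centralIndex
NULL

#' @rdname Ensemble-accessors
setMethod("members", "Ensemble", function(x) x@members)
#' @rdname Ensemble-accessors
setMethod("rmsdMatrixOf", "Ensemble", function(x) x@rmsdMatrix)
#' @rdname Ensemble-accessors
setMethod("centralIndex", "Ensemble", function(x) x@centralIndex)

#' @export
setMethod("show", "DensityGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "DensityGrid: %d x %d x %d cells, voxel %.3g x %.3g x %.3g A%s\n",
    d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
    object@voxelSize[3], if (object@smoothed) " (smoothed)" else ""))
  cat(sprintf("  origin (cell [1,1,1] center): %.2f %.2f %.2f A\n",
              object@origin[1], object@origin[2], object@origin[3]))
  cat(sprintf("  value range: [%.4g, %.4g] map units\n",
              min(object@values), max(object@values)))
})

#' @export
setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat(sprintf("StructureModel '%s' (model %d): %d atoms, %d residues, chains %s\n",
              object@sourceId, object@modelIndex, nrow(a),
              length(unique(paste(a$chain, a$resno))),
              paste(unique(a$chain), collapse = ",")))
})

#' @export
setMethod("show", "ComplexModel", function(object) {
  cat(sprintf("ComplexModel '%s'\n", object@label))
  cat(sprintf("  anchor: %d atoms (chains %s), heme Fe present\n",
              nrow(object@anchor@atoms),
              paste(unique(object@anchor@atoms$chain), collapse = ",")))
  cat(sprintf("  mobile: %d atoms (chains %s), Cu present\n",
              nrow(object@mobile@atoms),
              paste(unique(object@mobile@atoms$chain), collapse = ",")))
  cat(sprintf("  Cu-Fe distance: %.2f A\n", cofactorDistance(object)))
})

#' @export
setMethod("show", "Transform", function(object) {
  cat(sprintf("Transform: fit RMSD %.4g A over %d atom pairs\n",
              object@fitRMSD, object@nFitAtoms))
  cat("  rotation:\n")
  print(round(object@rotation, 4))
  cat(sprintf("  translation: %.3f %.3f %.3f A\n",
              object@translation[1], object@translation[2],
              object@translation[3]))
})

#' @export
setMethod("show", "ComparisonTable", function(object) {
  cat(sprintf("ComparisonTable: %d poses\n", length(object@labels)))
  print(formatComparisonTable(object), quote = FALSE)
})

#' @export
setMethod("show", "Ensemble", function(object) {
  s <- spreadStats(object)
  cat(sprintf(
    "Ensemble: %d members; central structure #%d; max pairwise RMSD %.2f A\n",
    length(object@members), object@centralIndex, s[["maxPairwiseRMSD"]]))
})

# -- internal helpers ---------------------------------------------------------

# standard atomic masses (a.m.u.) for the elements this pipeline meets
.ELEMENT_MASS <- c(
  "H" = 1.008, "C" = 12.011, "N" = 14.007, "O" = 15.999, "S" = 32.06,
  "P" = 30.974, "SE" = 78.971, "FE" = 55.845, "CU" = 63.546, "ZN" = 65.38,
  "MG" = 24.305, "MN" = 54.938, "CA" = 40.078, "NA" = 22.990, "K" = 39.098,
  "CL" = 35.45
)

elementMass <- function(element) {
  m <- .ELEMENT_MASS[toupper(element)]
  # unknown heavy elements fall back to carbon mass rather than failing
  m[is.na(m)] <- .ELEMENT_MASS[["C"]]
  unname(m)
}

# run `code` under a fixed RNG seed without disturbing the caller's stream
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

randomUnitVector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

# Rodrigues rotation matrix about `axis` (unit vector) by `angleDeg` degrees
rotationAboutAxis <- function(axis, angleDeg) {
  th <- angleDeg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
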