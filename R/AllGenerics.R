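#' Apply a rigid transform
#'
#' Applies a [Transform-class] (rotation then translation) to coordinates or
#' to a whole structural object. For a ComplexModel both bodies and both
#' cofactors move together (one rigid transform for the whole pose).
#'
#' @param x a numeric n x 3 coordinate matrix, a [StructureModel-class], or a
#'   [ComplexModel-class].
#' @param transform a [Transform-class].
#' @return an object of the same class as `x`, transformed.
#' @examples
#' tr <- kabsch(matrix(rnorm(12), 4), matrix(rnorm(12), 4))
#' applyTransform(diag(3), tr)
#' @export
setGeneric("applyTransform", function(x, transform)
  standardGeneric("applyTransform"))

#' @rdname DensityGrid-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname DensityGrid-accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' @rdname DensityGrid-accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname DensityGrid-accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname DensityGrid-accessors
#' @export
setGeneric("isSmoothed", function(x) standardGeneric("isSmoothed"))

#' @rdname StructureModel-accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname StructureModel-accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname ComplexModel-accessors
#' @export
setGeneric("anchorModel", function(x) standardGeneric("anchorModel"))

#' @rdname ComplexModel-accessors
#' @export
setGeneric("mobileModel", function(x) standardGeneric("mobileModel"))

#' @rdname ComplexModel-accessors
#' @export
setGeneric("cuAtom", function(x) standardGeneric("cuAtom"))

#' @rdname ComplexModel-accessors
#' @export
setGeneric("feAtom", function(x) standardGeneric("feAtom"))

#' @rdname ComplexModel-accessors
#' @export
setGeneric("poseLabel", function(x) standardGeneric("poseLabel"))

#' @rdname ComplexModel-accessors
#' @export
setGeneric("poseLabel<-", function(x, value) standardGeneric("poseLabel<-"))

#' @rdname Ensemble-accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname Ensemble-accessors
#' @export
setGeneric("rmsdMatrixOf", function(x) standardGeneric("rmsdMatrixOf"))

#' @rdname Ensemble-accessors
#' @export
setGeneric("centralIndex", function(x) standardGeneric("centralIndex"))
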