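#' @include AllClasses.R
NULL

#' Grid geometry accessors
#'
#' @param x a grid-backed object (\linkS4class{VolumeGrid},
#'   \linkS4class{LabelMask}, \linkS4class{DisplacementField},
#'   \linkS4class{SkeletonGraph}).
#' @return \code{gridSpacing}/\code{gridOrigin}: numeric(3) mm;
#'   \code{gridDim}: integer(3) voxel counts; \code{voxelData}: the raw
#'   array.
#' @examples
#' v <- VolumeGrid(array(0, c(4, 4, 2)), spacing = c(1, 1, 5))
#' gridSpacing(v)
#' gridDim(v)
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname gridSpacing
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname gridSpacing
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname gridSpacing
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Convert between voxel indices and world coordinates
#'
#' World coordinates are voxel centres: \code{world = origin +
#' (index - 1) * spacing} with 1-based R indices (equivalently a 0-based
#' \code{origin + i * spacing} convention). The two maps are mutual
#' inverses on the grid.
#'
#' @param x a grid-backed object.
#' @param idx n x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @param pts n x 3 matrix (or length-3 vector) of world mm coordinates.
#' @return n x 3 numeric matrix.
#' @export
setGeneric("indexToWorld", function(x, idx) standardGeneric("indexToWorld"))

#' @rdname indexToWorld
#' @export
setGeneric("worldToIndex", function(x, pts) standardGeneric("worldToIndex"))

#' @rdname gridSpacing
#' @export
setGeneric("phaseIndex", function(x) standardGeneric("phaseIndex"))

#' Number of motion phases
#' @param x a \linkS4class{MotionParams} or \linkS4class{SurfaceSequence}.
#' @export
setGeneric("nPhases", function(x) standardGeneric("nPhases"))

#' @rdname nPhases
#' @export
setGeneric("phaseTimes", function(x) standardGeneric("phaseTimes"))

#' Centerline accessors
#' @param x a \linkS4class{Centerline} (or \linkS4class{NurbsSurface} for
#'   \code{arcLength}: the per-section stations).
#' @export
setGeneric("linePoints", function(x) standardGeneric("linePoints"))

#' @rdname linePoints
#' @export
setGeneric("arcLength", function(x) standardGeneric("arcLength"))

#' Surface accessors
#' @param x a \linkS4class{NurbsSurface} or \linkS4class{ShellStack}.
#' @export
setGeneric("controlNet", function(x) standardGeneric("controlNet"))

#' @rdname controlNet
#' @export
setGeneric("sectionCenters", function(x) standardGeneric("sectionCenters"))

#' @rdname controlNet
#' @export
setGeneric("shellLevels", function(x) standardGeneric("shellLevels"))
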