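#' @include AllGenerics.R
NULL

# ---- constructors --------------------------------------------------------

#' Create a VolumeGrid
#'
#' @param data 3D numeric array.
#' @param spacing numeric(3), mm/voxel.
#' @param origin numeric(3), mm, world position of voxel (1,1,1).
#' @return a \linkS4class{VolumeGrid}.
#' @export
VolumeGrid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    new("VolumeGrid", data = data, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Create a LabelMask
#'
#' @param data 3D array of 0/1 (logical arrays are coerced).
#' @inheritParams VolumeGrid
#' @return a \linkS4class{LabelMask}.
#' @export
LabelMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    if (is.logical(data)) data <- array(as.numeric(data), dim(data))
    new("LabelMask", data = data, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Create a DisplacementField
#'
#' @param data 4D numeric array \code{c(nx, ny, nz, 3)}, mm, world axes.
#' @inheritParams VolumeGrid
#' @param phaseIndex integer phase label (>= 0).
#' @param info optional provenance list.
#' @return a \linkS4class{DisplacementField}.
#' @export
DisplacementField <- function(data, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0), phaseIndex = 0L,
                              info = list()) {
    new("DisplacementField", data = data, spacing = as.numeric(spacing),
        origin = as.numeric(origin), phaseIndex = as.integer(phaseIndex),
        info = info)
}

#' Zero displacement field on the grid of an existing object
#'
#' @param x a grid-backed object.
#' @param phaseIndex integer phase label.
#' @return a \linkS4class{DisplacementField} of zeros.
#' @export
zeroField <- function(x, phaseIndex = 0L) {
    DisplacementField(array(0, c(gridDim(x), 3L)), gridSpacing(x),
                      gridOrigin(x), phaseIndex)
}

# ---- accessors -----------------------------------------------------------

#' @rdname gridSpacing
setMethod("gridSpacing", "GridBacked", function(x) x@spacing)

#' @rdname gridSpacing
setMethod("gridOrigin", "GridBacked", function(x) x@origin)

#' @rdname gridSpacing
setMethod("gridDim", "VolumeGrid", function(x) dim(x@data))

#' @rdname gridSpacing
setMethod("gridDim", "DisplacementField", function(x) dim(x@data)[1:3])

#' @rdname gridSpacing
setMethod("voxelData", "VolumeGrid", function(x) x@data)

#' @rdname gridSpacing
setMethod("voxelData", "DisplacementField", function(x) x@data)

#' @rdname gridSpacing
setMethod("phaseIndex", "DisplacementField", function(x) x@phaseIndex)

.asPointMatrix <- function(p) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
    if (ncol(p) != 3L) stop("expected 3 columns (x, y, z)")
    p
}

#' @rdname indexToWorld
setMethod("indexToWorld", "GridBacked", function(x, idx) {
    idx <- .asPointMatrix(idx)
    sweep(sweep(idx - 1, 2L, x@spacing, "*"), 2L, x@origin, "+")
})

#' @rdname indexToWorld
setMethod("worldToIndex", "GridBacked", function(x, pts) {
    pts <- .asPointMatrix(pts)
    sweep(sweep(pts, 2L, x@origin, "-"), 2L, x@spacing, "/") + 1
})

#' @rdname nPhases
setMethod("nPhases", "MotionParams", function(x) x@nPhases)

#' @rdname nPhases
setMethod("nPhases", "SurfaceSequence", function(x) length(x@surfaces))

#' @rdname nPhases
setMethod("phaseTimes", "MotionParams", function(x) x@phaseTimes)

#' @rdname nPhases
setMethod("phaseTimes", "SurfaceSequence", function(x) x@times)

#' @rdname linePoints
setMethod("linePoints", "Centerline", function(x) x@points)

#' @rdname linePoints
setMethod("arcLength", "Centerline", function(x) x@arcLength)

#' @rdname linePoints
setMethod("arcLength", "NurbsSurface", function(x) x@arcLength)

#' @rdname controlNet
setMethod("controlNet", "NurbsSurface", function(x) x@controlNet)

#' @rdname controlNet
setMethod("sectionCenters", "NurbsSurface", function(x) x@centers)

#' @rdname controlNet
setMethod("shellLevels", "ShellStack", function(x) x@p)

# ---- show methods --------------------------------------------------------

.fmt3 <- function(v) paste(signif(v, 6), collapse = " x ")

setMethod("show", "VolumeGrid", function(object) {
    cat(class(object), ": ", .fmt3(dim(object@data)), " voxels, spacing ",
        .fmt3(object@spacing), " mm\n", sep = "")
    cat("  origin ", paste(signif(object@origin, 6), collapse = ", "),
        " mm; range [", signif(min(object@data), 5), ", ",
        signif(max(object@data), 5), "]\n", sep = "")
})

setMethod("show", "DisplacementField", function(object) {
    mag <- sqrt(rowSums(matrix(object@data, ncol = 3L)^2))
    cat("DisplacementField (phase ", object@phaseIndex, "): ",
        .fmt3(dim(object@data)[1:3]), " voxels, spacing ",
        .fmt3(object@spacing), " mm\n", sep = "")
    cat("  |u|: mean ", signif(mean(mag), 4), " mm, max ",
        signif(max(mag), 4), " mm, nonzero ",
        sum(mag > 0), " voxels\n", sep = "")
})

setMethod("show", "Centerline", function(object) {
    cat("Centerline: ", nrow(object@points), " points, length ",
        signif(max(object@arcLength), 6), " mm\n", sep = "")
})

setMethod("show", "SkeletonGraph", function(object) {
    cat("SkeletonGraph: ", nrow(object@voxels), " voxels, ",
        nrow(object@edges), " edges\n", sep = "")
})

setMethod("show", "NurbsSurface", function(object) {
    d <- dim(object@controlNet)
    cat("NurbsSurface: ", d[1], " sections x ", d[2],
        " points, degrees (", object@degreeU, ", ", object@degreeV,
        "), length ", signif(max(object@arcLength), 6), " mm\n", sep = "")
})

setMethod("show", "ShellStack", function(object) {
    cat("ShellStack: ", length(object@surfaces), " shells at p = ",
        paste(signif(object@p, 3), collapse = ", "), "\n", sep = "")
})

setMethod("show", "MotionParams", function(object) {
    cat("MotionParams: A = ", object@amplitude, " mm, lambda = ",
        object@wavelength, " mm, c = ", object@speed, " mm/s, alpha = ",
        object@attenuation, " (", object@dispersionDomain, "), ",
        object@nPhases, " phases over ",
        signif(max(object@phaseTimes), 5), " s\n", sep = "")
})

setMethod("show", "SurfaceSequence", function(object) {
    cat("SurfaceSequence: ", length(object@surfaces), " phases, t = 0 .. ",
        signif(max(object@times), 5), " s\n", sep = "")
})

setMethod("show", "ShellSampleSet", function(object) {
    v <- object@deformed - object@original
    mag <- sqrt(rowSums(v^2))
    cat("ShellSampleSet: ", nrow(object@original), " samples on ",
        length(unique(object@p)), " shells; |V| mean ",
        signif(mean(mag), 4), " mm, max ", signif(max(mag), 4),
        " mm\n", sep = "")
})

setMethod("show", "EvalReport", function(object) {
    cat("EvalReport\n")
    m <- object@metrics
    for (nm in names(m))
        cat("  ", nm, ": ", signif(m[[nm]][1], 5), "\n", sep = "")
    if (nrow(object@rmseByMotion))
        cat("  RMSE by motion bin: ", nrow(object@rmseByMotion),
            " bins\n", sep = "")
    if (nrow(object@rmseByDose))
        cat("  RMSE by dose bin: ", nrow(object@rmseByDose),
            " bins\n", sep = "")
})
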