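#' @include gitwin-package.R
NULL

# ---- grid-backed volumes -------------------------------------------------

#' Virtual parent for objects carrying voxel-grid geometry
#'
#' Holds the voxel spacing (mm/voxel) and the world coordinate of the first
#' voxel centre (mm). The package-wide convention: voxel indices are the
#' usual 1-based R indices, the world coordinate of voxel \code{i} is
#' \code{origin + (i - 1) * spacing}, axes are stored x (fastest), y, z
#' (slowest), and direction cosines are the identity.
#'
#' @slot spacing numeric(3), mm per voxel, strictly positive.
#' @slot origin numeric(3), mm, world position of voxel (1,1,1).
#' @keywords internal
setClass("GridBacked", representation("VIRTUAL",
    spacing = "numeric", origin = "numeric"))

.validGeometry <- function(object) {
    msg <- character()
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 strictly positive finite numbers")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "origin must be 3 finite numbers")
    msg
}

#' A 3D scalar volume on a regular grid
#'
#' The basic container for images and dose maps: a 3D array plus voxel
#' spacing and origin in mm. See \linkS4class{GridBacked} for the coordinate
#' convention.
#'
#' @slot data 3D numeric array (modality units, or Gy for dose maps).
#' @slot spacing,origin grid geometry, mm.
#' @export
setClass("VolumeGrid", contains = "GridBacked",
    representation(data = "array"))

setValidity("VolumeGrid", function(object) {
    msg <- .validGeometry(object)
    if (length(dim(object@data)) != 3L)
        msg <- c(msg, "data must be a 3D array")
    if (length(msg)) msg else TRUE
})

#' Binary organ mask
#'
#' A \linkS4class{VolumeGrid} whose voxels are restricted to {0, 1}.
#'
#' @export
setClass("LabelMask", contains = "VolumeGrid")

setValidity("LabelMask", function(object) {
    v <- unique(as.vector(object@data))
    if (!all(v %in% c(0, 1)))
        "mask voxels must all be 0 or 1"
    else TRUE
})

#' Dense displacement field for one motion phase
#'
#' Per-voxel 3-vectors of displacement in mm, expressed along the world
#' axes, stored as a 4D array with the vector component last. Vectors are
#' anchored at the undeformed voxel position (a forward / push-forward map).
#'
#' @slot data 4D numeric array, \code{dim = c(nx, ny, nz, 3)}, mm.
#' @slot phaseIndex integer >= 0 identifying the motion phase.
#' @slot info list of provenance (smoothing iterations, coverage, ...).
#' @export
setClass("DisplacementField", contains = "GridBacked",
    representation(data = "array", phaseIndex = "integer", info = "list"),
    prototype(phaseIndex = 0L, info = list()))

setValidity("DisplacementField", function(object) {
    msg <- .validGeometry(object)
    d <- dim(object@data)
    if (length(d) != 4L || d[4] != 3L)
        msg <- c(msg, "data must be a 4D array with 3 vector components")
    if (any(!is.finite(object@data)))
        msg <- c(msg, "displacements must be finite everywhere")
    if (length(object@phaseIndex) != 1L || object@phaseIndex < 0L)
        msg <- c(msg, "phaseIndex must be a single non-negative integer")
    if (length(msg)) msg else TRUE
})

#' Log-Jacobian determinant map of a displacement field
#'
#' Voxelwise \code{log det(I + grad u)}. Voxels where the determinant is
#' non-positive (local folding) are NaN and counted in \code{folded}.
#'
#' @slot folded integer, number of folded voxels.
#' @export
setClass("JacobianMap", contains = "VolumeGrid",
    representation(folded = "integer"), prototype(folded = 0L))

# ---- curves and surfaces -------------------------------------------------

#' Organ centerline
#'
#' An ordered polyline of world-mm points with cumulative arc length. After
#' equidistant resampling, consecutive arc-length steps are constant except
#' possibly the final segment.
#'
#' @slot points n x 3 matrix of world coordinates, mm.
#' @slot arcLength numeric(n), strictly increasing cumulative arc length, mm.
#' @export
setClass("Centerline",
    representation(points = "matrix", arcLength = "numeric"))

setValidity("Centerline", function(object) {
    msg <- character()
    if (ncol(object@points) != 3L || !is.numeric(object@points) ||
        any(!is.finite(object@points)))
        msg <- c(msg, "points must be a finite n x 3 numeric matrix")
    if (length(object@arcLength) != nrow(object@points))
        msg <- c(msg, "arcLength must have one entry per point")
    if (length(object@arcLength) > 1L && any(diff(object@arcLength) <= 0))
        msg <- c(msg, "arcLength must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' Thinned-skeleton adjacency graph
#'
#' Voxels surviving topology-preserving 3D thinning of a mask, with edges
#' joining 26-adjacent skeleton voxels. \code{boundaryDist} carries each
#' skeleton voxel's distance (mm) to the mask boundary, used to break
#' skeleton cycles.
#'
#' @slot voxels n x 3 integer matrix of 1-based voxel indices.
#' @slot edges m x 2 integer matrix of row indices into \code{voxels}.
#' @slot boundaryDist numeric(n), mm.
#' @export
setClass("SkeletonGraph", contains = "GridBacked",
    representation(voxels = "matrix", edges = "matrix",
                   boundaryDist = "numeric"))

#' One radial cross-section of an organ
#'
#' Boundary points cast from a centerline point in its orthogonal plane;
#' the control points of one row of the NURBS net.
#'
#' @slot center,tangent,normal,binormal numeric(3): section frame, mm /
#'   unit vectors (rotation-minimizing frames along the centerline).
#' @slot boundary J x 3 matrix of boundary points, mm.
#' @slot radii numeric(J), mm, distance of each boundary point to center.
#' @slot arc scalar arc-length station of the section along the organ, mm.
#' @export
setClass("SectionalCurve",
    representation(center = "numeric", tangent = "numeric",
                   normal = "numeric", binormal = "numeric",
                   boundary = "matrix", radii = "numeric", arc = "numeric"))

setValidity("SectionalCurve", function(object) {
    msg <- character()
    if (any(object@radii <= 0)) msg <- c(msg, "radii must be positive")
    if (nrow(object@boundary) != length(object@radii))
        msg <- c(msg, "boundary and radii disagree in length")
    if (length(msg)) msg else TRUE
})

#' Tubular NURBS (B-spline) surface
#'
#' Tensor-product surface over an I x J control net: clamped cubic along
#' the organ (u), periodic cubic around each section (v), all weights 1.
#' Rows of the net are the sectional-curve boundary points; \code{centers}
#' and \code{arcLength} keep each row's centerline station, which the motion
#' model and shell interpolation act on.
#'
#' @slot controlNet array \code{c(I, J, 3)}, mm.
#' @slot centers I x 3 matrix of section centers, mm.
#' @slot arcLength numeric(I), arc-length station per section, mm.
#' @slot degreeU,degreeV spline degrees (3, 3).
#' @export
setClass("NurbsSurface",
    representation(controlNet = "array", centers = "matrix",
                   arcLength = "numeric", degreeU = "integer",
                   degreeV = "integer"),
    prototype(degreeU = 3L, degreeV = 3L))

setValidity("NurbsSurface", function(object) {
    msg <- character()
    d <- dim(object@controlNet)
    if (length(d) != 3L || d[3] != 3L)
        msg <- c(msg, "controlNet must be an I x J x 3 array")
    else {
        if (nrow(object@centers) != d[1])
            msg <- c(msg, "centers must have one row per section")
        if (length(object@arcLength) != d[1])
            msg <- c(msg, "arcLength must have one entry per section")
        if (d[1] < object@degreeU + 1L)
            msg <- c(msg, "need at least degreeU + 1 sections")
        if (d[2] < object@degreeV + 1L)
            msg <- c(msg, "need at least degreeV + 1 points per section")
    }
    if (length(msg)) msg else TRUE
})

#' Radial stack of shell surfaces
#'
#' Surfaces interpolated between the organ surface (radial factor p = 0)
#' and its centerline (p = 1), used to carry the surface deformation into
#' the organ interior.
#'
#' @slot surfaces list of \linkS4class{NurbsSurface}, one per level.
#' @slot p numeric, radial factors in [0, 1], increasing.
#' @export
setClass("ShellStack",
    representation(surfaces = "list", p = "numeric"))

setValidity("ShellStack", function(object) {
    msg <- character()
    if (length(object@surfaces) != length(object@p))
        msg <- c(msg, "one surface per radial factor required")
    if (any(object@p < 0 | object@p > 1))
        msg <- c(msg, "radial factors must lie in [0, 1]")
    if (is.unsorted(object@p, strictly = TRUE))
        msg <- c(msg, "radial factors must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' Corresponding surface samples before and after deformation
#'
#' Points sampled on a uniform (u, v) grid of every shell in the original
#' and deformed configuration; the per-sample displacement is
#' \code{deformed - original}.
#'
#' @slot original,deformed n x 3 matrices of world-mm points.
#' @slot u,v,p numeric(n), parameter coordinates of each sample.
#' @export
setClass("ShellSampleSet",
    representation(original = "matrix", deformed = "matrix",
                   u = "numeric", v = "numeric", p = "numeric"))

setValidity("ShellSampleSet", function(object) {
    if (!identical(dim(object@original), dim(object@deformed)))
        return("original and deformed must have identical dimensions")
    if (any(!is.finite(object@original)) || any(!is.finite(object@deformed)))
        return("sample points must be finite")
    TRUE
})

# ---- motion --------------------------------------------------------------

#' Peristaltic traveling-wave motion parameters
#'
#' The wave displaces each sectional curve radially by
#' \code{(A / sqrt(3)) * sin(2 * pi * (L - c * t) / lambda)}, optionally
#' attenuated by \code{exp(-alpha * u)} in the spatial (u = arc length) or
#' temporal (u = t) domain.
#'
#' @slot amplitude A, mm.
#' @slot wavelength lambda, mm.
#' @slot speed c, mm/s.
#' @slot attenuation alpha, 1/mm (spatial) or 1/s (temporal).
#' @slot nPhases number of motion phases synthesized.
#' @slot phaseTimes numeric(nPhases), seconds, strictly increasing, first 0.
#' @slot dispersionDomain one of "none", "spatial", "temporal".
#' @export
setClass("MotionParams",
    representation(amplitude = "numeric", wavelength = "numeric",
                   speed = "numeric", attenuation = "numeric",
                   nPhases = "integer", phaseTimes = "numeric",
                   dispersionDomain = "character"))

setValidity("MotionParams", function(object) {
    msg <- character()
    if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
    if (object@wavelength <= 0) msg <- c(msg, "wavelength must be > 0")
    if (object@speed <= 0) msg <- c(msg, "speed must be > 0")
    if (object@attenuation < 0) msg <- c(msg, "attenuation must be >= 0")
    if (object@nPhases < 1L) msg <- c(msg, "nPhases must be >= 1")
    if (length(object@phaseTimes) != object@nPhases)
        msg <- c(msg, "phaseTimes must have nPhases entries")
    else {
        if (object@phaseTimes[1] != 0)
            msg <- c(msg, "first phase time must be 0")
        if (object@nPhases > 1L && any(diff(object@phaseTimes) <= 0))
            msg <- c(msg, "phaseTimes must be strictly increasing")
    }
    if (!object@dispersionDomain %in% c("none", "spatial", "temporal"))
        msg <- c(msg, "dispersionDomain must be none, spatial or temporal")
    if (length(msg)) msg else TRUE
})

#' Sequence of deformed surfaces, one per motion phase
#'
#' @slot surfaces list of \linkS4class{NurbsSurface} (deformed outer nets).
#' @slot times numeric, phase times in seconds.
#' @slot params the \linkS4class{MotionParams} that generated the sequence.
#' @export
setClass("SurfaceSequence",
    representation(surfaces = "list", times = "numeric",
                   params = "MotionParams"))

# ---- evaluation ----------------------------------------------------------

#' Evaluation report for a candidate displacement field
#'
#' @slot metrics one-row data.frame of summary metrics (TRE mean/sd, DSC,
#'   HD95, DWE, log-Jacobian mean/sd).
#' @slot rmseByMotion data.frame: RMSE of the displacement error binned by
#'   ground-truth motion magnitude (mm).
#' @slot rmseByDose data.frame: RMSE binned by dose (Gy); empty when no dose
#'   map was supplied.
#' @slot info list: error heatmap volume, settings, counts.
#' @export
setClass("EvalReport",
    representation(metrics = "data.frame", rmseByMotion = "data.frame",
                   rmseByDose = "data.frame", info = "list"))
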