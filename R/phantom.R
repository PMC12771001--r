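#' @include volio.R
NULL

#' Synthetic curved-tube phantom specification
#'
#' Defines a tubular "organ" (a swept sphere along a 3D path with a
#' possibly varying radius) inside a voxel grid, plus the intensity model
#' used to render it. Stands in for a patient scan so the full motion
#' pipeline is testable without any external data.
#'
#' @slot name preset name or "custom".
#' @slot shape integer(3) grid size in voxels.
#' @slot spacing,origin grid geometry, mm.
#' @slot pathPoints dense n x 3 polyline of the tube axis, world mm.
#' @slot pathRadii numeric(n) tube radius at each path point, mm.
#' @slot levels named numeric: \code{lumen}, \code{wall}, \code{background}
#'   intensity levels.
#' @slot lumenFrac fraction of the local radius occupied by the lumen.
#' @slot noiseSd Gaussian intensity noise standard deviation.
#' @slot marginMm minimum clearance required between the tube surface and
#'   the grid boundary (amplitude headroom so that voxelized motion never
#'   clips).
#' @slot seed RNG seed for the intensity noise.
#' @export
setClass("PhantomSpec",
    representation(name = "character", shape = "integer",
                   spacing = "numeric", origin = "numeric",
                   pathPoints = "matrix", pathRadii = "numeric",
                   levels = "numeric", lumenFrac = "numeric",
                   noiseSd = "numeric", marginMm = "numeric",
                   seed = "integer"))

setValidity("PhantomSpec", function(object) {
    msg <- character()
    if (length(object@shape) != 3L || any(object@shape < 4L))
        msg <- c(msg, "shape must be 3 integers >= 4")
    if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
    if (nrow(object@pathPoints) < 2L)
        msg <- c(msg, "path needs at least 2 points")
    if (length(object@pathRadii) != nrow(object@pathPoints))
        msg <- c(msg, "one radius per path point required")
    if (any(object@pathRadii <= 0)) msg <- c(msg, "radii must be positive")
    if (!all(c("lumen", "wall", "background") %in% names(object@levels)))
        msg <- c(msg, "levels must name lumen, wall and background")
    if (object@lumenFrac < 0 || object@lumenFrac >= 1)
        msg <- c(msg, "lumenFrac must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PhantomSpec", function(object) {
    cat("PhantomSpec '", object@name, "': ", .fmt3(object@shape),
        " voxels at ", .fmt3(object@spacing), " mm; tube length ",
        signif(max(.polylineArc(object@pathPoints)), 5), " mm, radius ",
        signif(min(object@pathRadii), 4), "-",
        signif(max(object@pathRadii), 4), " mm\n", sep = "")
})

.polylineArc <- function(pts) {
    seg <- sqrt(rowSums(diff(pts)^2))
    c(0, cumsum(seg))
}

# Resample a polyline (with optional per-point scalars) to a given
# arc-length step; endpoints always kept.
.resamplePolyline <- function(pts, step, scalars = NULL) {
    arc <- .polylineArc(pts)
    L <- max(arc)
    targets <- seq(0, L, by = step)
    if (L - targets[length(targets)] > 1e-9) targets <- c(targets, L)
    out <- vapply(1:3, function(a) approx(arc, pts[, a], targets)$y,
                  numeric(length(targets)))
    res <- list(points = out, arc = targets)
    if (!is.null(scalars))
        res$scalars <- approx(arc, scalars, targets)$y
    res
}

#' Construct a phantom specification
#'
#' @param pathPoints n x 3 matrix tracing the tube axis (world mm).
#' @param pathRadii tube radius per path point, mm (recycled if scalar).
#' @param shape integer(3) grid size.
#' @param spacing numeric(3) voxel size, mm.
#' @param origin numeric(3), mm.
#' @param levels named intensity levels (lumen, wall, background).
#' @param lumenFrac lumen fraction of the local radius.
#' @param noiseSd Gaussian noise sd.
#' @param marginMm required tube-to-edge clearance, mm.
#' @param seed RNG seed for noise.
#' @param name label.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(pathPoints, pathRadii, shape, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0),
                        levels = c(lumen = 50, wall = 300, background = 100),
                        lumenFrac = 0.55, noiseSd = 0, marginMm = 0,
                        seed = 7L, name = "custom") {
    if (length(pathRadii) == 1L) pathRadii <- rep(pathRadii, nrow(pathPoints))
    new("PhantomSpec", name = name, shape = as.integer(shape),
        spacing = as.numeric(spacing), origin = as.numeric(origin),
        pathPoints = pathPoints, pathRadii = as.numeric(pathRadii),
        levels = levels, lumenFrac = lumenFrac, noiseSd = noiseSd,
        marginMm = marginMm, seed = as.integer(seed))
}

#' Named phantom presets
#'
#' Two desk-scale stand-ins for the organ geometries the motion model
#' animates: \describe{
#'   \item{stomach}{a C-shaped arc with the tube radius tapering from 12 mm
#'     down to 6 mm, on a 96^3 grid at 2 mm spacing;}
#'   \item{bowel}{a three-quarter torus arc of constant 8 mm radius on the
#'     same grid.}
#' }
#' Both keep the tube surface at least \code{marginMm} (default 20 mm: the
#' 16 mm wave amplitude plus two voxels) away from the grid edge.
#'
#' @param name "stomach" or "bowel".
#' @param shape,spacing grid geometry.
#' @param noiseSd intensity noise sd.
#' @param seed RNG seed for the intensity noise.
#' @return a \linkS4class{PhantomSpec}.
#' @examples
#' spec <- phantomPreset("stomach")
#' spec
#' @export
phantomPreset <- function(name = c("stomach", "bowel"),
                          shape = c(96L, 96L, 96L), spacing = c(2, 2, 2),
                          noiseSd = 10, seed = 7L) {
    name <- match.arg(name)
    ctr <- (shape - 1) * spacing / 2
    s <- seq(0, 1, length.out = 257L)
    # organs terminate: taper the radius toward both ends so the tube stays
    # within the domain of the sectional model (no unmodeled spherical caps)
    taper <- pmin(1, s / 0.12, (1 - s) / 0.12)
    if (name == "stomach") {
        theta <- (-10 + 200 * s) * pi / 180
        rc <- 45
        pts <- cbind(ctr[1] + rc * cos(theta),
                     ctr[2] + rc * sin(theta),
                     ctr[3] + 12 * (s - 0.5))
        radii <- 2.5 + (12 - 6 * s - 2.5) * taper
    } else {
        theta <- 2 * pi * 0.75 * s
        rc <- 55
        pts <- cbind(ctr[1] + rc * cos(theta),
                     ctr[2] + rc * sin(theta),
                     ctr[3] + 6 * sin(2 * theta))
        radii <- 2.5 + (8 - 2.5) * taper
    }
    phantomSpec(pts, radii, shape = shape, spacing = spacing,
                noiseSd = noiseSd, marginMm = 16 + 2 * max(spacing),
                seed = seed, name = name)
}

#' Ground-truth tube axis of a phantom
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a \linkS4class{Centerline} tracing the true tube path (the
#'   oracle for centerline extraction).
#' @export
tubePath <- function(spec) {
    new("Centerline", points = spec@pathPoints,
        arcLength = .polylineArc(spec@pathPoints))
}

# Relative radial coordinate of every voxel. Two semantics:
#  - swept (default): min over path samples of (distance / local radius),
#    the union-of-balls tube used to generate phantoms;
#  - sectional: distance to the NEAREST axis point divided by the radius
#    there, i.e. each cross-section judged on its own station. This is the
#    analytic counterpart of the motion model, which deforms sectional
#    curves independently; with a swept rule a strongly expanded section
#    would smear its radius +/- R along the axis.
# <= 1 inside the tube, Inf far away.
.tubeRho <- function(spec, radiusOverride = NULL, sectional = FALSE) {
    dm <- spec@shape
    sp <- spec@spacing
    org <- spec@origin
    radii <- if (is.null(radiusOverride)) spec@pathRadii else radiusOverride
    res <- .resamplePolyline(spec@pathPoints, min(sp) / 2, radii)
    pts <- res$points
    rad <- pmax(res$scalars, 1e-6)
    searchR <- if (sectional) rep(max(rad), length(rad)) + min(sp) else rad
    rho <- array(Inf, dm)
    dmin <- array(Inf, dm)
    ax <- lapply(1:3, function(a) org[a] + (seq_len(dm[a]) - 1) * sp[a])
    for (k in seq_len(nrow(pts))) {
        p <- pts[k, ]
        r <- searchR[k]
        lo <- pmax(ceiling((p - r - org) / sp) + 1, 1)
        hi <- pmin(floor((p + r - org) / sp) + 1, dm)
        if (any(lo > hi)) next
        ixs <- lapply(1:3, function(a) lo[a]:hi[a])
        dx2 <- (ax[[1]][ixs[[1]]] - p[1])^2
        dy2 <- (ax[[2]][ixs[[2]]] - p[2])^2
        dz2 <- (ax[[3]][ixs[[3]]] - p[3])^2
        d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
        if (sectional) {
            sub <- dmin[ixs[[1]], ixs[[2]], ixs[[3]]]
            closer <- d < sub
            subRho <- rho[ixs[[1]], ixs[[2]], ixs[[3]]]
            subRho[closer] <- d[closer] / rad[k]
            dmin[ixs[[1]], ixs[[2]], ixs[[3]]] <- pmin(sub, d)
            rho[ixs[[1]], ixs[[2]], ixs[[3]]] <- subRho
        } else {
            sub <- rho[ixs[[1]], ixs[[2]], ixs[[3]]]
            rho[ixs[[1]], ixs[[2]], ixs[[3]]] <- pmin(sub, d / rad[k])
        }
    }
    rho
}

#' Voxelize the phantom tube into a binary mask
#'
#' A voxel is foreground when its centre lies within the local tube radius
#' of the axis. Errors when the tube violates the edge-margin rule or the
#' radius is below voxel resolution.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param radiusOverride optional numeric vector replacing the spec's
#'   per-path-point radii (used to build analytically deformed tubes).
#' @param allowCollapse skip the sub-voxel-radius error; segments whose
#'   radius falls below voxel resolution simply produce no voxels (used for
#'   analytically contracted tubes whose lumen may close completely).
#' @param sectional judge each voxel against the radius at its nearest
#'   axis station (the analytic counterpart of sectional-curve deformation)
#'   instead of the swept union-of-balls rule.
#' @return a \linkS4class{LabelMask}.
#' @export
makeTubeMask <- function(spec, radiusOverride = NULL,
                         allowCollapse = FALSE, sectional = FALSE) {
    validObject(spec)
    radii <- if (is.null(radiusOverride)) spec@pathRadii else radiusOverride
    if (length(radii) != nrow(spec@pathPoints))
        stop("radiusOverride must have one radius per path point")
    if (!allowCollapse && min(radii) < max(spec@spacing) / 2)
        stop("sub-voxel tube: minimum radius ", signif(min(radii), 3),
             " mm is below half the voxel size")
    lo <- spec@origin
    hi <- spec@origin + (spec@shape - 1) * spec@spacing
    clearance <- pmin(
        apply(sweep(spec@pathPoints, 2L, lo, "-"), 1L, min),
        apply(sweep(-spec@pathPoints, 2L, -hi, "-"), 1L, min))
    margin <- if (allowCollapse) 0 else spec@marginMm  # deformed comparator
    if (any(clearance - radii < margin))
        stop("tube exits grid or violates the ", margin,
             " mm edge margin (min clearance ",
             signif(min(clearance - radii), 4), " mm)")
    rho <- .tubeRho(spec, radii, sectional = sectional)
    LabelMask(array(as.numeric(rho <= 1), spec@shape), spec@spacing,
              spec@origin)
}

#' Render the phantom intensity volume
#'
#' Three intensity levels (lumen, wall, background) set by the relative
#' radial coordinate, plus seeded Gaussian noise; deterministic given the
#' spec's seed.
#'
#' @param mask the tube mask from [makeTubeMask()] (grid must match spec).
#' @param spec the \linkS4class{PhantomSpec}.
#' @return a \linkS4class{VolumeGrid}.
#' @export
makePhantomImage <- function(mask, spec) {
    if (!all(gridDim(mask) == spec@shape) ||
        !all(abs(gridSpacing(mask) - spec@spacing) < 1e-9))
        stop("mask grid does not match the phantom spec")
    rho <- .tubeRho(spec)
    img <- array(spec@levels[["background"]], spec@shape)
    img[rho <= 1] <- spec@levels[["wall"]]
    img[rho <= spec@lumenFrac] <- spec@levels[["lumen"]]
    if (spec@noiseSd > 0)
        img <- img + .withSeed(spec@seed,
            array(rnorm(prod(spec@shape), sd = spec@noiseSd), spec@shape))
    VolumeGrid(img, spec@spacing, spec@origin)
}

#' Synthetic Gaussian dose map
#'
#' An isotropic Gaussian dose blob. The centre is snapped to the nearest
#' voxel centre so the maximum equals \code{peakGy} exactly.
#'
#' @param grid any grid-backed object defining the geometry.
#' @param centerMm numeric(3), requested blob centre, world mm.
#' @param peakGy peak dose, Gy (> 0).
#' @param sigmaMm Gaussian standard deviation, mm.
#' @return a \linkS4class{VolumeGrid} in Gy.
#' @export
makeDoseMap <- function(grid, centerMm, peakGy, sigmaMm) {
    stopifnot(peakGy > 0, sigmaMm > 0)
    dm <- gridDim(grid)
    sp <- gridSpacing(grid)
    org <- gridOrigin(grid)
    ctr <- org + (pmin(pmax(round((centerMm - org) / sp), 0),
                       dm - 1)) * sp
    ax <- lapply(1:3, function(a) org[a] + (seq_len(dm[a]) - 1) * sp[a])
    d2 <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, "+"),
                (ax[[3]] - ctr[3])^2, "+")
    VolumeGrid(peakGy * exp(-d2 / (2 * sigmaMm^2)), sp, org)
}
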