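#' @include methods.R
NULL

# Distance (mm) from every voxel centre to the nearest foreground voxel
# centre of `mask` (0 inside the foreground). Spacing-aware exact EDT.
.edt <- function(mask) {
    d <- sqrt(edt3d_cpp(as.logical(voxelData(mask) > 0), gridDim(mask),
                        gridSpacing(mask)))
    array(d, gridDim(mask))
}

# Signed distance to the mask boundary: positive inside, negative outside,
# zero crossing midway between foreground and background voxel centres.
.signedDistance <- function(mask) {
    fg <- voxelData(mask) > 0
    dm <- dim(fg)
    sp <- gridSpacing(mask)
    dToFg <- sqrt(edt3d_cpp(as.logical(fg), dm, sp))
    dToBg <- sqrt(edt3d_cpp(as.logical(!fg), dm, sp))
    array(dToBg - dToFg, dm)
}

#' Dilate a binary mask by a metric radius
#'
#' Spherical (spacing-aware) dilation: a voxel joins the foreground when its
#' centre lies within \code{radiusMm} of a foreground voxel centre.
#'
#' @param mask a \linkS4class{LabelMask}.
#' @param radiusMm dilation radius in mm.
#' @return a \linkS4class{LabelMask}.
#' @export
dilateMask <- function(mask, radiusMm) {
    stopifnot(radiusMm >= 0)
    d <- .edt(mask)
    LabelMask(array(as.numeric(d <= radiusMm), gridDim(mask)),
              gridSpacing(mask), gridOrigin(mask))
}

#' Boundary voxels of a binary mask
#'
#' Foreground voxels with at least one 6-neighbor in the background (the
#' array border counts as background).
#'
#' @param mask a \linkS4class{LabelMask}.
#' @return a \linkS4class{LabelMask} of boundary voxels.
#' @export
boundaryVoxels <- function(mask) {
    fg <- voxelData(mask) > 0
    dm <- dim(fg)
    hasBgNb <- array(FALSE, dm)
    for (axis in 1:3) for (s in c(-1L, 1L)) {
        nb <- .shiftArray(fg, axis, s, fill = FALSE)
        hasBgNb <- hasBgNb | !nb
    }
    LabelMask(array(as.numeric(fg & hasBgNb), dm), gridSpacing(mask),
              gridOrigin(mask))
}

# Shift a 3D (or 4D, first-3-axes) array by one voxel along `axis`;
# s = +1 brings the neighbor at index+1 into each cell. `fill` pads.
.shiftArray <- function(a, axis, s, fill = 0) {
    dm <- dim(a)
    n <- dm[axis]
    idx <- rep(list(quote(expr = )), length(dm))
    out <- array(fill, dm)
    src <- if (s > 0) 2:n else 1:(n - 1)
    dst <- if (s > 0) 1:(n - 1) else 2:n
    idxSrc <- idx; idxSrc[[axis]] <- src
    idxDst <- idx; idxDst[[axis]] <- dst
    out <- do.call(`[<-`, c(list(out), idxDst,
                            list(do.call(`[`, c(list(a), idxSrc)))))
    out
}

# Fractional (1-based) grid coordinates of world points, snapped to exact
# integers when within 1e-7 voxel so that voxel-centre queries are exact.
.gridCoords <- function(spacing, origin, pts) {
    t <- sweep(sweep(pts, 2L, origin, "-"), 2L, spacing, "/") + 1
    r <- round(t)
    snap <- abs(t - r) < 1e-7
    t[snap] <- r[snap]
    t
}

# Trilinear interpolation weights for world points on a grid with border
# replication. Returns 8 linear indices and weights per point.
.interpWeights <- function(dm, spacing, origin, pts) {
    t <- .gridCoords(spacing, origin, pts)
    for (a in 1:3) t[, a] <- pmin(pmax(t[, a], 1), dm[a])
    i0 <- floor(t)
    for (a in 1:3) i0[, a] <- pmin(i0[, a], dm[a] - 1)
    i0[i0 < 1] <- 1
    f <- t - i0
    f[f < 0] <- 0; f[f > 1] <- 1
    nx <- dm[1]; nxy <- dm[1] * dm[2]
    base <- (i0[, 1]) + nx * (i0[, 2] - 1) + nxy * (i0[, 3] - 1)
    n <- nrow(pts)
    ix <- matrix(0, n, 8L)
    w <- matrix(0, n, 8L)
    k <- 0L
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        k <- k + 1L
        ix[, k] <- base + dx + nx * dy + nxy * dz
        w[, k] <- (if (dx) f[, 1] else 1 - f[, 1]) *
                  (if (dy) f[, 2] else 1 - f[, 2]) *
                  (if (dz) f[, 3] else 1 - f[, 3])
    }
    list(ix = ix, w = w)
}

# Trilinearly sample a 3D array at world points (n x 3), border-replicated.
.sampleTrilinear <- function(data, spacing, origin, pts, weights = NULL) {
    if (is.null(weights))
        weights <- .interpWeights(dim(data), spacing, origin, pts)
    vals <- matrix(data[weights$ix], ncol = 8L)
    rowSums(vals * weights$w)
}

# Nearest-neighbor sample of a 3D array at world points.
.sampleNearest <- function(data, spacing, origin, pts) {
    dm <- dim(data)
    t <- .gridCoords(spacing, origin, pts)
    i <- round(t)
    for (a in 1:3) i[, a] <- pmin(pmax(i[, a], 1), dm[a])
    data[i[, 1] + dm[1] * (i[, 2] - 1) + dm[1] * dm[2] * (i[, 3] - 1)]
}

# Sample a displacement field (4D, comp last) at world points -> n x 3 mm.
.sampleField <- function(field, pts) {
    dm <- gridDim(field)
    weights <- .interpWeights(dm, gridSpacing(field), gridOrigin(field), pts)
    u <- matrix(0, nrow(pts), 3L)
    nvox <- prod(dm)
    dat <- field@data
    for (comp in 1:3) {
        vals <- matrix(dat[weights$ix + (comp - 1) * nvox], ncol = 8L)
        u[, comp] <- rowSums(vals * weights$w)
    }
    u
}

# Evaluate an expression with a temporary RNG seed, restoring global state.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

.sameGrid <- function(a, b, tol = 1e-6) {
    all(gridDim(a) == gridDim(b)) &&
        all(abs(gridSpacing(a) - gridSpacing(b)) < tol) &&
        all(abs(gridOrigin(a) - gridOrigin(b)) < tol)
}

.stopIfGridMismatch <- function(a, b, what = "inputs") {
    if (!.sameGrid(a, b))
        stop(what, " must share one voxel grid (dim, spacing, origin)")
    invisible(TRUE)
}
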