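#' @include motion.R
NULL

#' Sample corresponding points on original and deformed shell stacks
#'
#' Both stacks are evaluated on the same uniform (u, v) grid per shell;
#' correspondence is by identical (u, v, p). The per-sample displacement is
#' \code{deformed - original}.
#'
#' @param stack original \linkS4class{ShellStack}.
#' @param deformedStack deformed \linkS4class{ShellStack} with the same
#'   radial factors and net dimensions.
#' @param nu,nv samples along / around the organ per shell.
#' @return a \linkS4class{ShellSampleSet}.
#' @export
sampleShells <- function(stack, deformedStack, nu = 200L, nv = 72L) {
    if (length(stack@surfaces) != length(deformedStack@surfaces) ||
        any(abs(stack@p - deformedStack@p) > 1e-12))
        stop("stacks must share one shell parameterization")
    d0 <- dim(stack@surfaces[[1]]@controlNet)
    d1 <- dim(deformedStack@surfaces[[1]]@controlNet)
    if (!identical(d0, d1))
        stop("stacks must share one control-net dimension")
    u <- seq(0, 1, length.out = nu)
    v <- seq(0, 1 - 1 / nv, length.out = nv)
    nPer <- nu * nv
    nAll <- nPer * length(stack@p)
    X <- matrix(0, nAll, 3L)
    Xd <- matrix(0, nAll, 3L)
    for (k in seq_along(stack@p)) {
        a <- evaluateSurface(stack@surfaces[[k]], u, v)
        b <- evaluateSurface(deformedStack@surfaces[[k]], u, v)
        rows <- (k - 1L) * nPer + seq_len(nPer)
        X[rows, ] <- matrix(a, nPer, 3L)
        Xd[rows, ] <- matrix(b, nPer, 3L)
    }
    new("ShellSampleSet", original = X, deformed = Xd,
        u = rep(rep(u, times = nv), length(stack@p)),
        v = rep(rep(v, each = nu), length(stack@p)),
        p = rep(stack@p, each = nPer))
}

#' Voxelize shell samples into a displacement field
#'
#' Each displacement vector is binned into the voxel containing its
#' original (undeformed) position; vectors landing in one voxel are
#' averaged. Voxels receiving no sample are zero.
#'
#' @param samples a \linkS4class{ShellSampleSet}.
#' @param grid grid-backed object defining the output geometry.
#' @param phaseIndex phase label for the result.
#' @return a \linkS4class{DisplacementField}; \code{info$coverage} holds
#'   the number of seeded voxels.
#' @export
voxelize <- function(samples, grid, phaseIndex = 0L) {
    dm <- gridDim(grid)
    sp <- gridSpacing(grid)
    org <- gridOrigin(grid)
    t <- .gridCoords(sp, org, samples@original)
    i <- round(t)
    bad <- i[, 1] < 1 | i[, 1] > dm[1] | i[, 2] < 1 | i[, 2] > dm[2] |
           i[, 3] < 1 | i[, 3] > dm[3]
    if (any(bad))
        stop(sum(bad), " sample(s) fall outside the voxel grid")
    lin <- i[, 1] + dm[1] * (i[, 2] - 1) + dm[1] * dm[2] * (i[, 3] - 1)
    V <- samples@deformed - samples@original
    sums <- rowsum(cbind(V, 1), lin)
    idx <- as.numeric(rownames(sums))
    dat <- array(0, c(dm, 3L))
    nvox <- prod(dm)
    for (comp in 1:3)
        dat[idx + (comp - 1) * nvox] <- sums[, comp] / sums[, 4]
    DisplacementField(dat, sp, org, phaseIndex,
                      info = list(coverage = length(idx),
                                  samples = nrow(V)))
}

#' Iteratively fill zero-motion voxels by neighbor averaging
#'
#' Seed voxels (nonzero displacement) are never altered. Initially-zero
#' voxels inside the support region are repeatedly replaced by the average
#' of their currently nonzero 6-neighbors (synchronous Jacobi updates),
#' until the mean per-voxel change drops below \code{tolMm}. In the limit
#' the filled values solve the discrete Laplace problem with the seeds as
#' Dirichlet data, so they obey the discrete maximum principle.
#'
#' @param field a \linkS4class{DisplacementField} (typically from
#'   [voxelize()]).
#' @param support \linkS4class{LabelMask} limiting where filling happens;
#'   displacement stays zero outside it. Use a dilation of the animated
#'   organ wide enough to cover the largest outward surface excursion.
#' @param tolMm convergence tolerance on the mean per-voxel update, mm.
#' @param maxIter iteration cap; exceeding it is an error reporting the
#'   residual.
#' @return the filled \linkS4class{DisplacementField};
#'   \code{info$iterations} and \code{info$residual} record convergence.
#' @export
smoothFill <- function(field, support, tolMm = 0.001, maxIter = 5000L) {
    stopifnot(tolMm > 0)
    .stopIfGridMismatch(field, support, "field and support")
    dm <- gridDim(field)
    dat <- field@data
    mag <- sqrt(dat[, , , 1]^2 + dat[, , , 2]^2 + dat[, , , 3]^2)
    seed <- mag > 0
    sup <- voxelData(support) > 0
    fill <- sup & !seed
    if (!any(fill) || !any(seed)) {
        field@info <- c(field@info, list(iterations = 0L, residual = 0))
        return(field)
    }
    # crop to the support bounding box (plus one voxel) for speed
    rng <- lapply(1:3, function(a) {
        pr <- range(which(apply(sup, a, any)))
        c(max(1L, pr[1] - 1L), min(dm[a], pr[2] + 1L))
    })
    ix <- rng[[1]][1]:rng[[1]][2]
    iy <- rng[[2]][1]:rng[[2]][2]
    iz <- rng[[3]][1]:rng[[3]][2]
    crop <- dat[ix, iy, iz, , drop = FALSE]
    dim(crop) <- c(length(ix), length(iy), length(iz), 3L)
    sol <- smoothfill_cpp(crop, as.logical(fill[ix, iy, iz]),
                          dim(crop)[1:3], tolMm, as.integer(maxIter))
    iter <- sol$iterations
    res <- sol$residual
    if (res >= tolMm)
        stop("smoothFill did not converge in ", maxIter,
             " iterations (residual ", signif(res, 4), " mm)")
    dat[ix, iy, iz, ] <- sol$field
    DisplacementField(dat, gridSpacing(field), gridOrigin(field),
                      field@phaseIndex,
                      info = c(field@info,
                               list(iterations = iter, residual = res)))
}

# Approximate inverse of a forward displacement field by fixed-point
# iteration: u_inv(x) <- -u(x + u_inv(x)).
.invertField <- function(field, iterations = 10L, tolMm = 0.05) {
    dm <- gridDim(field)
    sp <- gridSpacing(field)
    org <- gridOrigin(field)
    ax <- lapply(1:3, function(a) org[a] + (seq_len(dm[a]) - 1) * sp[a])
    pts <- cbind(rep(ax[[1]], times = dm[2] * dm[3]),
                 rep(rep(ax[[2]], each = dm[1]), times = dm[3]),
                 rep(ax[[3]], each = dm[1] * dm[2]))
    uinv <- matrix(0, nrow(pts), 3L)
    resid <- Inf
    for (k in seq_len(iterations)) {
        unew <- -.sampleField(field, pts + uinv)
        resid <- mean(sqrt(rowSums((unew - uinv)^2)))
        uinv <- unew
        if (resid < tolMm) break
    }
    list(uinv = uinv, pts = pts, residual = resid)
}

#' Warp a volume, mask or dose map with a forward displacement field
#'
#' The field follows the package convention of vectors anchored at
#' undeformed positions (a push-forward map); resampling therefore needs
#' the backward map. When the twin pipeline has built an exact backward
#' field from the shell correspondences (see [phaseField()]), pass it as
#' \code{inverse}; otherwise an approximate inverse is computed by
#' fixed-point iteration. Images and dose maps are interpolated
#' trilinearly, masks by nearest neighbor.
#'
#' @param volume a \linkS4class{VolumeGrid} (or \linkS4class{LabelMask}).
#' @param field a \linkS4class{DisplacementField} on the same grid.
#' @param kind "image", "dose" or "mask"; defaults to "mask" when given a
#'   \linkS4class{LabelMask}.
#' @param inverse optional \linkS4class{DisplacementField} holding the
#'   backward map (the preimage of voxel x is \code{x + inverse(x)}).
#' @param supersample per-axis subdivision of foreground voxels for the
#'   mask push-forward (see Details).
#' @details Masks combine two views of the deformation, both required for a
#'   voxel to be foreground: (i) membership — the backward map pulls each
#'   voxel centre to its preimage and the (trilinearly interpolated) mask
#'   must be >= 0.5 there; and (ii) coverage — the forward push of the
#'   supersampled foreground (each foreground voxel subdivided
#'   \code{supersample}^3 times, each sub-sample displaced by the field)
#'   must reach the voxel. Membership alone keeps ghost foreground in
#'   regions vacated by a contracting lumen (where the scattered backward
#'   map degenerates); coverage alone dilates every boundary by about half
#'   a sub-voxel. Their conjunction handles complete lumen collapse and
#'   strong expansion correctly, and a zero field reproduces the mask
#'   exactly.
#' @return the warped volume, same class as the input. Attribute
#'   \code{"inverseResidual"} records the fixed-point inversion residual
#'   (mm) when that route is used; a residual above half the smallest
#'   spacing triggers a warning.
#' @export
warpVolume <- function(volume, field,
                       kind = c("image", "dose", "mask"), inverse = NULL,
                       supersample = 4L) {
    if (missing(kind) && is(volume, "LabelMask")) kind <- "mask"
    else kind <- match.arg(kind)
    .stopIfGridMismatch(volume, field, "volume and field")
    if (!is.null(inverse)) {
        .stopIfGridMismatch(volume, inverse, "volume and inverse field")
        dm <- gridDim(volume)
        sp <- gridSpacing(volume)
        org <- gridOrigin(volume)
        ax <- lapply(1:3, function(a) org[a] + (seq_len(dm[a]) - 1) * sp[a])
        pts <- cbind(rep(ax[[1]], times = dm[2] * dm[3]),
                     rep(rep(ax[[2]], each = dm[1]), times = dm[3]),
                     rep(ax[[3]], each = dm[1] * dm[2]))
        inv <- list(pts = pts,
                    uinv = matrix(inverse@data, ncol = 3L),
                    residual = 0)
    } else {
        inv <- .invertField(field)
        if (inv$residual > 0.5 * min(gridSpacing(volume)))
            warning("field inversion residual ", signif(inv$residual, 3),
                    " mm exceeds half a voxel; the warp may be inaccurate")
    }
    src <- inv$pts + inv$uinv
    dat <- voxelData(volume)
    vals <- .sampleTrilinear(dat, gridSpacing(volume), gridOrigin(volume),
                             src)
    if (kind == "mask") {
        member <- array(vals >= 0.5, gridDim(volume))
        covered <- voxelData(.splatMask(volume, field, supersample)) > 0
        res <- LabelMask(array(as.numeric(member & covered),
                               gridDim(volume)),
                         gridSpacing(volume), gridOrigin(volume))
    } else {
        res <- VolumeGrid(array(vals, gridDim(volume)),
                          gridSpacing(volume), gridOrigin(volume))
    }
    attr(res, "inverseResidual") <- inv$residual
    res
}

# Push-forward warp for binary masks: subdivide every foreground voxel,
# displace each sub-sample by the (trilinearly interpolated) forward field
# and mark the voxel it lands in.
.splatMask <- function(mask, field, supersample = 4L) {
    dm <- gridDim(mask)
    sp <- gridSpacing(mask)
    org <- gridOrigin(mask)
    fg <- which(voxelData(mask) > 0)
    out <- array(0, dm)
    if (length(fg)) {
        idx <- arrayInd(fg, dm)
        ctr <- indexToWorld(mask, idx)
        k <- max(1L, as.integer(supersample))
        offs1 <- ((seq_len(k) - 0.5) / k - 0.5)
        offs <- as.matrix(expand.grid(offs1 * sp[1], offs1 * sp[2],
                                      offs1 * sp[3]))
        nxy <- dm[1] * dm[2]
        for (o in seq_len(nrow(offs))) {
            pts <- sweep(ctr, 2L, offs[o, ], "+")
            dst <- pts + .sampleField(field, pts)
            t <- .gridCoords(sp, org, dst)
            i <- round(t)
            ok <- i[, 1] >= 1 & i[, 1] <= dm[1] & i[, 2] >= 1 &
                  i[, 2] <= dm[2] & i[, 3] >= 1 & i[, 3] <= dm[3]
            out[i[ok, 1] + dm[1] * (i[ok, 2] - 1) +
                nxy * (i[ok, 3] - 1)] <- 1
        }
    }
    LabelMask(out, sp, org)
}

#' Log-Jacobian determinant map of a displacement field
#'
#' \code{log det(I + grad u)} with central differences in world mm
#' (one-sided at the grid faces). Zero for any uniform translation; voxels
#' with non-positive determinant (folding) become NaN and are counted.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @return a \linkS4class{JacobianMap}.
#' @export
logJacobian <- function(field) {
    dm <- gridDim(field)
    sp <- gridSpacing(field)
    grad <- vector("list", 9L)         # d u_comp / d axis
    k <- 0L
    for (comp in 1:3) {
        u <- field@data[, , , comp]
        for (axis in 1:3) {
            k <- k + 1L
            fwd <- .shiftArray(u, axis, +1L)
            bwd <- .shiftArray(u, axis, -1L)
            g <- (fwd - bwd) / (2 * sp[axis])
            # one-sided stencils on the two boundary faces
            idx <- rep(list(quote(expr = )), 3L)
            iLo <- idx; iLo[[axis]] <- 1L
            iHi <- idx; iHi[[axis]] <- dm[axis]
            iLo2 <- idx; iLo2[[axis]] <- 2L
            iHi2 <- idx; iHi2[[axis]] <- dm[axis] - 1L
            lo <- (do.call(`[`, c(list(u), iLo2)) -
                   do.call(`[`, c(list(u), iLo))) / sp[axis]
            hi <- (do.call(`[`, c(list(u), iHi)) -
                   do.call(`[`, c(list(u), iHi2))) / sp[axis]
            g <- do.call(`[<-`, c(list(g), iLo, list(lo)))
            g <- do.call(`[<-`, c(list(g), iHi, list(hi)))
            grad[[k]] <- g
        }
    }
    # J = I + grad u, det via explicit 3x3 expansion
    a11 <- 1 + grad[[1]]; a12 <- grad[[2]]; a13 <- grad[[3]]
    a21 <- grad[[4]]; a22 <- 1 + grad[[5]]; a23 <- grad[[6]]
    a31 <- grad[[7]]; a32 <- grad[[8]]; a33 <- 1 + grad[[9]]
    det <- a11 * (a22 * a33 - a23 * a32) -
           a12 * (a21 * a33 - a23 * a31) +
           a13 * (a21 * a32 - a22 * a31)
    folded <- sum(det <= 0)
    ld <- array(NaN, dm)
    ok <- det > 0
    ld[ok] <- log(det[ok])
    new("JacobianMap", data = ld, spacing = sp, origin = gridOrigin(field),
        folded = as.integer(folded))
}
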