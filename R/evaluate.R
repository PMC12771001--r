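#' @include dvf.R
NULL

#' Evaluation points on the organ surface and inner shells
#'
#' Samples the NURBS surface and inner shells of the undeformed organ; TRE
#' is computed at these points. At least two shell levels are used so both
#' surface and interior accuracy are probed.
#'
#' @param stack the organ's \linkS4class{ShellStack} (undeformed).
#' @param grid grid-backed object; points falling outside the grid are an
#'   error.
#' @param nu,nv samples along / around the organ per shell.
#' @param levels radial factors to sample; must select >= 2 shells.
#' @return n x 3 matrix of world-mm points.
#' @export
evalPoints <- function(stack, grid, nu = 50L, nv = 24L,
                       levels = c(0, 0.5)) {
    sel <- vapply(levels, function(p) which.min(abs(stack@p - p)), 0L)
    sel <- unique(sel)
    if (length(sel) < 2L)
        stop("evaluation points must cover at least 2 shell levels")
    u <- seq(0, 1, length.out = nu)
    v <- seq(0, 1 - 1 / nv, length.out = nv)
    pts <- do.call(rbind, lapply(sel, function(k)
        matrix(evaluateSurface(stack@surfaces[[k]], u, v), nu * nv, 3L)))
    lo <- gridOrigin(grid)
    hi <- gridOrigin(grid) + (gridDim(grid) - 1) * gridSpacing(grid)
    out <- sweep(pts, 2L, lo, "<") | sweep(pts, 2L, hi, ">")
    if (any(out))
        stop(sum(rowSums(out) > 0), " evaluation point(s) outside the grid")
    pts
}

#' Target registration error between two displacement fields
#'
#' Per point x: \code{||(x + u_gt(x)) - (x + u_cand(x))||} with trilinear
#' field sampling, i.e. the distance between the two mapped positions.
#' Symmetric in its arguments.
#'
#' @param points n x 3 matrix of world-mm evaluation points (inside the
#'   grid).
#' @param gt,cand \linkS4class{DisplacementField}s on one grid.
#' @return list with \code{mean}, \code{sd} and \code{perPoint} (mm).
#' @export
tre <- function(points, gt, cand) {
    .stopIfGridMismatch(gt, cand, "fields")
    lo <- gridOrigin(gt)
    hi <- gridOrigin(gt) + (gridDim(gt) - 1) * gridSpacing(gt)
    if (any(sweep(points, 2L, lo, "<") | sweep(points, 2L, hi, ">")))
        stop("evaluation point(s) outside the field grid")
    d <- .sampleField(gt, points) - .sampleField(cand, points)
    e <- sqrt(rowSums(d^2))
    list(mean = mean(e), sd = if (length(e) > 1L) sd(e) else 0,
         perPoint = e)
}

#' Dice similarity coefficient of two masks
#'
#' \code{2 |A and B| / (|A| + |B|)}. Two empty masks count as perfectly
#' matching (1, with a message).
#'
#' @param a,b \linkS4class{LabelMask}s on one grid.
#' @return a fraction in [0, 1].
#' @export
dsc <- function(a, b) {
    .stopIfGridMismatch(a, b, "masks")
    fa <- voxelData(a) > 0
    fb <- voxelData(b) > 0
    denom <- sum(fa) + sum(fb)
    if (denom == 0) {
        message("both masks empty; DSC defined as 1")
        return(1)
    }
    2 * sum(fa & fb) / denom
}

#' 95th-percentile symmetric surface distance
#'
#' Distances are measured between boundary voxels (spacing-aware), pooled
#' over both directions, and summarized at the given percentile with linear
#' interpolation.
#'
#' @param a,b non-empty \linkS4class{LabelMask}s on one grid.
#' @param percentile percentile of the pooled surface distances.
#' @return distance in mm.
#' @export
hd95 <- function(a, b, percentile = 95) {
    .stopIfGridMismatch(a, b, "masks")
    if (sum(voxelData(a)) == 0 || sum(voxelData(b)) == 0)
        stop("hd95 requires two non-empty masks")
    ba <- boundaryVoxels(a)
    bb <- boundaryVoxels(b)
    dToB <- .edt(bb)
    dToA <- .edt(ba)
    dAB <- dToB[voxelData(ba) > 0]
    dBA <- dToA[voxelData(bb) > 0]
    as.numeric(quantile(c(dAB, dBA), percentile / 100, type = 7))
}

#' Dose-warping error between two accumulated dose maps
#'
#' Signed relative difference \code{(D_cand - D_gt) / D_gt} averaged over
#' ROI voxels whose ground-truth dose exceeds \code{floorGy}, reported in
#' percent. The un-normalized sum is attached as attribute \code{"sum"},
#' the number of excluded low-dose voxels as \code{"excluded"}.
#'
#' @param accumDir candidate accumulated dose (\linkS4class{VolumeGrid},
#'   Gy).
#' @param accumGt ground-truth accumulated dose.
#' @param roi \linkS4class{LabelMask} region of interest (non-empty).
#' @param floorGy dose floor excluding near-zero denominators.
#' @return mean signed relative difference, percent.
#' @export
dwe <- function(accumDir, accumGt, roi, floorGy = 0.5) {
    .stopIfGridMismatch(accumDir, accumGt, "dose maps")
    .stopIfGridMismatch(accumDir, roi, "dose map and roi")
    sel <- voxelData(roi) > 0
    if (!any(sel)) stop("roi is empty")
    gt <- voxelData(accumGt)[sel]
    dir <- voxelData(accumDir)[sel]
    use <- gt > floorGy
    if (!any(use))
        stop("all roi voxels fall below the ", floorGy, " Gy dose floor")
    rel <- (dir[use] - gt[use]) / gt[use]
    out <- 100 * mean(rel)
    attr(out, "sum") <- 100 * sum(rel)
    attr(out, "excluded") <- sum(!use)
    out
}

#' Accumulate dose over motion phases by direct dose mapping
#'
#' The dose volume is warped by every phase's displacement field and the
#' per-phase doses are averaged.
#'
#' @param dose \linkS4class{VolumeGrid} in Gy.
#' @param fields list of \linkS4class{DisplacementField}s (one per phase).
#' @return accumulated \linkS4class{VolumeGrid}.
#' @export
accumulateDose <- function(dose, fields) {
    stopifnot(length(fields) >= 1L)
    acc <- array(0, gridDim(dose))
    for (f in fields) {
        .stopIfGridMismatch(dose, f, "dose and field")
        acc <- acc + voxelData(warpVolume(dose, f, kind = "dose"))
    }
    VolumeGrid(acc / length(fields), gridSpacing(dose), gridOrigin(dose))
}

#' RMSE of the displacement error, binned by motion magnitude or dose
#'
#' Voxelwise error \code{||u_cand - u_gt||} is aggregated as RMSE per bin
#' of the ground-truth motion magnitude (mm) or of an auxiliary dose volume
#' (Gy). Empty bins are omitted.
#'
#' @param gt,cand \linkS4class{DisplacementField}s on one grid.
#' @param binBy "motion" or "dose".
#' @param aux \linkS4class{VolumeGrid} with the dose (required for
#'   \code{binBy = "dose"}).
#' @param edges increasing bin edges; defaults to 1 mm-wide bins from 0 to
#'   the maximum ground-truth magnitude, or 10 Gy-wide dose bins.
#' @param mask optional \linkS4class{LabelMask} restricting the voxels
#'   considered.
#' @return data.frame with bin bounds, voxel count and RMSE (mm). The last
#'   bin includes its upper edge.
#' @export
rmseBinned <- function(gt, cand, binBy = c("motion", "dose"), aux = NULL,
                       edges = NULL, mask = NULL) {
    binBy <- match.arg(binBy)
    .stopIfGridMismatch(gt, cand, "fields")
    du <- cand@data - gt@data
    err <- sqrt(du[, , , 1]^2 + du[, , , 2]^2 + du[, , , 3]^2)
    gmag <- sqrt(gt@data[, , , 1]^2 + gt@data[, , , 2]^2 +
                 gt@data[, , , 3]^2)
    key <- if (binBy == "motion") gmag else {
        if (is.null(aux)) stop("dose binning needs an aux dose volume")
        .stopIfGridMismatch(gt, aux, "field and dose")
        voxelData(aux)
    }
    if (is.null(edges)) {
        width <- if (binBy == "motion") 1 else 10
        edges <- seq(0, max(key) + width, by = width)
    }
    if (is.unsorted(edges, strictly = TRUE))
        stop("bin edges must be strictly increasing")
    sel <- if (is.null(mask)) rep(TRUE, length(key)) else
        as.vector(voxelData(mask) > 0)
    k <- as.vector(key)[sel]
    e <- as.vector(err)[sel]
    bin <- findInterval(k, edges, rightmost.closed = TRUE)
    inRange <- bin >= 1L & bin <= length(edges) - 1L
    bin <- bin[inRange]
    e <- e[inRange]
    if (!length(e))
        return(data.frame(lower = numeric(0), upper = numeric(0),
                          n = integer(0), rmse = numeric(0)))
    ms <- rowsum(cbind(e^2, 1), bin)
    ids <- as.integer(rownames(ms))
    data.frame(lower = edges[ids], upper = edges[ids + 1L],
               n = as.integer(ms[, 2]), rmse = sqrt(ms[, 1] / ms[, 2]))
}

#' Score a candidate displacement field against the ground truth
#'
#' Computes the full metric suite for one registration direction (phase 0
#' to the evaluated phase): TRE at surface and shell points, DSC and HD95
#' of the candidate-warped versus ground-truth-warped organ mask,
#' log-Jacobian statistics of the candidate, RMSE binned by motion
#' magnitude (and by dose when given), and the dose-warping error from
#' direct dose mapping.
#'
#' @param gt ground-truth \linkS4class{DisplacementField}.
#' @param cand candidate \linkS4class{DisplacementField}.
#' @param organMask undeformed organ \linkS4class{LabelMask}.
#' @param points evaluation points from [evalPoints()].
#' @param dose optional \linkS4class{VolumeGrid} (Gy).
#' @param gtFields,candFields optional per-phase field lists for dose
#'   accumulation; default to the single evaluated phase.
#' @param motionEdges,doseEdges optional bin edges for [rmseBinned()].
#' @param doseFloor dose floor for [dwe()], Gy.
#' @return an \linkS4class{EvalReport}; \code{info$errorVolume} holds the
#'   voxelwise error heatmap as a \linkS4class{VolumeGrid}.
#' @export
evaluateDVF <- function(gt, cand, organMask, points, dose = NULL,
                        gtFields = list(gt), candFields = list(cand),
                        motionEdges = NULL, doseEdges = NULL,
                        doseFloor = 0.5) {
    .stopIfGridMismatch(gt, cand, "fields")
    .stopIfGridMismatch(gt, organMask, "field and mask")
    t <- tre(points, gt, cand)
    mGt <- warpVolume(organMask, gt, kind = "mask")
    mCand <- warpVolume(organMask, cand, kind = "mask")
    overlap <- dsc(mGt, mCand)
    surf <- hd95(mGt, mCand)
    jac <- logJacobian(cand)
    jd <- voxelData(jac)
    inOrgan <- voxelData(organMask) > 0
    jacMean <- mean(jd[inOrgan], na.rm = TRUE)
    jacSd <- sd(jd[inOrgan], na.rm = TRUE)
    du <- cand@data - gt@data
    err <- sqrt(du[, , , 1]^2 + du[, , , 2]^2 + du[, , , 3]^2)
    byMotion <- rmseBinned(gt, cand, "motion", edges = motionEdges)
    byDose <- if (is.null(dose)) data.frame() else
        rmseBinned(gt, cand, "dose", aux = dose, edges = doseEdges,
                   mask = organMask)
    dweVal <- NA_real_
    if (!is.null(dose)) {
        accGt <- accumulateDose(dose, gtFields)
        accCand <- accumulateDose(dose, candFields)
        dweVal <- as.numeric(dwe(accCand, accGt, organMask,
                                 floorGy = doseFloor))
    }
    metrics <- data.frame(
        treMean = t$mean, treSd = t$sd, dsc = overlap, hd95 = surf,
        dwePercent = dweVal, logJacMean = jacMean, logJacSd = jacSd,
        foldedVoxels = jac@folded)
    new("EvalReport", metrics = metrics, rmseByMotion = byMotion,
        rmseByDose = byDose,
        info = list(errorVolume = VolumeGrid(err, gridSpacing(gt),
                                             gridOrigin(gt)),
                    doseFloor = doseFloor, nPoints = nrow(points)))
}
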