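#' @include phantom.R
NULL

#' Thin a binary mask to a skeleton graph
#'
#' Topology-preserving 3D thinning: border voxels that are simple points
#' (removal changes neither foreground nor background connectivity) and not
#' curve endpoints are deleted in successive directional passes until the
#' mask is one voxel thick. Surviving voxels are connected into a graph by
#' 26-adjacency.
#'
#' @param mask a non-empty \linkS4class{LabelMask}.
#' @param anchorsMm optional matrix (or vector) of world-mm landmark points
#'   (typically the manually chosen centerline endpoints); the foreground
#'   voxel nearest each landmark is pinned and survives thinning, so the
#'   skeleton spans the landmarks instead of retreating from tapering organ
#'   tips.
#' @return a \linkS4class{SkeletonGraph}; \code{boundaryDist} holds each
#'   skeleton voxel's distance to the mask boundary (mm), used later to
#'   break skeleton cycles.
#' @export
skeletonize <- function(mask, anchorsMm = NULL) {
    fg <- voxelData(mask) > 0
    if (!any(fg)) stop("cannot skeletonize an empty mask")
    dm <- gridDim(mask)
    anchor <- NULL
    if (!is.null(anchorsMm)) {
        anchorsMm <- .asPointMatrix(anchorsMm)
        fgIdx <- which(fg)
        fgPts <- indexToWorld(mask, arrayInd(fgIdx, dm))
        anchor <- array(FALSE, dm)
        for (i in seq_len(nrow(anchorsMm))) {
            d2 <- rowSums(sweep(fgPts, 2L, anchorsMm[i, ], "-")^2)
            anchor[fgIdx[which.min(d2)]] <- TRUE
        }
    }
    sk <- thin3d_cpp(as.logical(fg), dm, anchor)
    vox <- which(array(sk, dm), arr.ind = TRUE)
    storage.mode(vox) <- "integer"
    # depth inside the organ: distance to the nearest background voxel
    bg <- LabelMask(array(as.numeric(!fg), dm), gridSpacing(mask),
                    gridOrigin(mask))
    dBound <- .edt(bg)[vox]
    # edges between 26-adjacent skeleton voxels
    nx <- dm[1]; nxy <- dm[1] * dm[2]
    lin <- vox[, 1] + nx * (vox[, 2] - 1L) + nxy * (vox[, 3] - 1L)
    row <- integer(prod(dm))
    row[lin] <- seq_along(lin)
    e1 <- integer(0); e2 <- integer(0)
    offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
    for (k in seq_len(nrow(offs))) {
        nb <- cbind(vox[, 1] + offs$dx[k], vox[, 2] + offs$dy[k],
                    vox[, 3] + offs$dz[k])
        ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 &
              nb[, 2] <= dm[2] & nb[, 3] >= 1 & nb[, 3] <= dm[3]
        nbl <- nb[ok, 1] + nx * (nb[ok, 2] - 1L) + nxy * (nb[ok, 3] - 1L)
        j <- row[nbl]
        i <- which(ok)[j > 0]
        j <- j[j > 0]
        keep <- i < j          # each undirected edge once
        e1 <- c(e1, i[keep]); e2 <- c(e2, j[keep])
    }
    ord <- order(e1, e2)
    new("SkeletonGraph", voxels = vox,
        edges = cbind(e1, e2)[ord, , drop = FALSE],
        boundaryDist = dBound, spacing = gridSpacing(mask),
        origin = gridOrigin(mask))
}

# Snap a world-mm point to the nearest skeleton voxel (row index).
.snapToSkeleton <- function(graph, pointMm) {
    w <- indexToWorld(graph, graph@voxels)
    d2 <- rowSums(sweep(w, 2L, pointMm, "-")^2)
    which.min(d2)
}

#' Extract the centerline between two endpoints of a skeleton
#'
#' Builds the skeleton adjacency graph, prunes cycles (keeping, at each
#' cycle, the passage running deepest inside the organ: the removed edge is
#' the one whose endpoints lie closest to the mask boundary), and returns
#' the unique endpoint-to-endpoint path of the resulting tree, found by
#' breadth-first search. All branches off the path are discarded.
#'
#' @param graph a \linkS4class{SkeletonGraph}.
#' @param startMm,endMm numeric(3) world-mm endpoints; each is snapped to
#'   the nearest skeleton voxel.
#' @return a \linkS4class{Centerline} (voxel-center polyline with cumulative
#'   arc length).
#' @export
longestPath <- function(graph, startMm, endMm) {
    nV <- nrow(graph@voxels)
    if (nV == 0L) stop("empty skeleton graph")
    s <- .snapToSkeleton(graph, as.numeric(startMm))
    e <- .snapToSkeleton(graph, as.numeric(endMm))
    g <- igraph::make_empty_graph(n = nV, directed = FALSE)
    if (nrow(graph@edges) > 0L)
        g <- igraph::add_edges(g, t(graph@edges))
    comp <- igraph::components(g)
    if (comp$membership[s] != comp$membership[e])
        stop("endpoints lie in different skeleton components (",
             comp$membership[s], " vs ", comp$membership[e], ")")
    if (s == e) {
        return(new("Centerline",
                   points = indexToWorld(graph, graph@voxels[s, ,
                                                             drop = FALSE]),
                   arcLength = 0))
    }
    # prune cycles: maximum-depth spanning tree (deterministic tie-break by
    # edge order)
    if (nrow(graph@edges) >= nV) {
        depth <- (graph@boundaryDist[graph@edges[, 1]] +
                  graph@boundaryDist[graph@edges[, 2]]) / 2
        w <- -depth + seq_len(nrow(graph@edges)) * 1e-9
        g <- igraph::mst(g, weights = w)
    }
    p <- igraph::shortest_paths(g, from = s, to = e)$vpath[[1]]
    idx <- as.integer(p)
    pts <- indexToWorld(graph, graph@voxels[idx, , drop = FALSE])
    new("Centerline", points = pts, arcLength = .polylineArc(pts))
}

#' Resample a centerline to equidistant arc-length steps
#'
#' Points are placed at arc-length multiples of \code{stepMm}; both
#' endpoints are kept, so the final segment may be shorter.
#'
#' @param line a \linkS4class{Centerline}.
#' @param stepMm arc-length step, mm; the total length must be at least
#'   twice the step.
#' @return a resampled \linkS4class{Centerline}.
#' @export
resampleEquidistant <- function(line, stepMm) {
    stopifnot(stepMm > 0)
    L <- max(line@arcLength)
    if (L < 2 * stepMm)
        stop("centerline too short (", signif(L, 4), " mm) for a ",
             stepMm, " mm step")
    res <- .resamplePolyline(line@points, stepMm)
    new("Centerline", points = res$points, arcLength = res$arc)
}

#' Mask-to-centerline convenience wrapper
#'
#' Runs [skeletonize()], [longestPath()] and [resampleEquidistant()] in
#' sequence.
#'
#' @param mask organ \linkS4class{LabelMask}.
#' @param startMm,endMm world-mm endpoints (snapped to the skeleton).
#' @param stepMm resampling step; default twice the largest in-plane
#'   spacing.
#' @param smoothDf degrees of freedom of the smoothing spline fitted to the
#'   voxel polyline (per coordinate, against cumulative arc length) before
#'   resampling. The default, a quarter of the polyline's point count,
#'   removes the staircase zigzag of the discrete skeleton — which would
#'   otherwise inflate arc length by a few percent and jitter the
#'   arc-length stations the traveling wave is evaluated at — while
#'   following the organ's curvature. Set to 0 to disable smoothing.
#' @return a \linkS4class{Centerline}.
#' @export
extractCenterline <- function(mask, startMm, endMm,
                              stepMm = max(gridSpacing(mask)[1:2]),
                              smoothDf = NULL) {
    graph <- skeletonize(mask, anchorsMm = rbind(startMm, endMm))
    line <- longestPath(graph, startMm, endMm)
    n <- nrow(line@points)
    if (is.null(smoothDf)) smoothDf <- max(4L, round(n / 4))
    if (smoothDf >= 4L && n > smoothDf) {
        sm <- vapply(1:3, function(a)
            stats::smooth.spline(line@arcLength, line@points[, a],
                                 df = smoothDf)$y, numeric(n))
        line <- new("Centerline", points = sm,
                    arcLength = .polylineArc(sm))
    }
    resampleEquidistant(line, stepMm)
}
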