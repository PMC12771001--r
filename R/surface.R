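#' @include centerline.R
NULL

# Cox-de Boor B-spline basis matrix: length(x) rows, one column per basis
# function over `knots` at the given degree. x must lie within the valid
# parameter range; the right end of the range is included.
.bsplineBasis <- function(x, knots, degree) {
    m <- length(x)
    nk <- length(knots)
    xmax <- knots[nk - degree]          # right end of the valid range
    B <- matrix(0, m, nk - 1L)
    for (j in seq_len(nk - 1L)) {
        if (knots[j + 1L] > knots[j])
            B[, j] <- as.numeric(x >= knots[j] &
                                 (x < knots[j + 1L] |
                                  (x == xmax & knots[j + 1L] >= xmax)))
    }
    for (d in seq_len(degree)) {
        Bn <- matrix(0, m, nk - 1L - d)
        for (j in seq_len(nk - 1L - d)) {
            den1 <- knots[j + d] - knots[j]
            den2 <- knots[j + d + 1L] - knots[j + 1L]
            t1 <- if (den1 > 0) (x - knots[j]) / den1 * B[, j] else 0
            t2 <- if (den2 > 0)
                (knots[j + d + 1L] - x) / den2 * B[, j + 1L] else 0
            Bn[, j] <- t1 + t2
        }
        B <- Bn
    }
    B
}

# Clamped uniform knot vector on [0, 1] for n control points, cubic etc.
.clampedKnots <- function(n, degree) {
    inner <- if (n - degree - 1L >= 1L)
        seq_len(n - degree - 1L) / (n - degree) else numeric(0)
    c(rep(0, degree + 1L), inner, rep(1, degree + 1L))
}

# Basis for a closed (periodic) direction with J distinct control points:
# evaluated via J + degree wrapped control columns over uniform knots.
.periodicBasis <- function(v, J, degree) {
    v <- v - floor(v)                   # wrap into [0, 1)
    n <- J + degree
    knots <- seq(-degree, n) / J
    .bsplineBasis(v, knots, degree)
}

#' Cast radial sectional curves from a centerline
#'
#' At every centerline point, rays are cast at equally spaced angles in the
#' plane orthogonal to the local tangent and marched outward until they
#' first cross the mask boundary; the crossing is located to sub-voxel
#' precision by linear interpolation of the mask's signed distance. Section
#' frames are rotation-minimizing (parallel transport) along the
#' centerline, so corresponding rays stay aligned from section to section.
#'
#' @param mask organ \linkS4class{LabelMask}.
#' @param line \linkS4class{Centerline}; every point must lie inside the
#'   mask.
#' @param raysPerSection number of rays J (>= 8).
#' @return a list of \linkS4class{SectionalCurve}.
#' @export
castSections <- function(mask, line, raysPerSection = 36L) {
    stopifnot(raysPerSection >= 8L)
    J <- as.integer(raysPerSection)
    pts <- line@points
    n <- nrow(pts)
    if (n < 2L) stop("centerline must have at least 2 points")
    sdist <- .signedDistance(mask)
    sp <- gridSpacing(mask)
    org <- gridOrigin(mask)
    dm <- gridDim(mask)

    # tangents by central differences, then parallel-transported frames
    tang <- rbind(pts[2, ] - pts[1, ],
                  (pts[-(1:2), , drop = FALSE] -
                   pts[seq_len(n - 2), , drop = FALSE]) / 2,
                  pts[n, ] - pts[n - 1, ])
    if (n == 2L) tang <- tang[c(1, 3), , drop = FALSE]
    tang <- tang / sqrt(rowSums(tang^2))
    frames <- .transportFrames(tang)

    ctrVal <- .sampleTrilinear(sdist, sp, org, pts)
    if (any(ctrVal <= 0))
        stop("centerline point(s) ",
             paste(which(ctrVal <= 0), collapse = ", "),
             " lie outside the mask")

    step <- 0.25 * min(sp)
    maxR <- sqrt(sum(((dm - 1) * sp)^2))
    nsteps <- ceiling(maxR / step)
    tvals <- (0:nsteps) * step
    theta <- 2 * pi * (seq_len(J) - 1L) / J

    sections <- vector("list", n)
    for (i in seq_len(n)) {
        dirs <- outer(cos(theta), frames$normal[i, ]) +
                outer(sin(theta), frames$binormal[i, ])
        # sample signed distance along all rays at once
        samp <- pts[rep(i, J * length(tvals)), , drop = FALSE] +
            dirs[rep(seq_len(J), times = length(tvals)), ] *
            rep(tvals, each = J)
        inGrid <- samp >= matrix(org, nrow(samp), 3, byrow = TRUE) &
                  samp <= matrix(org + (dm - 1) * sp, nrow(samp), 3,
                                 byrow = TRUE)
        inGrid <- rowSums(inGrid) == 3L
        vals <- .sampleTrilinear(sdist, sp, org, samp)
        vals[!inGrid] <- NA_real_
        vmat <- matrix(vals, nrow = J)
        radii <- numeric(J)
        for (jr in seq_len(J)) {
            v <- vmat[jr, ]
            k <- which(v < 0)[1]
            if (is.na(k)) {
                if (anyNA(v))
                    stop("ray ", jr, " of section ", i,
                         " exited the grid before hitting the boundary")
                stop("ray ", jr, " of section ", i,
                     " never crossed the mask boundary")
            }
            frac <- v[k - 1] / (v[k - 1] - v[k])
            radii[jr] <- tvals[k - 1] + frac * step
        }
        if (any(radii < 0.5 * min(sp)))
            stop("degenerate section ", i, ": boundary radius ",
                 signif(min(radii), 3),
                 " mm is below half a voxel (centerline touches the mask ",
                 "surface)")
        sections[[i]] <- new("SectionalCurve", center = pts[i, ],
            tangent = tang[i, ], normal = frames$normal[i, ],
            binormal = frames$binormal[i, ],
            boundary = pts[rep(i, J), ] + dirs * radii,
            radii = radii, arc = line@arcLength[i])
    }
    sections
}

# Rotation-minimizing frames: propagate an initial normal along the tangent
# sequence with the minimal rotation aligning successive tangents.
.transportFrames <- function(tang) {
    n <- nrow(tang)
    normal <- matrix(0, n, 3L)
    binorm <- matrix(0, n, 3L)
    seedAxis <- diag(3)[which.min(abs(tang[1, ])), ]
    v <- seedAxis - sum(seedAxis * tang[1, ]) * tang[1, ]
    normal[1, ] <- v / sqrt(sum(v^2))
    binorm[1, ] <- .cross3(tang[1, ], normal[1, ])
    for (i in seq_len(n - 1L)) {
        a <- tang[i, ]; b <- tang[i + 1L, ]
        axis <- .cross3(a, b)
        sa <- sqrt(sum(axis^2))
        ca <- sum(a * b)
        if (sa < 1e-12) {
            normal[i + 1L, ] <- normal[i, ]
        } else {
            axis <- axis / sa
            ang <- atan2(sa, ca)
            normal[i + 1L, ] <- .rodrigues(normal[i, ], axis, ang)
        }
        # re-orthogonalize against the tangent to stop drift
        v <- normal[i + 1L, ] - sum(normal[i + 1L, ] * b) * b
        normal[i + 1L, ] <- v / sqrt(sum(v^2))
        binorm[i + 1L, ] <- .cross3(b, normal[i + 1L, ])
    }
    list(normal = normal, binormal = binorm)
}

.cross3 <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
}

.rodrigues <- function(v, axis, ang) {
    v * cos(ang) + .cross3(axis, v) * sin(ang) +
        axis * sum(axis * v) * (1 - cos(ang))
}

#' Assemble a tubular NURBS surface from sectional curves
#'
#' The boundary points of the sections become the control net: clamped
#' cubic along the organ, periodic cubic around each section, unit weights.
#'
#' @param sections list of \linkS4class{SectionalCurve} with a common
#'   number of rays; at least degree + 1 sections are required.
#' @param degreeU,degreeV spline degrees.
#' @return a \linkS4class{NurbsSurface}.
#' @export
fitNurbs <- function(sections, degreeU = 3L, degreeV = 3L) {
    I <- length(sections)
    if (I < degreeU + 1L)
        stop("need at least ", degreeU + 1L, " sections, got ", I)
    J <- nrow(sections[[1]]@boundary)
    if (!all(vapply(sections, function(s) nrow(s@boundary), 0L) == J))
        stop("all sections must share one ray count")
    net <- array(0, c(I, J, 3L))
    centers <- matrix(0, I, 3L)
    arc <- numeric(I)
    for (i in seq_len(I)) {
        net[i, , ] <- sections[[i]]@boundary
        centers[i, ] <- sections[[i]]@center
        arc[i] <- sections[[i]]@arc
    }
    new("NurbsSurface", controlNet = net, centers = centers,
        arcLength = arc, degreeU = as.integer(degreeU),
        degreeV = as.integer(degreeV))
}

#' Evaluate a NURBS surface on a (u, v) parameter grid
#'
#' u runs along the organ on [0, 1] (clamped), v around the section
#' (periodic, wrapped modulo 1).
#'
#' @param surface a \linkS4class{NurbsSurface}.
#' @param u,v numeric parameter vectors.
#' @return an array \code{c(length(u), length(v), 3)} of world-mm points.
#' @export
evaluateSurface <- function(surface, u, v) {
    net <- surface@controlNet
    I <- dim(net)[1]; J <- dim(net)[2]
    du <- surface@degreeU; dv <- surface@degreeV
    Bu <- .bsplineBasis(pmin(pmax(u, 0), 1), .clampedKnots(I, du), du)
    Bv <- .periodicBasis(v, J, dv)
    wrap <- c(seq_len(J), seq_len(dv))
    out <- array(0, c(length(u), length(v), 3L))
    for (comp in 1:3)
        out[, , comp] <- Bu %*% net[, wrap, comp] %*% t(Bv)
    out
}

#' Interpolate an inner shell toward the centerline
#'
#' Every control point moves linearly toward its section centre:
#' \code{P(p) = (1 - p) * P + p * center}. p = 0 returns the surface
#' unchanged; p = 1 collapses every section onto the centerline.
#'
#' @param surface a \linkS4class{NurbsSurface}.
#' @param p radial factor in [0, 1].
#' @return a \linkS4class{NurbsSurface}.
#' @export
interpolateShell <- function(surface, p) {
    if (p < 0 || p > 1) stop("radial factor p must lie in [0, 1]")
    net <- surface@controlNet
    for (comp in 1:3)
        net[, , comp] <- (1 - p) * net[, , comp] +
            p * surface@centers[, comp]
    initialize(surface, controlNet = net)
}

#' Build a radial stack of shells
#'
#' @param surface the outer \linkS4class{NurbsSurface}.
#' @param p radial factors; must start at 0 (the surface itself) and
#'   increase. The default spans the full radius; the p = 1 shell is the
#'   (stationary) centerline itself and seeds the zero displacement there.
#' @return a \linkS4class{ShellStack}.
#' @export
makeShellStack <- function(surface, p = c(0, 0.25, 0.5, 0.75, 1)) {
    new("ShellStack",
        surfaces = lapply(p, function(pk) interpolateShell(surface, pk)),
        p = as.numeric(p))
}

#' Serialize a NURBS surface to JSON
#'
#' Writes the control net, section centers, arc-length stations and degrees;
#' [readSurfaceJSON()] restores the object.
#'
#' @param surface a \linkS4class{NurbsSurface}.
#' @param path output .json path.
#' @return the path, invisibly.
#' @export
writeSurfaceJSON <- function(surface, path) {
    d <- dim(surface@controlNet)
    jsonlite::write_json(list(
        degrees = c(surface@degreeU, surface@degreeV),
        sections = d[1], rays = d[2],
        control_net = as.numeric(surface@controlNet),   # column-major
        centers = as.numeric(surface@centers),
        arc_length_mm = surface@arcLength), path, digits = NA)
    invisible(path)
}

#' @rdname writeSurfaceJSON
#' @export
readSurfaceJSON <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("NurbsSurface",
        controlNet = array(as.numeric(x$control_net),
                           c(x$sections, x$rays, 3)),
        centers = matrix(as.numeric(x$centers), ncol = 3),
        arcLength = as.numeric(x$arc_length_mm),
        degreeU = as.integer(x$degrees[1]),
        degreeV = as.integer(x$degrees[2]))
}

#' Export a sampled surface as a Wavefront OBJ mesh
#'
#' Quad mesh over a uniform (u, v) grid, closed around v; intended for
#' visual quality assurance in any mesh viewer.
#'
#' @param surface a \linkS4class{NurbsSurface}.
#' @param path output .obj path.
#' @param nu,nv sampling density.
#' @return the path, invisibly.
#' @export
writeSurfaceOBJ <- function(surface, path, nu = 80L, nv = 36L) {
    S <- evaluateSurface(surface, seq(0, 1, length.out = nu),
                         seq(0, 1 - 1 / nv, length.out = nv))
    con <- file(path, "w")
    on.exit(close(con))
    for (j in seq_len(nv)) for (i in seq_len(nu))
        writeLines(sprintf("v %.6f %.6f %.6f", S[i, j, 1], S[i, j, 2],
                           S[i, j, 3]), con)
    vid <- function(i, j) (j - 1L) * nu + i
    for (j in seq_len(nv)) {
        jn <- if (j == nv) 1L else j + 1L
        for (i in seq_len(nu - 1L))
            writeLines(sprintf("f %d %d %d %d", vid(i, j), vid(i + 1L, j),
                               vid(i + 1L, jn), vid(i, jn)), con)
    }
    invisible(path)
}
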