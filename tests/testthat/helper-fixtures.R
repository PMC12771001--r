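# Shared fixtures and independent brute-force oracles. Fixtures are built
# in code; the expensive stomach-preset model is computed once per session.

.cache <- new.env(parent = emptyenv())

# Straight tube along x, analytic axis at (y0, z0), radius rMm.
straightTubeMask <- function(nx = 30L, ny = 15L, nz = 15L,
                             spacing = c(1, 1, 1), rMm = 3) {
  y0 <- (ny - 1) * spacing[2] / 2
  z0 <- (nz - 1) * spacing[3] / 2
  dat <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) for (j in seq_len(ny)) {
    d2 <- ((j - 1) * spacing[2] - y0)^2 + ((k - 1) * spacing[3] - z0)^2
    if (d2 <= rMm^2) dat[, j, k] <- 1
  }
  list(mask = LabelMask(dat, spacing), axisY = y0, axisZ = z0)
}

stomachTwinFixture <- function() {
  if (!exists("stomach", .cache)) {
    spec <- phantomPreset("stomach", noiseSd = 0)
    mask <- makeTubeMask(spec)
    path <- tubePath(spec)
    model <- buildOrganModel(mask, path@points[1, ],
                             path@points[nrow(path@points), ])
    assign("stomach", list(spec = spec, mask = mask, path = path,
                           model = model,
                           params = stomachMotionParams()), .cache)
  }
  get("stomach", .cache)
}

# ---- independent oracles (plain loops, no package internals) -------------

# trilinear interpolation by explicit 8-corner loop
oracleTrilinear <- function(arr, spacing, origin, pt) {
  dm <- dim(arr)
  t <- (pt - origin) / spacing + 1
  i0 <- pmin(pmax(floor(t), 1), dm - 1)
  f <- pmin(pmax(t - i0, 0), 1)
  val <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
         (if (dz) f[3] else 1 - f[3])
    val <- val + w * arr[i0[1] + dx, i0[2] + dy, i0[3] + dz]
  }
  val
}

oracleFieldSample <- function(field, pt) {
  vapply(1:3, function(c)
    oracleTrilinear(voxelData(field)[, , , c], gridSpacing(field),
                    gridOrigin(field), pt), 0)
}

oracleTRE <- function(points, gt, cand) {
  vapply(seq_len(nrow(points)), function(i) {
    d <- oracleFieldSample(gt, points[i, ]) -
         oracleFieldSample(cand, points[i, ])
    sqrt(sum(d^2))
  }, 0)
}

# per-voxel mean of vectors binned at their nearest voxel
oracleVoxelize <- function(X, V, dm, spacing, origin) {
  out <- array(0, c(dm, 3))
  cnt <- array(0, dm)
  for (i in seq_len(nrow(X))) {
    idx <- round((X[i, ] - origin) / spacing) + 1
    stopifnot(all(idx >= 1), all(idx <= dm))
    cnt[idx[1], idx[2], idx[3]] <- cnt[idx[1], idx[2], idx[3]] + 1
    for (c in 1:3)
      out[idx[1], idx[2], idx[3], c] <- out[idx[1], idx[2], idx[3], c] +
        V[i, c]
  }
  for (c in 1:3) {
    o <- out[, , , c]
    o[cnt > 0] <- o[cnt > 0] / cnt[cnt > 0]
    out[, , , c] <- o
  }
  out
}

# synchronous neighbor-average fill, naive triple loop
oracleSmoothFill <- function(dat, fill, tol, maxIter = 5000L) {
  dm <- dim(dat)[1:3]
  cur <- dat
  nFill <- sum(fill)
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    nxt <- cur
    sumDelta <- 0
    for (z in seq_len(dm[3])) for (y in seq_len(dm[2]))
      for (x in seq_len(dm[1])) {
        if (!fill[x, y, z]) next
        s <- c(0, 0, 0); cnt <- 0
        for (d in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                       c(0, 0, -1), c(0, 0, 1))) {
          nb <- c(x, y, z) + d
          if (any(nb < 1) || any(nb > dm)) next
          v <- cur[nb[1], nb[2], nb[3], ]
          if (any(v != 0)) { s <- s + v; cnt <- cnt + 1 }
        }
        if (cnt > 0) {
          newv <- s / cnt
          sumDelta <- sumDelta +
            sqrt(sum((newv - cur[x, y, z, ])^2))
          nxt[x, y, z, ] <- newv
        }
      }
    res <- sumDelta / nFill
    cur <- nxt
    if (res < tol) break
  }
  list(field = cur, iterations = iter, residual = res)
}

oracleBoundary <- function(fg) {
  dm <- dim(fg)
  out <- array(FALSE, dm)
  for (z in seq_len(dm[3])) for (y in seq_len(dm[2]))
    for (x in seq_len(dm[1])) {
      if (!fg[x, y, z]) next
      onBg <- FALSE
      for (d in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                     c(0, 0, -1), c(0, 0, 1))) {
        nb <- c(x, y, z) + d
        if (any(nb < 1) || any(nb > dm) || !fg[nb[1], nb[2], nb[3]]) {
          onBg <- TRUE
          break
        }
      }
      out[x, y, z] <- onBg
    }
  out
}

oracleHd95 <- function(a, b, spacing, percentile = 95) {
  ba <- which(oracleBoundary(a > 0), arr.ind = TRUE)
  bb <- which(oracleBoundary(b > 0), arr.ind = TRUE)
  pa <- sweep(ba - 1, 2, spacing, "*")
  pb <- sweep(bb - 1, 2, spacing, "*")
  dAB <- vapply(seq_len(nrow(pa)), function(i)
    sqrt(min(rowSums(sweep(pb, 2, pa[i, ], "-")^2))), 0)
  dBA <- vapply(seq_len(nrow(pb)), function(i)
    sqrt(min(rowSums(sweep(pa, 2, pb[i, ], "-")^2))), 0)
  as.numeric(quantile(c(dAB, dBA), percentile / 100, type = 7))
}

oracleRmseBinned <- function(gt, cand, edges) {
  gmag <- sqrt(gt[, , , 1]^2 + gt[, , , 2]^2 + gt[, , , 3]^2)
  err <- sqrt((cand[, , , 1] - gt[, , , 1])^2 +
              (cand[, , , 2] - gt[, , , 2])^2 +
              (cand[, , , 3] - gt[, , , 3])^2)
  out <- data.frame()
  for (b in seq_len(length(edges) - 1)) {
    inBin <- if (b == length(edges) - 1)
      gmag >= edges[b] & gmag <= edges[b + 1]
    else gmag >= edges[b] & gmag < edges[b + 1]
    if (!any(inBin)) next
    out <- rbind(out, data.frame(lower = edges[b], upper = edges[b + 1],
                                 n = sum(inBin),
                                 rmse = sqrt(mean(err[inBin]^2))))
  }
  out
}

randomSmoothField <- function(dm, spacing = c(1, 1, 1), scale = 0.5,
                              seed = 1) {
  set.seed(seed)
  dat <- array(0, c(dm, 3))
  ax <- lapply(1:3, function(a) seq(0, 1, length.out = dm[a]))
  for (c in 1:3) {
    a <- runif(3, -1, 1)
    ph <- runif(3, 0, 2 * pi)
    g <- outer(outer(sin(2 * pi * ax[[1]] + ph[1]) * a[1],
                     cos(2 * pi * ax[[2]] + ph[2]) * a[2], "+"),
               sin(2 * pi * ax[[3]] + ph[3]) * a[3], "+")
    dat[, , , c] <- scale * g
  }
  DisplacementField(dat, spacing)
}
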