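test_that("thinning degenerates symmetric blobs and fixes single voxels", {
  dm <- c(11L, 11L, 11L)
  ball <- array(0, dm)
  for (x in 1:11) for (y in 1:11) for (z in 1:11)
    if ((x - 6)^2 + (y - 6)^2 + (z - 6)^2 <= 16) ball[x, y, z] <- 1
  sk <- skeletonize(LabelMask(ball))
  expect_lte(nrow(sk@voxels), 8)
  ctr <- colMeans(indexToWorld(sk, sk@voxels))
  expect_lt(sqrt(sum((ctr - c(5, 5, 5))^2)), 2.5)
  single <- array(0, c(3, 3, 3)); single[2, 2, 2] <- 1
  sk1 <- skeletonize(LabelMask(single))
  expect_identical(unname(sk1@voxels), matrix(c(2L, 2L, 2L), 1))
  expect_error(skeletonize(LabelMask(array(0, c(3, 3, 3)))), "empty")
})

test_that("straight tube thins to voxels on the axis", {
  tube <- straightTubeMask(30, 15, 15, rMm = 3)
  sk <- skeletonize(tube$mask)
  w <- indexToWorld(sk, sk@voxels)
  dAxis <- sqrt((w[, 2] - tube$axisY)^2 + (w[, 3] - tube$axisZ)^2)
  expect_true(all(dAxis <= 1 + 1e-9))   # within one voxel of the axis
})

test_that("longest path keeps the endpoint-to-endpoint branch only", {
  # Y graph: stem a-b, branches b-c and b-d-e; voxel coordinates chosen so
  # all edges are 26-adjacent
  vox <- rbind(a = c(1, 1, 1), b = c(2, 1, 1), c = c(3, 2, 1),
               d = c(3, 1, 1), e = c(4, 1, 1))
  storage.mode(vox) <- "integer"
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(2L, 4L), c(4L, 5L))
  g <- new("SkeletonGraph", voxels = vox, edges = edges,
           boundaryDist = rep(1, 5), spacing = c(1, 1, 1),
           origin = c(0, 0, 0))
  line <- longestPath(g, c(0, 0, 0), c(3, 0, 0))
  expect_equal(nrow(linePoints(line)), 4)       # a, b, d, e
  expect_equal(unname(linePoints(line)[, 1]), c(0, 1, 2, 3))
  # oracle: exhaustive enumeration of simple paths between a and e
  ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
  all <- igraph::all_simple_paths(ig, from = 1, to = 5)
  best <- all[[which.max(lengths(all))]]
  expect_equal(as.integer(best), c(1L, 2L, 4L, 5L))
  # path graph a-b-c returns the unique path
  g2 <- new("SkeletonGraph", voxels = vox[1:3, ],
            edges = rbind(c(1L, 2L), c(2L, 3L)),
            boundaryDist = rep(1, 3), spacing = c(1, 1, 1),
            origin = c(0, 0, 0))
  expect_equal(nrow(linePoints(longestPath(g2, c(0, 0, 0),
                                           c(2, 1, 0)))), 3)
  # degenerate: identical endpoints give a single-point line
  expect_equal(nrow(linePoints(longestPath(g2, c(0, 0, 0),
                                           c(0, 0, 0)))), 1)
})

test_that("disconnected endpoints raise an informative error", {
  vox <- rbind(c(1L, 1L, 1L), c(2L, 1L, 1L), c(6L, 6L, 6L))
  g <- new("SkeletonGraph", voxels = vox,
           edges = matrix(c(1L, 2L), 1), boundaryDist = rep(1, 3),
           spacing = c(1, 1, 1), origin = c(0, 0, 0))
  expect_error(longestPath(g, c(0, 0, 0), c(5, 5, 5)), "components")
})

test_that("equidistant resampling hits exact arithmetic and errors", {
  line <- new("Centerline", points = cbind(seq(0, 10, 1), 0, 0),
              arcLength = seq(0, 10, 1))
  r <- resampleEquidistant(line, 2)
  expect_equal(arcLength(r), c(0, 2, 4, 6, 8, 10))
  expect_equal(linePoints(r)[, 1], c(0, 2, 4, 6, 8, 10))
  expect_error(resampleEquidistant(line, 11), "too short")
  # quarter circle radius 10: arc-length spacing 1 +/- 1e-3
  th <- seq(0, pi / 2, length.out = 2000)
  qpts <- cbind(10 * cos(th), 10 * sin(th), 0)
  qc <- new("Centerline", points = qpts,
            arcLength = c(0, cumsum(sqrt(rowSums(diff(qpts)^2)))))
  r2 <- resampleEquidistant(qc, 1)
  seg <- sqrt(rowSums(diff(linePoints(r2))^2))
  expect_true(all(abs(seg[-length(seg)] - 1) < 1e-3))
})

test_that("centerline extraction is deterministic and accurate on presets", {
  fx <- stomachTwinFixture()
  line1 <- fx$model$centerline
  line2 <- buildOrganModel(fx$mask, fx$path@points[1, ],
                           fx$path@points[nrow(fx$path@points), ])$centerline
  expect_identical(linePoints(line1), linePoints(line2))
  # directed Hausdorff both ways, against the stored ground-truth path
  diag <- sqrt(sum(gridSpacing(fx$mask)^2))
  dLine <- vapply(seq_len(nrow(linePoints(line1))), function(i)
    min(sqrt(rowSums(sweep(fx$path@points, 2, linePoints(line1)[i, ],
                           "-")^2))), 0)
  expect_lt(max(dLine), diag)
})
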