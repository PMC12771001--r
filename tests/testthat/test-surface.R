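test_that("radial casting recovers a cylinder's radius", {
  tube <- straightTubeMask(40, 17, 17, rMm = 5)
  line <- new("Centerline",
              points = cbind(seq(6, 33, 1), tube$axisY, tube$axisZ),
              arcLength = seq(0, 27, 1))
  sections <- castSections(tube$mask, line, 36)
  radii <- unlist(lapply(sections, function(s) s@radii))
  expect_true(all(abs(radii - 5) <= 0.5 + 1e-9))   # half in-plane spacing
})

test_that("elliptical sections follow the analytic radius profile", {
  # ellipse a=6, b=3 in the y-z plane, constant along x
  dm <- c(20L, 21L, 15L)
  dat <- array(0, dm)
  for (z in seq_len(dm[3])) for (y in seq_len(dm[2])) {
    if (((y - 11) / 6)^2 + ((z - 8) / 3)^2 <= 1) dat[, y, z] <- 1
  }
  mask <- LabelMask(dat)
  line <- new("Centerline", points = cbind(seq(4, 15, 1), 10, 7),
              arcLength = seq(0, 11, 1))
  sections <- castSections(mask, line, 72)
  s <- sections[[6]]
  # angle of each ray in the y-z plane, measured from the ellipse's y axis
  rel <- sweep(s@boundary, 2, s@center, "-")
  th <- atan2(rel[, 3], rel[, 2])
  rTheo <- 6 * 3 / sqrt(9 * cos(th)^2 + 36 * sin(th)^2)
  expect_true(all(abs(s@radii - rTheo) <= 0.75))   # sub-voxel tolerance
})

test_that("degenerate sections (center at the boundary) are an error", {
  tube <- straightTubeMask(30, 15, 15, rMm = 3)
  offAxis <- new("Centerline",
                 points = cbind(seq(6, 23, 1), tube$axisY + 4, tube$axisZ),
                 arcLength = seq(0, 17, 1))
  expect_error(castSections(tube$mask, offAxis, 36), "outside|degenerate")
  nearEdge <- new("Centerline",
                  points = cbind(seq(6, 23, 1), tube$axisY + 3.2,
                                 tube$axisZ),
                  arcLength = seq(0, 17, 1))
  expect_error(castSections(tube$mask, nearEdge, 36),
               "outside|degenerate")
})

test_that("NURBS fit reproduces a cylinder within half a voxel", {
  tube <- straightTubeMask(40, 17, 17, rMm = 5)
  line <- new("Centerline",
              points = cbind(seq(6, 33, 1), tube$axisY, tube$axisZ),
              arcLength = seq(0, 27, 1))
  surf <- fitNurbs(castSections(tube$mask, line, 36))
  S <- evaluateSurface(surf, seq(0, 1, length.out = 60),
                       seq(0, 1 - 1 / 48, length.out = 48))
  P <- matrix(S, ncol = 3)
  r <- sqrt((P[, 2] - tube$axisY)^2 + (P[, 3] - tube$axisZ)^2)
  expect_true(all(abs(r - 5) <= 0.5))
  expect_error(fitNurbs(castSections(tube$mask, line, 36)[1]), "at least")
})

test_that("shell interpolation is linear toward the centerline", {
  tube <- straightTubeMask(40, 17, 17, rMm = 5)
  line <- new("Centerline",
              points = cbind(seq(6, 33, 1), tube$axisY, tube$axisZ),
              arcLength = seq(0, 27, 1))
  surf <- fitNurbs(castSections(tube$mask, line, 36))
  expect_equal(controlNet(interpolateShell(surf, 0)), controlNet(surf))
  collapsed <- interpolateShell(surf, 1)
  for (i in seq_len(dim(controlNet(collapsed))[1]))
    expect_true(all(abs(sweep(controlNet(collapsed)[i, , ], 2,
                              sectionCenters(surf)[i, ])) < 1e-12))
  half <- interpolateShell(surf, 0.5)
  rel <- controlNet(half)[3, , ] - matrix(sectionCenters(surf)[3, ], 36, 3,
                                          byrow = TRUE)
  rel0 <- controlNet(surf)[3, , ] - matrix(sectionCenters(surf)[3, ], 36, 3,
                                           byrow = TRUE)
  expect_equal(rel, rel0 / 2, tolerance = 1e-12)
  expect_error(interpolateShell(surf, 1.2), "0, 1")
  # monotone shrinkage across a shell stack
  stack <- makeShellStack(surf)
  radAt <- function(s) {
    rel <- controlNet(s)[5, , ] - matrix(sectionCenters(s)[5, ], 36, 3,
                                         byrow = TRUE)
    sqrt(rowSums(rel^2))
  }
  r <- vapply(stack@surfaces, radAt, numeric(36))
  expect_true(all(diff(t(r)) <= 1e-12))
})

test_that("section frames carry no seam twist along curved organs", {
  fx <- stomachTwinFixture()
  sections <- castSections(fx$mask, fx$model$centerline, 36)
  firstRay <- t(vapply(sections, function(s)
    (s@boundary[1, ] - s@center) / sqrt(sum((s@boundary[1, ] - s@center)^2)),
    numeric(3)))
  dots <- rowSums(firstRay[-1, ] * firstRay[-nrow(firstRay), ])
  expect_true(all(dots > 0))
})

test_that("surface JSON serialization round-trips", {
  tube <- straightTubeMask(40, 17, 17, rMm = 5)
  line <- new("Centerline",
              points = cbind(seq(6, 33, 1), tube$axisY, tube$axisZ),
              arcLength = seq(0, 27, 1))
  surf <- fitNurbs(castSections(tube$mask, line, 12))
  f <- tempfile(fileext = ".json")
  writeSurfaceJSON(surf, f)
  back <- readSurfaceJSON(f)
  expect_equal(controlNet(back), controlNet(surf), tolerance = 1e-12)
  expect_equal(arcLength(back), arcLength(surf), tolerance = 1e-12)
  obj <- tempfile(fileext = ".obj")
  writeSurfaceOBJ(surf, obj, nu = 10L, nv = 8L)
  lines <- readLines(obj)
  expect_equal(sum(startsWith(lines, "v ")), 80)
  expect_equal(sum(startsWith(lines, "f ")), 8 * 9)
})
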