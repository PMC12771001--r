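test_that("wave and dispersion match their closed forms", {
  p <- stomachMotionParams()
  expect_equal(peristalticWave(55 / 4, 0, p), 16 / sqrt(3),
               tolerance = 1e-12)
  expect_equal(peristalticWave(0, 0, p), 0, tolerance = 1e-12)
  expect_equal(peristalticWave(27.5, 5.5, p), 0, tolerance = 1e-12)
  expect_equal(dispersion(10, 0), 1, tolerance = 1e-15)
  expect_equal(dispersion(0, 0.3), 1, tolerance = 1e-15)
  expect_equal(dispersion(10, 0.1), exp(-1), tolerance = 1e-15)
  expect_error(dispersion(-1, 0.1), ">= 0")
})

test_that("motion parameter validation and presets", {
  p <- stomachMotionParams()
  expect_equal(c(p@amplitude, p@wavelength, p@speed, p@attenuation),
               c(16, 55, 5, 0))
  expect_equal(nPhases(p), 21L)
  expect_equal(phaseTimes(p)[1], 0)
  expect_equal(max(phaseTimes(p)), 55 / 5)      # one full period
  b <- largeBowelMotionParams()
  expect_equal(c(b@wavelength, b@speed), c(40, 8))
  expect_error(motionParams(16, -5, 5), "wavelength")
  expect_error(motionParams(16, 55, 5, phaseTimes = c(1, 2),
                            nPhases = 2), "first phase")
})

simpleSurface <- function(radius = 10, nSections = 8, J = 12) {
  centers <- cbind(seq(0, 35, length.out = nSections), 0, 0)
  net <- array(0, c(nSections, J, 3))
  th <- 2 * pi * (seq_len(J) - 1) / J
  for (i in seq_len(nSections)) {
    net[i, , ] <- cbind(centers[i, 1], radius * cos(th), radius * sin(th))
  }
  new("NurbsSurface", controlNet = net, centers = centers,
      arcLength = centers[, 1], degreeU = 3L, degreeV = 3L)
}

test_that("control-point deformation moves points radially", {
  surf <- simpleSurface(radius = 10)
  p0 <- motionParams(0, 55, 5)
  expect_equal(controlNet(deformControls(surf, p0, 3)),
               controlNet(surf))                       # A = 0 identity
  # factor forced to -4 (sin = -1 at L = 3/4 lambda): radius 10 -> 6,
  # same angular position
  lam <- 40
  p <- motionParams(4 * sqrt(3), lam, 5)
  def <- deformControls(
    new("NurbsSurface", controlNet = surf@controlNet,
        centers = surf@centers,
        arcLength = rep(3 * lam / 4, length(surf@arcLength)),
        degreeU = 3L, degreeV = 3L), p, 0)
  rel <- controlNet(def)[2, , ] - matrix(sectionCenters(surf)[2, ], 12, 3,
                                         byrow = TRUE)
  expect_equal(unname(sqrt(rowSums(rel^2))), rep(6, 12),
               tolerance = 1e-9)
  rel0 <- controlNet(surf)[2, , ] - matrix(sectionCenters(surf)[2, ], 12, 3,
                                           byrow = TRUE)
  cosang <- rowSums(rel * rel0) / (6 * 10)
  expect_equal(unname(cosang), rep(1, 12), tolerance = 1e-9)
})

test_that("deformation equals the per-point formula (independent loop)", {
  surf <- simpleSurface(radius = 8, nSections = 10, J = 16)
  p <- motionParams(5, 30, 4)
  t <- 1.7
  def <- deformControls(surf, p, t)
  for (i in c(1, 4, 9)) for (j in c(1, 7, 16)) {
    L <- surf@arcLength[i]
    f <- (5 / sqrt(3)) * sin(2 * pi * (L - 4 * t) / 30)
    d <- surf@controlNet[i, j, ] - surf@centers[i, ]
    d <- d / sqrt(sum(d^2))
    expected <- surf@controlNet[i, j, ] + f * d
    expect_equal(controlNet(def)[i, j, ], expected, tolerance = 1e-12)
  }
})

test_that("contraction clamps at the minimum radius", {
  surf <- simpleSurface(radius = 2)
  p <- motionParams(16, 40, 8)     # |F| up to 9.24 > radius
  def <- deformControls(surf, p, 0, clampMm = 0.25)
  net <- controlNet(def)
  rel <- net
  for (comp in 1:3) rel[, , comp] <- net[, , comp] - surf@centers[, comp]
  radii <- sqrt(apply(rel^2, c(1, 2), sum))
  expect_true(all(radii >= 0.25 - 1e-12))
  expect_gt(attr(def, "clamped"), 0)
})

test_that("sequence synthesis: counts, periodicity, bounds, covariance", {
  surf <- simpleSurface()
  p <- stomachMotionParams()
  seqn <- synthesizeSequence(surf, p)
  expect_equal(nPhases(seqn), 21)
  # phase 0 and phase 20 coincide (one full period, alpha = 0)
  expect_equal(controlNet(seqn@surfaces[[1]]),
               controlNet(seqn@surfaces[[21]]), tolerance = 1e-9)
  # single-phase sequence
  one <- synthesizeSequence(surf, motionParams(16, 55, 5, nPhases = 1))
  expect_equal(nPhases(one), 1)
  # displacement bound A/sqrt(3) for unit d, alpha = 0
  for (k in c(3, 11, 18)) {
    d <- controlNet(seqn@surfaces[[k]]) - controlNet(surf)
    mag <- sqrt(apply(d^2, c(1, 2), sum))
    expect_true(all(mag <= 16 / sqrt(3) + 1e-9))
  }
  # translation covariance: shifting t by delta == shifting L by c*delta
  delta <- 0.8
  set.seed(3)
  L <- runif(20, 0, 200)
  expect_equal(peristalticWave(L, 2 + delta, p),
               peristalticWave(L - 5 * delta, 2, p), tolerance = 1e-12)
})
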