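test_that("voxelize averages collisions and leaves untouched voxels zero", {
  g <- VolumeGrid(array(0, c(8, 8, 8)), spacing = c(1, 1, 1))
  X <- rbind(c(3.1, 3, 3), c(2.9, 3, 3))     # same voxel
  s <- new("ShellSampleSet", original = X,
           deformed = X + rbind(c(1, 0, 0), c(3, 0, 0)),
           u = c(0, 0), v = c(0, 0), p = c(0, 0))
  f <- voxelize(s, g)
  expect_equal(voxelData(f)[4, 4, 4, ], c(2, 0, 0))
  expect_equal(sum(voxelData(f) != 0), 1)
  bad <- new("ShellSampleSet", original = rbind(c(20, 1, 1)),
             deformed = rbind(c(20, 1, 1)), u = 0, v = 0, p = 0)
  expect_error(voxelize(bad, g), "outside")
})

test_that("voxelize matches a naive double loop on random samples", {
  set.seed(7)
  dm <- c(10L, 9L, 8L)
  g <- VolumeGrid(array(0, dm), spacing = c(1.2, 0.8, 2), origin = c(3, 0, -4))
  n <- 200
  X <- cbind(runif(n, 3, 3 + 9 * 1.2), runif(n, 0, 8 * 0.8),
             runif(n, -4, -4 + 7 * 2))
  V <- matrix(rnorm(3 * n), n)
  s <- new("ShellSampleSet", original = X, deformed = X + V,
           u = numeric(n), v = numeric(n), p = numeric(n))
  f <- voxelize(s, g)
  expected <- oracleVoxelize(X, V, dm, gridSpacing(g), gridOrigin(g))
  expect_equal(voxelData(f), expected, tolerance = 1e-9)
})

test_that("smoothFill honors the simple contracts", {
  dm <- c(6L, 5L, 4L)
  z <- DisplacementField(array(0, c(dm, 3)))
  sup <- LabelMask(array(1, dm))
  out <- smoothFill(z, sup)
  expect_equal(voxelData(out), voxelData(z))
  expect_lte(out@info$iterations, 1)
  # row [v, 0, v]: middle voxel becomes the average of equal neighbors
  dat <- array(0, c(3, 1, 1, 3))
  dat[1, 1, 1, ] <- c(2, 0, 0); dat[3, 1, 1, ] <- c(2, 0, 0)
  f <- DisplacementField(dat)
  out2 <- smoothFill(f, LabelMask(array(1, c(3, 1, 1))))
  expect_equal(voxelData(out2)[2, 1, 1, ], c(2, 0, 0))
  expect_equal(voxelData(out2)[1, 1, 1, ], c(2, 0, 0))  # seed unchanged
})

test_that("smoothFill matches the naive loop implementation exactly", {
  set.seed(11)
  dm <- c(9L, 8L, 7L)
  dat <- array(0, c(dm, 3))
  seeds <- sample(prod(dm), 25)
  for (c in 1:3) {
    comp <- array(0, dm)
    comp[seeds] <- rnorm(25)
    dat[, , , c] <- comp
  }
  sup <- array(0, dm)
  sup[2:8, 2:7, 2:6] <- 1
  sup[seeds] <- 1
  f <- DisplacementField(dat)
  out <- smoothFill(f, LabelMask(sup), tolMm = 0.001)
  seedMask <- dat[, , , 1] != 0 | dat[, , , 2] != 0 | dat[, , , 3] != 0
  expected <- oracleSmoothFill(dat, sup > 0 & !seedMask, tol = 0.001)
  expect_equal(voxelData(out), expected$field, tolerance = 1e-9)
  expect_equal(out@info$iterations, expected$iterations)
  # seeds unchanged, terminal residual below tolerance
  for (c in 1:3)
    expect_equal(voxelData(out)[, , , c][seedMask],
                 dat[, , , c][seedMask])
  expect_lt(out@info$residual, 0.001)
  # discrete maximum principle on the magnitude
  mag <- sqrt(voxelData(out)[, , , 1]^2 + voxelData(out)[, , , 2]^2 +
              voxelData(out)[, , , 3]^2)
  seedMag <- sqrt(dat[, , , 1]^2 + dat[, , , 2]^2 + dat[, , , 3]^2)
  expect_lte(max(mag), max(seedMag) + 1e-12)
})

test_that("smoothFill approaches harmonic interpolation between plates", {
  # seeds on two opposite x-faces; the limit is linear in x
  dm <- c(7L, 5L, 5L)
  dat <- array(0, c(dm, 3))
  dat[1, , , 1] <- 2
  dat[7, , , 1] <- 4
  f <- DisplacementField(dat)
  out <- smoothFill(f, LabelMask(array(1, dm)), tolMm = 1e-7)
  lin <- 2 + (4 - 2) * (0:6) / 6
  for (x in 2:6)
    expect_equal(mean(voxelData(out)[x, , , 1]), lin[x], tolerance = 1e-3)
})

test_that("warping follows the inverse-map contract", {
  dm <- c(12L, 10L, 8L)
  img <- VolumeGrid(array(rnorm(prod(dm)), dm))
  zero <- DisplacementField(array(0, c(dm, 3)))
  expect_equal(voxelData(warpVolume(img, zero, "image")), voxelData(img),
               tolerance = 1e-12)
  # uniform +3 voxel x-shift moves an impulse by +3 voxels
  imp <- array(0, dm); imp[4, 5, 4] <- 1
  u <- array(0, c(dm, 3)); u[, , , 1] <- 3
  shift <- DisplacementField(u)
  w <- warpVolume(VolumeGrid(imp), shift, "image")
  expect_equal(voxelData(w)[7, 5, 4], 1, tolerance = 1e-9)
  expect_equal(sum(voxelData(w)), 1, tolerance = 1e-9)
  # warp then warp back with the negated field restores the interior
  smooth <- VolumeGrid(array(rep(sin(seq(0, 3, length.out = dm[1])), 80),
                             dm))
  back <- DisplacementField(-u)
  rt <- warpVolume(warpVolume(smooth, shift, "image"), back, "image")
  expect_equal(voxelData(rt)[5:9, , ], voxelData(smooth)[5:9, , ],
               tolerance = 1e-9)
})

test_that("mask warping is exact under the zero field", {
  tube <- straightTubeMask(20, 11, 11, rMm = 3)
  zero <- DisplacementField(array(0, c(gridDim(tube$mask), 3)))
  w <- warpVolume(tube$mask, zero, "mask")
  expect_identical(voxelData(w), voxelData(tube$mask))
})

test_that("log-Jacobian matches closed forms", {
  dm <- c(10L, 10L, 10L)
  zero <- DisplacementField(array(0, c(dm, 3)))
  expect_true(all(voxelData(logJacobian(zero)) == 0))
  u <- array(0, c(dm, 3)); u[, , , 2] <- 4.2
  expect_true(all(abs(voxelData(logJacobian(
    DisplacementField(u)))) < 1e-12))
  # u_x = 0.1 x  ->  log det = log(1.1) everywhere (exact for linear)
  lin <- array(0, c(dm, 3))
  xw <- (0:(dm[1] - 1)) * 1.5
  lin[, , , 1] <- array(rep(0.1 * xw, dm[2] * dm[3]), dm)
  jac <- logJacobian(DisplacementField(lin, spacing = c(1.5, 1, 1)))
  expect_equal(max(abs(voxelData(jac) - log(1.1))), 0, tolerance = 1e-9)
  expect_identical(jac@folded, 0L)
  # folding: strong negative gradient flips the determinant to NaN
  fold <- array(0, c(dm, 3))
  fold[, , , 1] <- array(rep(-2 * xw, dm[2] * dm[3]), dm)
  jf <- logJacobian(DisplacementField(fold, spacing = c(1.5, 1, 1)))
  expect_gt(jf@folded, 0)
})

test_that("identity deformation voxelizes to the zero field", {
  fx <- stomachTwinFixture()
  stack <- fx$model$stack
  s <- sampleShells(stack, stack, nu = 40L, nv = 24L)
  f <- voxelize(s, fx$mask)
  expect_true(all(voxelData(f) == 0))
  # rigid translation: every sample vector equals the shift
  shifted <- stack
  for (k in seq_along(shifted@surfaces)) {
    net <- controlNet(shifted@surfaces[[k]])
    net[, , 1] <- net[, , 1] + 1
    shifted@surfaces[[k]] <- initialize(shifted@surfaces[[k]],
      controlNet = net,
      centers = cbind(shifted@surfaces[[k]]@centers[, 1] + 1,
                      shifted@surfaces[[k]]@centers[, -1]))
  }
  s2 <- sampleShells(stack, shifted, nu = 20L, nv = 12L)
  V <- s2@deformed - s2@original
  expect_equal(max(abs(sweep(V, 2, c(1, 0, 0)))), 0, tolerance = 1e-9)
})
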