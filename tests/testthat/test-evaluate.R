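test_that("TRE: identity, Pythagoras, and naive-loop equivalence", {
  dm <- c(12L, 12L, 10L)
  gt <- randomSmoothField(dm, scale = 0.8, seed = 4)
  pts <- cbind(runif(40, 1, 10), runif(40, 1, 10), runif(40, 1, 8))
  t0 <- tre(pts, gt, gt)
  expect_equal(t0$mean, 0, tolerance = 1e-12)
  # candidate offset by (3, 4, 0): TRE exactly 5 everywhere
  off <- gt@data
  off[, , , 1] <- off[, , , 1] + 3
  off[, , , 2] <- off[, , , 2] + 4
  cand <- DisplacementField(off)
  t5 <- tre(pts, gt, cand)
  expect_equal(unname(t5$perPoint), rep(5, 40), tolerance = 1e-9)
  # random smooth fields: matches the unvectorized loop
  cand2 <- randomSmoothField(dm, scale = 0.5, seed = 9)
  t2 <- tre(pts, gt, cand2)
  expect_equal(t2$perPoint, oracleTRE(pts, gt, cand2), tolerance = 1e-9)
  # symmetry
  expect_equal(tre(pts, cand2, gt)$perPoint, t2$perPoint,
               tolerance = 1e-12)
  expect_error(tre(rbind(c(100, 0, 0)), gt, cand2), "outside")
})

test_that("DSC arithmetic and edge cases", {
  dm <- c(10L, 10L, 4L)
  a <- array(0, dm); a[1:5, 1:5, ] <- 1       # 100 voxels
  b <- array(0, dm); b[3:7, 1:5, ] <- 1       # 100 voxels, overlap 60
  ma <- LabelMask(a); mb <- LabelMask(b)
  expect_equal(dsc(ma, ma), 1)
  expect_equal(dsc(ma, mb), 2 * 60 / 200)
  expect_equal(dsc(ma, mb), dsc(mb, ma))
  disj <- array(0, dm); disj[8:10, 8:10, ] <- 1
  expect_equal(dsc(ma, LabelMask(disj)), 0)
  expect_message(v <- dsc(LabelMask(array(0, dm)), LabelMask(array(0, dm))),
                 "empty")
  expect_equal(v, 1)
})

test_that("HD95 is spacing-aware and matches the brute-force oracle", {
  dm <- c(16L, 12L, 10L)
  a <- array(0, dm); a[4:8, 4:8, 3:6] <- 1
  b <- array(0, dm); b[7:11, 4:8, 3:6] <- 1   # +3 voxels along x
  ma <- LabelMask(a); mb <- LabelMask(b)
  h <- hd95(ma, mb)
  expect_equal(h, oracleHd95(a, b, c(1, 1, 1)), tolerance = 1e-9)
  expect_equal(h, 3, tolerance = 1e-9)
  expect_equal(hd95(ma, ma), 0)
  expect_equal(hd95(mb, ma), h, tolerance = 1e-12)    # symmetric
  # anisotropic: one-slice z-shift at 5 mm slices
  az <- array(0, dm); az[4:8, 4:8, 3:6] <- 1
  bz <- array(0, dm); bz[4:8, 4:8, 4:7] <- 1
  maz <- LabelMask(az, spacing = c(1, 1, 5))
  mbz <- LabelMask(bz, spacing = c(1, 1, 5))
  expect_equal(hd95(maz, mbz), oracleHd95(az, bz, c(1, 1, 5)),
               tolerance = 1e-9)
  expect_equal(hd95(maz, mbz), 5, tolerance = 1e-9)
  expect_error(hd95(ma, LabelMask(array(0, dm))), "non-empty")
})

test_that("DWE: identity, constant ratio, cancellation, invariances", {
  dm <- c(8L, 8L, 6L)
  set.seed(5)
  gt <- VolumeGrid(array(runif(prod(dm), 1, 50), dm))
  roi <- LabelMask(array(1, dm))
  expect_equal(as.numeric(dwe(gt, gt, roi)), 0)
  up <- VolumeGrid(voxelData(gt) * 1.1)
  expect_equal(as.numeric(dwe(up, gt, roi)), 10, tolerance = 1e-9)
  # +10% on half the voxels, -10% on the other half: signed mean 0
  mix <- voxelData(gt)
  sel <- array(rep(c(TRUE, FALSE), length.out = prod(dm)), dm)
  mix[sel] <- mix[sel] * 1.1
  mix[!sel] <- mix[!sel] * 0.9
  expect_equal(as.numeric(dwe(VolumeGrid(mix), gt, roi)), 0,
               tolerance = 1e-9)
  # invariant to rescaling both dose maps
  expect_equal(as.numeric(dwe(VolumeGrid(mix * 3), VolumeGrid(voxelData(gt) * 3),
                              roi)),
               as.numeric(dwe(VolumeGrid(mix), gt, roi)), tolerance = 1e-9)
  # dose floor excludes low-dose voxels
  low <- voxelData(gt); low[1:4, , ] <- 0.1
  gl <- VolumeGrid(low)
  out <- dwe(gl, gl, roi, floorGy = 0.5)
  expect_equal(as.numeric(out), 0)
  expect_equal(attr(out, "excluded"), sum(low <= 0.5))
  expect_error(dwe(gl, VolumeGrid(array(0.1, dm)), roi), "floor")
})

test_that("dose accumulation by direct dose mapping", {
  dm <- c(14L, 10L, 8L)
  dose <- VolumeGrid(array(rnorm(prod(dm), 30, 5), dm))
  zero <- DisplacementField(array(0, c(dm, 3)))
  acc <- accumulateDose(dose, list(zero, zero))
  expect_equal(voxelData(acc), voxelData(dose), tolerance = 1e-12)
  # two opposite uniform shifts of a linear ramp average to the ramp
  ramp <- VolumeGrid(array(rep(seq(0, 26, 2), dm[2] * dm[3]), dm))
  up <- array(0, c(dm, 3)); up[, , , 1] <- 2
  dn <- array(0, c(dm, 3)); dn[, , , 1] <- -2
  acc2 <- accumulateDose(ramp, list(DisplacementField(up),
                                    DisplacementField(dn)))
  expect_equal(voxelData(acc2)[4:11, , ], voxelData(ramp)[4:11, , ],
               tolerance = 1e-9)
})

test_that("binned RMSE: identity, uniform offset, naive oracle", {
  dm <- c(12L, 11L, 9L)
  gt <- randomSmoothField(dm, scale = 2, seed = 21)
  out0 <- rmseBinned(gt, gt, "motion")
  expect_true(all(out0$rmse == 0))
  off <- gt@data; off[, , , 1] <- off[, , , 1] + 2
  cand <- DisplacementField(off)
  out2 <- rmseBinned(gt, cand, "motion")
  expect_true(all(abs(out2$rmse - 2) < 1e-9))
  edges <- c(0, 1, 2, 5)
  cand2 <- randomSmoothField(dm, scale = 1.3, seed = 22)
  mine <- rmseBinned(gt, cand2, "motion", edges = edges)
  orc <- oracleRmseBinned(gt@data, cand2@data, edges)
  expect_equal(mine$rmse, orc$rmse, tolerance = 1e-9)
  expect_equal(mine$n, orc$n)
  # dose binning uses the aux volume
  dose <- VolumeGrid(array(runif(prod(dm), 0, 50), dm))
  byDose <- rmseBinned(gt, cand2, "dose", aux = dose,
                       edges = c(0, 10, 30, 60))
  expect_equal(sum(byDose$n), prod(dm))
  expect_error(rmseBinned(gt, cand2, "dose"), "aux")
  expect_error(rmseBinned(gt, cand2, "motion", edges = c(2, 1)),
               "increasing")
})

test_that("evaluateDVF assembles a coherent report", {
  dm <- c(16L, 14L, 12L)
  gt <- randomSmoothField(dm, scale = 0.6, seed = 31)
  cand <- randomSmoothField(dm, scale = 0.6, seed = 32)
  organ <- array(0, dm); organ[5:12, 5:10, 4:9] <- 1
  mask <- LabelMask(organ)
  pts <- cbind(runif(30, 5, 11), runif(30, 5, 9), runif(30, 4, 8))
  dose <- VolumeGrid(array(runif(prod(dm), 5, 40), dm))
  rep <- evaluateDVF(gt, cand, mask, pts, dose = dose)
  m <- rep@metrics
  expect_true(m$dsc >= 0 && m$dsc <= 1)
  expect_gte(m$hd95, 0)
  expect_gte(m$treMean, 0)
  expect_true(is.finite(m$dwePercent))
  expect_true(nrow(rep@rmseByMotion) >= 1)
  expect_true(nrow(rep@rmseByDose) >= 1)
  expect_s4_class(rep@info$errorVolume, "VolumeGrid")
  # self-evaluation is perfect
  self <- evaluateDVF(gt, gt, mask, pts, dose = dose)
  expect_equal(self@metrics$treMean, 0, tolerance = 1e-12)
  expect_equal(self@metrics$dsc, 1)
  expect_equal(self@metrics$hd95, 0)
  expect_equal(self@metrics$dwePercent, 0, tolerance = 1e-12)
  expect_true(all(self@rmseByMotion$rmse == 0))
})
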