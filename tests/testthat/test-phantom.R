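test_that("straight-tube mask stays within the stated radius", {
  pts <- cbind(seq(4, 26, length.out = 45), 7, 7)
  spec <- phantomSpec(pts, 3, shape = c(30, 15, 15))
  mask <- makeTubeMask(spec)
  fg <- which(voxelData(mask) > 0, arr.ind = TRUE)
  w <- indexToWorld(mask, fg)
  dAxis <- sqrt((w[, 2] - 7)^2 + (w[, 3] - 7)^2)
  # interior voxels: strictly within the radius (tube body, away from ends)
  body <- w[, 1] > 5 & w[, 1] < 25
  expect_true(all(dAxis[body] <= 3 + 1e-9))
  expect_gt(sum(body), 100)
})

test_that("sub-voxel tube radius is an error", {
  pts <- cbind(seq(4, 26, length.out = 45), 7, 7)
  spec <- phantomSpec(pts, 0.4, shape = c(30, 15, 15))
  expect_error(makeTubeMask(spec), "sub-voxel")
})

test_that("preset tube is one solid component without cavities", {
  spec <- phantomPreset("stomach", shape = c(64, 64, 64), spacing = c(3, 3, 3),
                        noiseSd = 0)
  mask <- makeTubeMask(spec)
  dm <- gridDim(mask)
  shift6 <- function(a) {      # union of 6-neighbor shifts
    out <- array(FALSE, dm)
    out[-1, , ] <- out[-1, , ] | a[-dm[1], , ]
    out[-dm[1], , ] <- out[-dm[1], , ] | a[-1, , ]
    out[, -1, ] <- out[, -1, ] | a[, -dm[2], ]
    out[, -dm[2], ] <- out[, -dm[2], ] | a[, -1, ]
    out[, , -1] <- out[, , -1] | a[, , -dm[3]]
    out[, , -dm[3]] <- out[, , -dm[3]] | a[, , -1]
    out
  }
  flood <- function(seed, domain) {
    reached <- seed & domain
    repeat {
      grown <- (reached | shift6(reached)) & domain
      if (identical(grown, reached)) break
      reached <- grown
    }
    reached
  }
  fg <- voxelData(mask) > 0
  seed <- array(FALSE, dm)
  seed[which(fg)[1]] <- TRUE
  expect_true(all(flood(seed, fg) == fg))       # one connected component
  # no cavities: all background reachable from the volume border
  border <- array(FALSE, dm)
  border[c(1, dm[1]), , ] <- TRUE
  border[, c(1, dm[2]), ] <- TRUE
  border[, , c(1, dm[3])] <- TRUE
  expect_true(all(flood(border & !fg, !fg) == !fg))
})

test_that("phantom image renders three levels, deterministically", {
  spec <- phantomPreset("stomach", shape = c(48, 48, 48), spacing = c(4, 4, 4),
                        noiseSd = 0)
  mask <- makeTubeMask(spec)
  img <- makePhantomImage(mask, spec)
  expect_setequal(unique(as.vector(voxelData(img))), c(50, 300, 100))
  spec2 <- phantomPreset("stomach", shape = c(48, 48, 48),
                         spacing = c(4, 4, 4), noiseSd = 10, seed = 11)
  a <- makePhantomImage(mask, spec2)
  b <- makePhantomImage(mask, spec2)
  expect_identical(voxelData(a), voxelData(b))
  spec3 <- phantomPreset("stomach", shape = c(48, 48, 48),
                         spacing = c(4, 4, 4), noiseSd = 10, seed = 12)
  expect_false(identical(voxelData(a),
                         voxelData(makePhantomImage(mask, spec3))))
})

test_that("dose map follows the Gaussian closed form", {
  g <- VolumeGrid(array(0, c(21, 21, 21)), spacing = c(2, 2, 2))
  ctr <- c(20, 20, 20)
  dose <- makeDoseMap(g, ctr, peakGy = 40, sigmaMm = 10)
  expect_equal(max(voxelData(dose)), 40)
  # value at one sigma from the (snapped) center
  v <- voxelData(dose)[16, 11, 11]     # 10 mm along x from center voxel
  expect_equal(v, 40 * exp(-0.5), tolerance = 1e-12)
  # huge sigma: near-uniform
  flat <- makeDoseMap(g, ctr, peakGy = 10, sigmaMm = 1e5)
  expect_lt(diff(range(voxelData(flat))), 1e-4)
})
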