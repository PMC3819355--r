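boxMask <- function(shape, lo, hi) {
  m <- array(FALSE, shape)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

test_that("voxelwise tSNR is mean over population SD, NA for flat voxels", {
  arr <- array(0, c(2, 2, 1, 4))
  arr[1, 1, 1, ] <- c(98, 102, 98, 102)    # mean 100, sd 2
  arr[2, 1, 1, ] <- c(10, 10, 10, 10)      # zero variance
  arr[1, 2, 1, ] <- c(1, 2, 3, 4)
  arr[2, 2, 1, ] <- c(-5, 5, -5, 5)        # mean 0
  vol <- volumeSeries(arr, samplingInterval = 2)
  m <- voxelwiseTsnr(vol)
  expect_equal(m[1, 1, 1], 50)
  expect_true(is.na(m[2, 1, 1]))
  expect_equal(m[1, 2, 1], 2.5 / sqrt(1.25))
  expect_equal(m[2, 2, 1], 0)
  # scaling all intensities leaves the map unchanged
  m2 <- voxelwiseTsnr(volumeSeries(arr * 3, samplingInterval = 2))
  expect_equal(m2, m)
})

test_that("synthetic volumes are seeded and hit the expected tSNR", {
  v1 <- synthVolume(noiseSd = 8, seed = 3)
  v2 <- synthVolume(noiseSd = 8, seed = 3)
  expect_identical(v1@data, v2@data)              # bitwise reproducible
  expect_false(identical(v1@data, synthVolume(noiseSd = 8, seed = 4)@data))
  tsnr <- voxelwiseTsnr(v1)
  expect_equal(mean(tsnr), 100 / 8, tolerance = 0.05)  # resting mode
  expect_true(any(v1@mask) && any(!v1@mask))
})

test_that("ROI estimates average regions and mirror under complement", {
  vol <- synthVolume(shape = c(6, 6, 4), design = designSpec("block"),
                     psc = 2, noiseSd = 1, seed = 11)
  est <- roiActivationEstimate(vol)
  flip <- roiActivationEstimate(vol, !vol@mask)
  expect_identical(samples(est$inMask), samples(flip$outMask))
  expect_identical(samples(est$outMask), samples(flip$inMask))
  # planted course recovered within noise / sqrt(n_voxels)
  planted <- activationSignal(designSpec("block"), psc = 2)
  nIn <- sum(vol@mask)
  resid <- samples(est$inMask) - samples(planted)
  expect_lt(sd(resid), 3 / sqrt(nIn))
  # homogeneous volume: both regions give identical flat courses
  flat <- volumeSeries(array(7, c(2, 2, 2, 5)), samplingInterval = 1)
  m <- boxMask(c(2, 2, 2), c(1, 1, 1), c(1, 2, 2))
  efl <- roiActivationEstimate(flat, m)
  expect_equal(samples(efl$inMask), samples(efl$outMask))
  expect_error(roiActivationEstimate(flat, array(TRUE, c(2, 2, 2))),
               "each region")
})

test_that("noise isolation removes the region course", {
  vol <- synthVolume(shape = c(6, 6, 4), design = designSpec("block"),
                     psc = 1, noiseSd = 2, seed = 21,
                     nTime = 100)
  est <- roiActivationEstimate(vol)
  res <- roiNoiseIsolate(vol, est$inMask, vol@mask)
  expect_equal(dim(res), c(sum(vol@mask), 100))
  expect_equal(mean(rowMeans(res)), 0, tolerance = 0.2)
  # a voxel equal to the region average leaves a zero residual
  arr <- vol@data
  arr[1, 1, 1, ] <- samples(est$inMask)
  m2 <- array(FALSE, dim(arr)[1:3]); m2[1, 1, 1] <- TRUE; m2[6, 6, 4] <- TRUE
  v2 <- volumeSeries(arr, samplingInterval = 2)
  r2 <- roiNoiseIsolate(v2, est$inMask, m2)
  expect_equal(max(abs(r2[1, ])), 0)
  # residual SD recovers the planted noise SD within 10% at 200 points
  vol200 <- synthVolume(shape = c(6, 6, 4),
                        design = designSpec("block"), psc = 1,
                        noiseSd = 2, seed = 22)
  e200 <- roiActivationEstimate(vol200)
  r200 <- roiNoiseIsolate(vol200, e200$inMask, vol200@mask)
  sds <- apply(r200, 1, sd)
  expect_equal(mean(sds), 2, tolerance = 0.1)
})

test_that("region CNR is complement-symmetric and scales with noise", {
  vol <- synthVolume(shape = c(6, 6, 4), design = designSpec("block"),
                     psc = 1, noiseSd = 1, seed = 31)
  s <- regionCnr(vol, metric = "cnr_amp")
  sFlip <- regionCnr(vol, mask = !vol@mask, metric = "cnr_amp")
  expect_equal(s@inMask, sFlip@outMask)
  expect_equal(s@outMask, sFlip@inMask)
  expect_true(s@inMask[["min"]] <= s@inMask[["mean"]] &&
                s@inMask[["mean"]] <= s@inMask[["max"]])
  # halving the planted noise roughly doubles the in-mask SD-based CNR
  # (the amplitude estimator takes a maximum over noisy samples, so its
  # small upward noise bias would blur the factor; sigma_S is additive in
  # variance and nearly unbiased here)
  wide <- boxMask(c(6, 6, 4), c(2, 2, 1), c(5, 5, 4))   # 64 voxels, so the
  # averaged course carries little residual noise
  volW <- synthVolume(shape = c(6, 6, 4), design = designSpec("block"),
                      psc = 1, noiseSd = 1, mask = wide, seed = 31)
  sSd <- regionCnr(volW, metric = "cnr_sd")
  volHalf <- synthVolume(shape = c(6, 6, 4), design = designSpec("block"),
                         psc = 1, noiseSd = 0.5, mask = wide, seed = 31)
  sHalf <- regionCnr(volHalf, metric = "cnr_sd")
  expect_equal(sHalf@inMask[["mean"]] / sSd@inMask[["mean"]], 2,
               tolerance = 0.1)
  # a mask planted with no activation has SD-based CNR near zero (the
  # region-average course retains noise of SD sigma/sqrt(n_voxels))
  rest <- synthVolume(shape = c(6, 6, 4), noiseSd = 1, seed = 32,
                      nTime = 200)
  bigMask <- boxMask(c(6, 6, 4), c(2, 2, 1), c(5, 5, 4))   # 64 voxels
  sRest <- regionCnr(rest, mask = bigMask, metric = "cnr_sd")
  expect_lt(sRest@inMask[["mean"]], 2.5 / sqrt(64))
})

test_that("NIfTI round-trips preserve data, TR and mask", {
  vol <- synthVolume(shape = c(4, 4, 3), design = designSpec("block"),
                     psc = 1, noiseSd = 1, seed = 41)
  img <- tempfile(fileext = ".nii.gz")
  msk <- tempfile(fileext = ".nii.gz")
  writeVolume(vol, img)
  writeVolume(array(as.numeric(vol@mask), dim(vol@mask)), msk)
  back <- readVolume(img, msk)
  expect_equal(back@data, vol@data, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back@samplingInterval, 2)
  expect_identical(back@mask, vol@mask)
  unlink(c(img, msk))
})
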