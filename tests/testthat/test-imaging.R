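# small handmade stacks: array indexed (channel, z, y, x)
mkStack <- function(arr, pixel_um = 1, slice_um = 1) {
  ZStack(arr, pixel_um = pixel_um, slice_um = slice_um)
}
mkMask <- function(m, pixel_um = 1, slice_um = 1) {
  BinaryStack(m, pixel_um = pixel_um, slice_um = slice_um)
}

test_that("median denoising removes hot pixels and keeps flats", {
  arr <- array(50, c(3, 6, 9, 9))
  expect_identical(intensityArray(medianDenoise(mkStack(arr), 3)), arr)
  expect_identical(medianDenoise(mkStack(arr), 1), mkStack(arr)) # identity

  hot <- array(0, c(3, 6, 9, 9))
  hot[1, 3, 5, 5] <- 255
  den <- medianDenoise(mkStack(hot), 3)
  expect_true(all(intensityArray(den) == 0))
  expect_error(medianDenoise(mkStack(hot), 4), "odd")
})

test_that("Otsu threshold agrees with the exhaustive-search oracle", {
  v <- c(rep(10, 900), rep(200, 100))
  t0 <- otsuThreshold(v)
  expect_equal(t0, otsuOracle(v))
  expect_equal(sum(v > t0), 100)

  half <- c(rep(0, 50), rep(255, 50))
  expect_equal(sum(half > otsuThreshold(half)), 50)

  set.seed(21)
  for (i in 1:100) {
    img <- sample(0:255, 400, replace = TRUE)
    expect_identical(as.numeric(otsuThreshold(img)), as.numeric(otsuOracle(img)))
  }
})

test_that("binarization detects the bright class and flags constants", {
  arr <- array(10, c(3, 4, 10, 10))
  arr[1, 2, 1:5, ] <- 200
  bs <- otsuBinarize(mkStack(arr), "syto9")
  expect_equal(sum(maskArray(bs)), 50)
  expect_false(isDegenerate(bs))

  flat <- array(0, c(3, 4, 10, 10))
  bs0 <- otsuBinarize(mkStack(flat), 1)
  expect_true(isDegenerate(bs0))
  expect_equal(sum(maskArray(bs0)), 0)
})

test_that("base-slice removal drops exactly the substrate slices", {
  m <- array(FALSE, c(30, 5, 5))
  m[1:4, , ] <- TRUE # artifact confined to the first four slices
  m[10, 2, 2] <- TRUE
  bs <- mkMask(m)
  out <- removeBaseSlices(bs, 4)
  expect_equal(nSlices(out), 26)
  expect_equal(sum(maskArray(out)), 1)
  expect_identical(removeBaseSlices(bs, 0), bs)
  shallow <- mkMask(array(TRUE, c(4, 5, 5)))
  expect_error(removeBaseSlices(shallow, 4), "insufficient")
})

test_that("merging is a voxelwise OR: identity, additivity, idempotence", {
  a <- array(FALSE, c(3, 4, 4))
  a[1, 1, 1:2] <- TRUE # 2 voxels
  b <- array(FALSE, c(3, 4, 4))
  b[2, 3, 1:4] <- TRUE # 4 voxels, disjoint
  empty <- array(FALSE, c(3, 4, 4))
  ma <- mkMask(a)
  expect_equal(maskArray(mergeBinary(list(ma, mkMask(empty)))), a)
  expect_equal(sum(maskArray(mergeBinary(list(ma, mkMask(b))))), 6)
  expect_equal(maskArray(mergeBinary(list(ma, ma))), a)
  expect_error(mergeBinary(list(ma, mkMask(array(FALSE, c(2, 4, 4))))),
               "mismatch")
})

test_that("per-slice areas, maximum area and coverage", {
  m <- array(FALSE, c(3, 10, 10))
  m[1, , ] <- TRUE          # 100 px
  m[2, 1:5, 1:9] <- TRUE    # 45 px
  bs <- mkMask(m)
  expect_equal(sliceAreas(bs), c(100, 45, 0))
  ma <- maxArea(bs)
  expect_equal(ma$max_area_um2, 100)
  expect_equal(ma$coverage, 1)
  expect_equal(maxArea(mkMask(array(FALSE, c(3, 10, 10))))$max_area_um2, 0)
})

test_that("MBH counts occupied slices, contiguous or not", {
  m <- array(FALSE, c(20, 5, 5))
  m[c(1:10, 15, 20), 3, 3] <- TRUE
  expect_equal(maxBiofilmHeight(mkMask(m)), 12)
  expect_equal(maxBiofilmHeight(mkMask(m, slice_um = 0.5)), 6)
  expect_equal(maxBiofilmHeight(mkMask(array(FALSE, c(5, 4, 4)))), 0)
})

test_that("biovolume sums slice areas times slice thickness", {
  m <- array(FALSE, c(3, 10, 10))
  m[1, , ] <- TRUE
  m[2, 1:5, ] <- TRUE
  m[3, 1:5, 1:5] <- TRUE
  expect_equal(biovolume(mkMask(m)), 175)
  expect_equal(biovolume(mkMask(array(FALSE, c(3, 4, 4)))), 0)
})

test_that("hemisphere geometry matches continuum values at fine voxels", {
  r <- 20
  scn <- cleanStackScenario(
    frame_px = 100, n_slices = 24, pixel_um = 0.5, slice_um = 1,
    clusters = list(list(center_um = c(25, 25), radius_um = r)),
    eps_voxel_fraction = 0
  )
  sim <- simulateZStack(scn)
  mask <- mkMask(sim$truth$mask, pixel_um = 0.5, slice_um = 1)
  expect_equal(maxBiofilmHeight(mask), r) # slices 0..r-1 occupied
  expect_lt(abs(maxArea(mask)$max_area_um2 - pi * r^2) / (pi * r^2), 0.05)
  expect_lt(abs(biovolume(mask) - 2 / 3 * pi * r^3) / (2 / 3 * pi * r^3), 0.1)
})

test_that("quantifyStack equals the manual composition of its stages", {
  sim <- simulateZStack(stackScenario(background_mean = 15,
                                      background_sd = 5, seed = 4))
  st <- sim$stack
  m <- quantifyStack(st, kernel = 3, base_slices = 4)

  den <- medianDenoise(st, 3)
  masks <- lapply(channelNames(den), function(ch) otsuBinarize(den, ch))
  masks <- lapply(masks, removeBaseSlices, n = 4)
  total <- mergeBinary(masks)
  eps <- mergeBinary(masks[2:3])
  expect_equal(m@biovolume_um3, biovolume(total))
  expect_equal(m@mbh_um, maxBiofilmHeight(total))
  expect_equal(m@max_area_um2, maxArea(total)$max_area_um2)
  expect_equal(m@eps_biovolume_um3, biovolume(eps))
  expect_equal(m@n_slices_analyzed, nSlices(total))
})

test_that("blank control stacks quantify to zero biomass", {
  blank <- simulateZStack(stackScenario(clusters = list(),
                                        background_mean = 12,
                                        background_sd = 4, seed = 9))
  m <- quantifyStack(blank$stack)
  # background noise is symmetric speckle; after denoising and base-slice
  # removal essentially nothing survives thresholding as structure
  expect_equal(m@mbh_um, 0)
  expect_equal(m@biovolume_um3, 0)
  expect_true(is.na(m@eps_fraction))
})

test_that("noise-free pipeline metrics equal generator voxel truth exactly", {
  sim <- simulateZStack(cleanStackScenario(seed = 6))
  tr <- sim$truth
  m <- quantifyStack(sim$stack, kernel = 1, base_slices = 4)
  keep <- 5:length(tr$per_slice_counts) # slices surviving base removal
  pa <- pixelUm(sim$stack)^2
  expect_equal(m@biovolume_um3, sum(tr$per_slice_counts[keep]) * pa)
  expect_equal(m@mbh_um, sum(tr$per_slice_counts[keep] > 0))
  expect_equal(m@max_area_um2, max(tr$per_slice_counts[keep]) * pa)
  expect_equal(m@eps_biovolume_um3, sum(tr$per_slice_eps_counts[keep]) * pa)
})

test_that("EPS fraction recovers the generator's assignment", {
  sim <- simulateZStack(cleanStackScenario(seed = 12))
  m <- quantifyStack(sim$stack, kernel = 1)
  expect_lt(abs(m@eps_fraction - 0.92), 0.02)
})

test_that("base-slice artifact does not change the metrics", {
  scn_clean <- cleanStackScenario(seed = 8)
  scn_art <- cleanStackScenario(seed = 8, base_artifact = TRUE)
  m1 <- quantifyStack(simulateZStack(scn_clean)$stack, kernel = 1)
  m2 <- quantifyStack(simulateZStack(scn_art)$stack, kernel = 1)
  expect_equal(as.data.frame(m1), as.data.frame(m2))

  # artifact alone, no clusters: everything removed with the base slices
  blank_art <- simulateZStack(stackScenario(clusters = list(),
                                            base_artifact = TRUE, seed = 8))
  m3 <- quantifyStack(blank_art$stack, kernel = 1)
  expect_equal(m3@biovolume_um3, 0)
  expect_equal(m3@mbh_um, 0)
})

test_that("metrics ignore the order of channels in the merge", {
  sim <- simulateZStack(cleanStackScenario(seed = 13))
  den <- medianDenoise(sim$stack, 1)
  masks <- lapply(channelNames(den), function(ch) otsuBinarize(den, ch))
  masks <- lapply(masks, removeBaseSlices, n = 4)
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    expect_equal(biovolume(mergeBinary(masks[perm])),
                 biovolume(mergeBinary(masks)))
  }
})

test_that("adding detected voxels never decreases a metric", {
  set.seed(31)
  base <- array(runif(8 * 12 * 12) < 0.1, c(8, 12, 12))
  grown <- base
  grown[sample(which(!grown), 40)] <- TRUE
  b1 <- mkMask(base)
  b2 <- mkMask(grown)
  expect_gte(biovolume(b2), biovolume(b1))
  expect_gte(maxBiofilmHeight(b2), maxBiofilmHeight(b1))
  expect_gte(maxArea(b2)$max_area_um2, maxArea(b1)$max_area_um2)
  # biovolume bounded by the imaged volume
  expect_lte(biovolume(b2), 8 * 12 * 12)
})
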