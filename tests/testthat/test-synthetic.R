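test_that("same seed reproduces the simulated series bit for bit", {
  scn <- seriesScenario(seed = 33)
  a <- simulateReactorSeries(scn)
  b <- simulateReactorSeries(scn)
  expect_identical(a, b)
  c <- simulateReactorSeries(seriesScenario(seed = 34))
  expect_false(identical(a$bulk, c$bulk))
})

test_that("analytic steady state: constant series and exact ISS recovery", {
  n0 <- 5e7
  scn <- seriesScenario(ngtr_profile = n0, biofilm_accum_profile = 0,
                        noise_gcv = 0, seed = 1)
  sim <- simulateReactorSeries(scn)
  ar <- sim$bulk[sim$bulk$source == "AR1", ]
  expect_lt(diff(range(ar$icc_cells_ml)) / mean(ar$icc_cells_ml), 1e-12)
  est <- ngtrInstantaneous(1e3, ar$icc_cells_ml[5], ReactorConfig())
  expect_equal(est$ngtr_cells_day, n0, tolerance = 1e-9)
})

test_that("simulation conserves cell number at every step", {
  step <- function(day) ifelse(day < 20, 5e7, 5e8)
  scn <- seriesScenario(ngtr_profile = step, biofilm_accum_profile = 2e6,
                        noise_gcv = 0, seed = 3)
  sim <- simulateReactorSeries(scn)
  tr <- sim$truth
  v <- volumeMl(scn$config)
  q <- flowMlMin(scn$config) * 1440
  n_tot <- tr$c_ar * v + tr$n_bf
  dt <- diff(tr$time)
  dN <- diff(n_tot) / dt
  # midpoint source terms on the fine grid
  mid <- head(tr$time, -1) + dt / 2
  src <- q * (scn$tap_profile(mid) - (head(tr$c_ar, -1) + tail(tr$c_ar, -1)) / 2) +
    scn$ngtr_profile(mid)
  rel <- abs(dN - src) / max(abs(src))
  # discard the two steps straddling the NGTR discontinuity; the central
  # difference used by this check is itself second-order in dt, which sets
  # the attainable tolerance
  rel <- rel[abs(mid - 20) > dt[1]]
  expect_lt(max(rel), 1e-4)
})

test_that("NSS recovers a noise-free constant NGTR within 1% and improves with sampling", {
  errAt <- function(interval) {
    scn <- seriesScenario(
      ngtr_profile = 4e7, biofilm_accum_profile = 3e6,
      noise_gcv = 0, sample_interval_days = interval,
      duration_days = 10, biofilm_sample_days = c(0, 10),
      c0 = 5e3, # start away from steady state so the window means matter
      seed = 2
    )
    sim <- simulateReactorSeries(scn)
    est <- ngtrNonsteady(sim$bulk, sim$biofilm[1, ], sim$biofilm[2, ],
                         scn$config, tol_days = 0.5)
    abs(est$ngtr_cells_day - 4e7) / 4e7
  }
  e_fine <- errAt(0.01)
  expect_lt(e_fine, 0.01)
  e_coarse <- errAt(1)
  expect_lt(e_fine, e_coarse) # denser sampling reduces the window-mean error
})

test_that("NSS tracks each segment of a stepped NGTR within 1%", {
  step <- function(day) ifelse(day < 20, 5e7, 5e8)
  scn <- seriesScenario(
    ngtr_profile = step, biofilm_accum_profile = 1e6,
    noise_gcv = 0, sample_interval_days = 0.01,
    biofilm_sample_days = c(0, 20, 40), seed = 2
  )
  sim <- simulateReactorSeries(scn)
  cfg <- scn$config
  for (seg in list(c(1, 2, 5e7), c(2, 3, 5e8))) {
    est <- ngtrNonsteady(sim$bulk, sim$biofilm[seg[1], ], sim$biofilm[seg[2], ],
                         cfg, tol_days = 0.5)
    truth <- truthWindowMean(sim$truth, est$t1, est$t2, "ngtr")
    # grid mean touches the step boundary point, so only near-equality
    expect_equal(truth, seg[3], tolerance = 1e-3)
    expect_lt(abs(est$ngtr_cells_day - seg[3]) / seg[3], 0.01)
  }
})

test_that("a decay scenario with negative NGTR stays feasible and is recovered", {
  scn <- seriesScenario(
    ngtr_profile = -2e6, biofilm_accum_profile = 0, noise_gcv = 0,
    sample_interval_days = 0.01, duration_days = 10,
    biofilm_sample_days = c(0, 10), seed = 4
  )
  sim <- simulateReactorSeries(scn)
  ar <- sim$bulk[sim$bulk$source == "AR1", ]
  expect_true(all(ar$icc_cells_ml > 0))
  est <- ngtrNonsteady(sim$bulk, sim$biofilm[1, ], sim$biofilm[2, ],
                       scn$config, tol_days = 0.5)
  expect_lt(abs(est$ngtr_cells_day - (-2e6)) / 2e6, 0.01)
  expect_true(is.na(est$ratio_tap_ngtr)) # undefined during net decay
})

test_that("ISS equals NSS at true steady state", {
  scn <- seriesScenario(ngtr_profile = 5e7, biofilm_accum_profile = 0,
                        noise_gcv = 0, biofilm_sample_days = c(0, 10), seed = 1)
  sim <- simulateReactorSeries(scn)
  nss <- ngtrNonsteady(sim$bulk, sim$biofilm[1, ], sim$biofilm[2, ],
                       scn$config, tol_days = 0.5)
  ar <- sim$bulk[sim$bulk$source == "AR1", ]
  iss <- ngtrInstantaneous(1e3, ar$icc_cells_ml[3], scn$config)
  expect_equal(nss$accumulation_cells_day, 0, tolerance = 1e-3)
  expect_equal(nss$ngtr_cells_day, iss$ngtr_cells_day, tolerance = 1e-9 * 5e7)
})

test_that("lognormal noise recovers truth geometrically at the stated rate", {
  g <- 0.3
  n <- 100
  scn <- seriesScenario(ngtr_profile = 5e7, biofilm_accum_profile = 0,
                        noise_gcv = g, duration_days = n - 1,
                        sample_interval_days = 1, seed = 10)
  sim <- simulateReactorSeries(scn)
  ar <- sim$bulk[sim$bulk$source == "AR1", ]
  truth <- sim$truth$c_ar_sampled[1] # constant at steady state
  gs <- geometricSummary(ar$icc_cells_ml)
  expect_lt(abs(gs$geomean - truth) / truth, 3 * g / sqrt(n))
  # and the gCV estimate sits near the generating noise level
  expect_lt(abs(gs$gcv - g), 0.12)
})

test_that("stack generator truth equals an independent voxel recount", {
  center <- c(25, 25)
  r <- 20
  scn <- cleanStackScenario(
    frame_px = 60, n_slices = 24, pixel_um = 1, slice_um = 1,
    clusters = list(list(center_um = center, radius_um = r)),
    eps_voxel_fraction = 0
  )
  sim <- simulateZStack(scn)
  oracle <- hemisphereVoxelOracle(center, r, 24, 60, 60, 1, 1)
  expect_equal(sim$truth$voxel_count, oracle$count)
  expect_equal(sim$truth$per_slice_counts, oracle$per_slice)
  expect_equal(sim$truth$mbh_um, 20)
  expect_equal(sim$truth$biovolume_um3, oracle$count) # 1 um3 voxels
  # the stack's bright voxels are exactly the truth mask
  syto <- intensityArray(sim$stack)[1, , , ]
  expect_equal(syto > 0, sim$truth$mask)
})

test_that("hollow shells leave the interior dark", {
  scn <- cleanStackScenario(
    frame_px = 60, n_slices = 24, pixel_um = 1, slice_um = 1,
    clusters = list(list(center_um = c(30, 30), radius_um = 15,
                         shape = "hollow-shell", shell_um = 3)),
    eps_voxel_fraction = 0
  )
  sim <- simulateZStack(scn)
  # center column near the substrate is inside the cavity
  expect_false(sim$truth$mask[2, 30, 30])
  full <- hemisphereVoxelOracle(c(30, 30), 15, 24, 60, 60, 1, 1)$count
  cavity <- hemisphereVoxelOracle(c(30, 30), 12, 24, 60, 60, 1, 1)$count
  expect_equal(sim$truth$voxel_count, full - cavity)
})

test_that("stack generation is seed-deterministic", {
  scn <- stackScenario(background_mean = 12, background_sd = 4,
                       base_artifact = TRUE, seed = 5)
  expect_identical(simulateZStack(scn), simulateZStack(scn))
})

test_that("fixture suite is complete and reproducible", {
  d1 <- file.path(tempdir(), "fix1")
  d2 <- file.path(tempdir(), "fix2")
  unlink(c(d1, d2), recursive = TRUE)
  makeFixtureSuite(d1, seed = 1)
  makeFixtureSuite(d2, seed = 1)
  f1 <- list.files(d1)
  expect_length(grep("^series_.*_bulk\\.csv$", f1), 3)
  expect_length(grep("^stack_.*\\.tif$", f1), 4)
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     info = f)
  }
  # the blank fixture quantifies to zero biomass
  blank <- readZStack(file.path(d1, "stack_blank.tif"), pixel_um = 0.5)
  m <- quantifyStack(blank)
  expect_equal(m@biovolume_um3, 0)
  expect_equal(m@mbh_um, 0)
})
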