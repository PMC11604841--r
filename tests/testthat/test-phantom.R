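test_that("true VDP equals brute-force voxel counting", {
  # no defects
  spec <- phantom_spec(grid_shape = c(32, 32, 32), seed = 1)
  truth <- build_phantom(spec)
  expect_identical(truth$true_vdp_percent, 0)
  expect_true(all(truth$vent_amplitude_map[truth$lung_mask] == 1))

  # one sphere, radius chosen by search to cover ~10% of the lung
  lung_n <- sum(truth$lung_mask)
  ctr <- c(23, 16, 18)
  r10 <- defect_radius_search(truth, ctr, 0.10)
  spec1 <- phantom_spec(grid_shape = c(32, 32, 32), seed = 1,
                        defects = list(list(center = ctr, radius_vox = r10,
                                            ventilation_scale = 0)))
  t1 <- build_phantom(spec1)
  g <- expand.grid(x = 1:32, y = 1:32, z = 1:32)
  sph <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2 <= r10^2
  expect_equal(t1$true_vdp_percent, 100 * sum(sph) / lung_n)
  expect_equal(t1$true_vdp_percent, 10, tolerance = 1)

  # two disjoint defects: VDP = 100 (n1 + n2) / N
  spec2 <- phantom_spec(grid_shape = c(32, 32, 32), seed = 1,
                        defects = list(
                          list(center = c(23, 16, 18), radius_vox = 3,
                               ventilation_scale = 0),
                          list(center = c(10, 16, 18), radius_vox = 2.5,
                               ventilation_scale = 0.5)))
  t2 <- build_phantom(spec2)
  n1 <- sum((g$x - 23)^2 + (g$y - 16)^2 + (g$z - 18)^2 <= 9)
  n2 <- sum((g$x - 10)^2 + (g$y - 16)^2 + (g$z - 18)^2 <= 6.25)
  expect_equal(t2$true_vdp_percent, 100 * (n1 + n2) / lung_n)
  # defect insertion conserves the lung mask
  expect_identical(t2$lung_mask, truth$lung_mask)
  expect_true(all(t2$defect_mask[t2$defect_mask] &
                    t2$lung_mask[t2$defect_mask]))
})

test_that("defects outside the lungs are rejected", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32),
                       defects = list(list(center = c(16, 16, 16),
                                           radius_vox = 4,
                                           ventilation_scale = 0)))
  expect_error(build_phantom(spec), "outside")
})

test_that("frame_at_phase implements the density model", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), seed = 2,
                       defects = list(list(center = c(23, 16, 18),
                                           radius_vox = 3,
                                           ventilation_scale = 0)))
  truth <- build_phantom(spec)
  f0 <- frame_at_phase(truth, spec, 0)
  f1 <- frame_at_phase(truth, spec, 1, warp = FALSE)
  # b = 0 equals the unwarped end-expiration reference
  expect_identical(f0, frame_at_phase(truth, spec, 0, warp = FALSE))
  # healthy lung voxel: rho (1 - alpha b); rho = 0.5, alpha = 0.3
  healthy <- truth$lung_mask & !truth$defect_mask
  expect_equal(unique(f0[healthy]), 0.5)
  expect_equal(unique(f1[healthy]), 0.5 * (1 - 0.3))
  # defect voxel (scale 0): identical at b = 0 and b = 1 before warping
  expect_identical(f0[truth$defect_mask], f1[truth$defect_mask])
  # scaled example: v = 1, rho = 1, alpha = 0.3, b = 1 -> 0.7
  spec2 <- spec
  spec2$lungs$parenchyma_intensity <- 1
  t2 <- build_phantom(spec2)
  expect_equal(unique(frame_at_phase(t2, spec2, 1, warp = FALSE)[
    t2$lung_mask & !t2$defect_mask]), 0.7)
})

test_that("acquisition DC behaves: static constant, drift recovered, b monotone", {
  st <- static_acq()
  dc <- Mod(st$acq$kdata[, 1, 1])
  # static noiseless phantom: k-centre magnitude constant across spokes
  expect_lt(diff(range(dc)) / mean(dc), 1e-9)

  # drift on a static phantom: k-centre reproduces g(t) up to scale
  spec <- st$spec
  spec$drift$amplitude <- 0.2
  acq <- simulate_acquisition(st$truth, spec, st$traj, 2000, TR_s = 0.0019)
  t <- acq$timestamp_s
  gt <- 1 + 0.2 * sin(2 * pi * t / spec$drift$period_s)
  dc <- Mod(acq$kdata[, 1, 1])
  expect_gt(suppressWarnings(summary(lm(dc ~ gt)))$r.squared, 0.99)

  # breathing on, noise off: the k-centre magnitude falls as b rises
  # (density drops on inspiration), so the correlation is strongly negative
  spec_b <- st$spec
  spec_b$breathing$amplitude <- 1
  acq_b <- simulate_acquisition(st$truth, spec_b, st$traj, 2000,
                                TR_s = 0.0095)
  dc0 <- Mod(acq_b$kdata[, 1, 1])
  expect_lt(cor(dc0, acq_b$truth$phase_of_spoke), -0.9)
})

test_that("simulation is deterministic given the seed", {
  spec <- phantom_spec(grid_shape = c(24, 24, 24), n_coils = 2, seed = 9)
  truth <- build_phantom(spec)
  traj <- radial_trajectory(500, 24)
  a1 <- simulate_acquisition(truth, spec, traj, 500, 0.002)
  a2 <- simulate_acquisition(truth, spec, traj, 500, 0.002)
  expect_identical(a1$kdata, a2$kdata)
})

test_that("xe volume: constant in lung, threshold oracle, bias correction", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), seed = 3)
  truth <- build_phantom(spec)
  xe <- simulate_xe_volume(truth, spec)
  # no defects, no bias/noise: constant inside the (slab-consistent) lung
  expect_lt(diff(range(xe$image[xe$mask & xe$image > 0])), 1e-9)

  # one dead defect covering ~10% of the lung -> threshold VDP ~~ 10
  ctr <- c(23, 16, 18)
  r10 <- defect_radius_search(truth, ctr, 0.10)
  spec1 <- phantom_spec(grid_shape = c(32, 32, 32), seed = 3,
                        defects = list(list(center = ctr, radius_vox = r10,
                                            ventilation_scale = 0)))
  t1 <- build_phantom(spec1)
  xe1 <- simulate_xe_volume(t1, spec1, slab_mm = spec1$voxel_size_mm * 2)
  res <- threshold_vdp(xe1$image, xe1$mask)
  expect_equal(res$vdp_percent, 10, tolerance = 2)

  # bias field raises in-lung CoV; polynomial correction reduces it
  xeb <- simulate_xe_volume(truth, spec, bias_amplitude = 0.5)
  healthy <- xeb$mask & truth$lung_mask
  cov_pre <- sd(xeb$image[healthy]) / mean(xeb$image[healthy])
  corr <- bias_correct(xeb$image, xeb$mask)
  cov_post <- sd(corr[healthy]) / mean(corr[healthy])
  expect_lt(cov_post, cov_pre)
  expect_equal(mean(corr[xeb$mask]), mean(xeb$image[xeb$mask]),
               tolerance = 1e-9)
  # slab thicker than the lung errors
  expect_error(simulate_xe_volume(truth, spec, slab_mm = 4 * 32),
               "slab")
})
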