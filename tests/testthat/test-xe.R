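test_that("threshold VDP: hand-counted oracle, boundaries, invariances", {
  vol <- array(110, c(10, 10, 1))
  vol[1:10] <- 10
  mask <- array(TRUE, c(10, 10, 1))
  # mean 100, threshold 60 -> the ten 10-valued voxels are defect
  expect_equal(threshold_vdp(vol, mask)$vdp_percent, 10.0)
  # scale invariance
  for (c in c(0.1, 1, 1000))
    expect_equal(threshold_vdp(vol * c, mask)$vdp_percent, 10.0)
  # uniform image: no voxel strictly below 60% of its own mean
  expect_equal(threshold_vdp(array(5, c(4, 4, 4)),
                             array(TRUE, c(4, 4, 4)))$vdp_percent, 0)
  # frac boundaries
  expect_equal(threshold_vdp(vol, mask, frac = 0)$vdp_percent, 0)
  expect_equal(threshold_vdp(vol, mask, frac = 2)$vdp_percent, 100)
  # voxels exactly at the threshold are healthy (strict <)
  v2 <- array(c(60, 100, 100, 140), c(4, 1, 1))  # mean 100, thr 60
  m2 <- array(TRUE, c(4, 1, 1))
  expect_equal(threshold_vdp(v2, m2, 0.6)$vdp_percent, 0)
  expect_equal(threshold_vdp(v2 - 0.5 * (v2 == 60), m2, 0.6)$vdp_percent, 25)
  # monotone in frac
  set.seed(12)
  v <- array(runif(1000, 0, 2), c(10, 10, 10))
  m <- array(TRUE, c(10, 10, 10))
  vdps <- vapply(seq(0, 1.5, by = 0.1), function(f)
    threshold_vdp(v, m, f)$vdp_percent, numeric(1))
  expect_true(all(diff(vdps) >= 0))
})

test_that("bias correction: identity on constants, kills a known bias", {
  dm <- c(16, 16, 16)
  mask <- array(FALSE, dm); mask[4:13, 4:13, 4:13] <- TRUE
  cst <- array(2.5, dm)
  out <- bias_correct(cst, mask)
  expect_equal(as.vector(out), as.vector(cst), tolerance = 1e-9)
  # constant x known quadratic bias: CoV reduced >= 10x, mean preserved
  g <- preful3d:::coord_grids(dm)
  u <- (g$x - 8.5) / 16; w <- (g$z - 8.5) / 16
  bias <- exp(0.8 * u - 0.5 * u^2 + 0.6 * u * w + 0.4 * w)
  vol <- cst * bias
  corr <- bias_correct(vol, mask)
  cov0 <- sd(vol[mask]) / mean(vol[mask])
  cov1 <- sd(corr[mask]) / mean(corr[mask])
  expect_gt(cov0 / cov1, 10)
  expect_equal(mean(corr[mask]), mean(vol[mask]), tolerance = 1e-9)
  # non-positive values: offset applied with a warning, mean still preserved
  vneg <- vol; vneg[5, 5, 5] <- -0.1
  expect_warning(cneg <- bias_correct(vneg, mask), "offset")
  expect_equal(mean(cneg[mask]), mean(vneg[mask]), tolerance = 1e-6)
})

test_that("rigid alignment: identity, shift recovery, MI contract", {
  dm <- c(24, 24, 24)
  g <- preful3d:::coord_grids(dm)
  vol <- array(exp(-((g$x - 12)^2 + (g$y - 12)^2 + (g$z - 12)^2) / 30) +
                 0.5 * exp(-((g$x - 16)^2 + (g$y - 9)^2 + (g$z - 14)^2) / 12),
               dm)
  r0 <- rigid_align(vol, vol)
  expect_lt(sqrt(sum(r0$params[4:6]^2)), 0.2)
  expect_gte(r0$mi, r0$mi_identity - 1e-9)
  # known 3-voxel shift recovered within 0.5 voxel
  mov <- array(warp_trilinear(as.vector(vol), dm, 0, 0, 3), dm)
  r3 <- rigid_align(mov, vol)
  expect_lt(abs(r3$params[6] - (-3)), 0.5)
  expect_lt(max(abs(r3$params[4:5])), 0.5)
  expect_gte(r3$mi, r3$mi_identity)
})
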