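make_series <- function(amps, fun, dm = c(8, 8, 8)) {
  data <- array(0, c(length(amps), dm))
  for (i in seq_along(amps)) data[i, , , ] <- fun(amps[i])
  structure(list(data = data, state_amplitude = amps, voxel_size_mm = 4),
            class = "image_series")
}

test_that("phase interpolation: linear exactness, constants, bias-variance", {
  amps <- c(0.05, 0.18, 0.33, 0.46, 0.61, 0.74, 0.88, 0.97)
  dm <- c(8, 8, 8)
  base <- array(runif(prod(dm), 1, 2), dm)
  slope <- array(runif(prod(dm), -1, 1), dm)
  ser <- make_series(amps, function(a) base + slope * a, dm)
  ph <- interpolate_phases(ser, n_out = 15)
  expect_equal(ph$phase_grid, seq(min(amps), max(amps), length.out = 15))
  for (k in c(1, 8, 15)) {
    expected <- base + slope * ph$phase_grid[k]
    expect_equal(ph$data[k, , , ], expected, tolerance = 1e-6)
  }
  # constant voxel stays constant
  serc <- make_series(amps, function(a) base, dm)
  phc <- interpolate_phases(serc, n_out = 5)
  for (k in 1:5) expect_equal(phc$data[k, , , ], base, tolerance = 1e-9)
  expect_error(interpolate_phases(ser, bandwidth = 0), "bandwidth")

  # bias-variance: residual to a sinusoidal truth dips at a middle bandwidth
  set.seed(9)
  amps2 <- seq(0, 1, length.out = 24)
  f <- function(a) sin(2 * pi * a)
  noise <- rnorm(24, sd = 0.15)
  sig <- f(amps2) + noise
  ser1 <- structure(list(data = array(sig, c(24, 1, 1, 1)),
                         state_amplitude = amps2, voxel_size_mm = 1),
                    class = "image_series")
  res <- vapply(c(0.02, 0.08, 0.5), function(bw) {
    p <- interpolate_phases(ser1, n_out = 24, bandwidth = bw)
    sqrt(mean((p$data[, 1, 1, 1] - f(p$phase_grid))^2))
  }, numeric(1))
  expect_lt(res[2], res[1])
  expect_lt(res[2], res[3])
})

test_that("RVent follows the convention arithmetic", {
  dm <- c(4, 4, 4)
  ph <- structure(list(
    data = array(c(rep(1.0, prod(dm)), rep(0.85, prod(dm)),
                   rep(0.7, prod(dm))), c(3, dm))), class = "phase_series")
  # order phases so data[1] is brightest: already; mask everything
  ph$data <- aperm(array(c(array(1, dm), array(0.85, dm), array(0.7, dm)),
                         c(dm, 3)), c(4, 1, 2, 3))
  mask <- array(TRUE, dm)
  rv <- compute_rvent(ph, mask)
  expect_equal(unique(as.vector(rv$map)), 0.30, tolerance = 1e-12)
  rv2 <- compute_rvent(ph, mask, convention = "insp-denominator")
  expect_equal(unique(as.vector(rv2$map)), 0.3 / 0.7, tolerance = 1e-12)
  # S_ex = S_in -> 0
  ph$data[] <- 1
  expect_true(all(compute_rvent(ph, mask)$map == 0))
  # non-positive S_ex flagged invalid and excluded
  ph$data[] <- 1; ph$data[1, 1, 1, 1] <- 0; ph$data[3, 1, 1, 1] <- -1
  ph$data[1, , , 2:4] <- 2   # make phase 1 the expiration end
  rv3 <- compute_rvent(ph, mask)
  expect_equal(rv3$n_invalid, 1)
  expect_true(is.na(rv3$map[1, 1, 1]))
})

test_that("k-means VDP matches oracles and is invariant/deterministic", {
  dm <- c(10, 10, 1)
  rv <- array(0.30, dm)
  rv[1:10] <- 0
  mask <- array(TRUE, dm)
  res <- vdp_kmeans(rv, mask, k = 2, mode = "3D")
  expect_equal(res$vdp_percent, 10.0)
  expect_equal(res$cluster_means, c(0, 0.30), tolerance = 1e-12)

  # all-equal input is degenerate
  expect_error(vdp_kmeans(array(1, dm), mask, k = 2), "distinct")

  # brute-force contiguous-partition oracle on small random sets
  set.seed(10)
  for (rep in 1:5) {
    v <- round(runif(12), 3)
    arr <- array(c(v, rep(9, 13)), c(25, 1, 1))
    m <- array(c(rep(TRUE, 12), rep(FALSE, 13)), c(25, 1, 1))
    km <- vdp_kmeans(arr, m, k = 3, mode = "3D")
    orc <- kmeans_oracle_1d(v, 3)
    n_low <- sum(orc$cluster == 1)
    expect_equal(km$vdp_percent, 100 * n_low / 12, tolerance = 1e-9)
    expect_equal(km$cluster_means, orc$centers, tolerance = 1e-9)
  }

  # adding voxels outside the mask changes nothing
  rv_big <- array(c(rv, runif(100)), c(10, 10, 2))
  mask_big <- array(c(mask, array(FALSE, dm)), c(10, 10, 2))
  res2 <- vdp_kmeans(rv_big, mask_big, k = 2, mode = "3D")
  expect_equal(res2$vdp_percent, res$vdp_percent)

  # determinism and 4-component mixture recovery
  set.seed(11)
  comp <- sample(1:4, 4000, replace = TRUE, prob = c(0.1, 0.3, 0.3, 0.3))
  mus <- c(0.02, 0.18, 0.30, 0.42)
  v4 <- array(rnorm(4000, mus[comp], 0.015), c(40, 10, 10))
  m4 <- array(TRUE, c(40, 10, 10))
  r1 <- vdp_kmeans(v4, m4, k = 4, mode = "3D")
  r2 <- vdp_kmeans(v4, m4, k = 4, mode = "3D")
  expect_identical(r1$defect_mask, r2$defect_mask)
  expect_equal(r1$cluster_means, mus, tolerance = 0.02)
  expect_equal(r1$vdp_percent, 100 * mean(comp == 1), tolerance = 2)
  # pooled 2D mode equals 3D on the same volume
  expect_equal(vdp_kmeans(v4, m4, k = 4, mode = "2D")$vdp_percent,
               r1$vdp_percent)
})
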