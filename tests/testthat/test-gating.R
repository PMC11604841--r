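test_that("extract_dc averages the first readout magnitudes", {
  # synthetic acquisition with hand-set first-five magnitudes (3,4,5,4,4)
  kd <- array(0i, dim = c(2, 8, 1))
  kd[1, 1:5, 1] <- c(3, 4, 5, 4, 4)
  kd[2, 1:5, 1] <- c(1, 1, 1, 1, 1) * 2i
  acq <- structure(list(kdata = kd, meta = list(TR_s = 0.002)),
                   class = "radial_acquisition")
  dc <- extract_dc(acq, n_points = 5, coil = 1)
  expect_equal(dc$raw, c(4, 2))
  expect_error(extract_dc(acq, coil = 3), "out of range")

  # static noiseless phantom: the k-centre sample is exactly constant and
  # the 5-point navigator (which reaches slightly off-centre samples on the
  # ramp) is constant to within a few percent
  st <- static_acq()
  dc0 <- Mod(st$acq$kdata[, 1, 1])
  expect_lt(diff(range(dc0)) / mean(dc0), 1e-9)
  raw <- extract_dc(st$acq, coil = 1)$raw
  expect_lt(diff(range(raw)) / mean(raw), 0.15)
})

test_that("Savitzky-Golay smoothing reproduces polynomials and the LS kernel", {
  # degree <= polyorder polynomial passes through unchanged
  x <- seq_len(101)
  y <- 2 + 0.3 * x - 0.01 * x^2
  sm <- smooth_waveform(y, window = 11, polyorder = 3)
  expect_equal(sm, y, tolerance = 1e-8)

  # impulse response equals the directly solved least-squares kernel
  n <- 51; w <- 9; p <- 2
  imp <- numeric(n); imp[26] <- 1
  sm <- smooth_waveform(imp, window = w, polyorder = p)
  h <- (w - 1) / 2
  A <- outer(-h:h, 0:p, "^")
  kern <- (A %*% solve(crossprod(A), t(A)))[h + 1, ]
  expect_equal(sm[26 + (-h:h)], rev(kern), tolerance = 1e-10)

  # white noise variance shrinks
  set.seed(5)
  z <- rnorm(2000)
  expect_lt(var(smooth_waveform(z, 21, 2)), var(z))
  expect_error(smooth_waveform(z[1:10], window = 21))
})

test_that("block rescaling follows the min-max contract", {
  expect_equal(rescale_blocks(c(2, 6, 4), block_size = 3), c(0, 1, 0.5))
  expect_equal(rescale_blocks(rep(3, 7), block_size = 4), rep(0.5, 7))
  # drifting sinusoid: each full block spans exactly [0, 1]
  t <- seq(0, 60, by = 0.02)
  sig <- sin(2 * pi * t / 4) + 0.05 * t
  nm <- rescale_blocks(sig, block_size = 500)
  for (s in seq(1, length(sig) - 499, by = 500)) {
    expect_equal(range(nm[s:(s + 499)]), c(0, 1))
  }
  expect_true(all(nm >= 0 & nm <= 1))
})

test_that("phase binning: counts, weights and ordering", {
  set.seed(6)
  amp <- runif(300)
  b <- bin_phases(amp, n_states = 30, shared_fraction = 0)
  counts <- vapply(b$membership, nrow, 1L)
  expect_true(all(counts == 10))
  expect_equal(sort(unlist(lapply(b$membership, `[[`, "spoke"))), 1:300)
  expect_true(all(diff(b$state_amplitude) > 0))

  b3 <- bin_phases(amp, n_states = 30, shared_fraction = 0.3)
  counts <- vapply(b3$membership, nrow, 1L)
  # 10 core + 3 from each neighbour; end states have one neighbour
  expect_equal(counts[1], 13L)
  expect_equal(counts[30], 13L)
  expect_true(all(counts[2:29] == 16L))
  # shared weights decay with distance from the bin edge; core weights 1
  m <- b3$membership[[15]]
  expect_true(all(m$weight[1:10] == 1))
  shared <- m$weight[11:16]
  expect_true(all(shared <= 1 & shared > 0))
  # weight = exp(0) = 1 at the bin edge: nearest shared spoke has the
  # largest weight of its donor group
  expect_equal(max(m$weight[11:13]), m$weight[11])
  # no spoke in more than 3 states
  memb <- table(unlist(lapply(b3$membership, `[[`, "spoke")))
  expect_lte(max(memb), 3)
  expect_error(bin_phases(runif(10), n_states = 30), "fewer spokes")
})

test_that("self-gating recovers the breathing phase on the phantom", {
  sm <- small_acq()
  g <- self_gate(sm$acq, n_states = 8)
  b <- sm$acq$truth$phase_of_spoke
  expect_gt(abs(cor(g$waveform$normalized, b)), 0.9)
  # state index vs true amplitude quantile: strong rank agreement
  st <- integer(length(b))
  for (j in seq_along(g$binning$membership)) {
    m <- g$binning$membership[[j]]
    st[m$spoke[m$weight == 1]] <- j
  }
  expect_gt(abs(cor(st, rank(b))), 0.95)
})
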