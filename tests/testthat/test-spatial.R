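make_blob <- function(dm = c(32, 32, 32)) {
  g <- preful3d:::coord_grids(dm)
  array(exp(-((g$x - 16)^2 + (g$y - 16)^2 + (g$z - 16)^2) / 60) +
          0.3 * exp(-((g$x - 10)^2 + (g$y - 20)^2 + (g$z - 12)^2) / 30), dm)
}

test_that("registration: identity, known shift recovery, SD reduction", {
  dm <- c(32, 32, 32)
  blob <- make_blob(dm)
  # all states identical -> fields ~ 0
  ser <- structure(list(data = array(rep(blob, 3), c(3, dm)),
                        state_amplitude = c(0.1, 0.5, 0.9),
                        voxel_size_mm = 4), class = "image_series")
  ser$data <- aperm(array(blob, c(dm, 3)), c(4, 1, 2, 3))
  r <- register_to_mid(ser)
  expect_lt(max(abs(unlist(r$fields))), 0.1)
  expect_equal(r$mid_state, 2L)

  # known 2-voxel superior shift recovered within 0.5 voxel in the core
  shifted <- array(warp_trilinear(as.vector(blob), dm, 0, 0, 2), dm)
  ser$data[1, , , ] <- shifted
  r <- register_to_mid(ser, iters = 40)
  core <- blob > 0.3
  expect_lt(abs(mean(r$fields[[1]]$uz[core]) - (-2)), 0.5)
  # SSD never increased (fallback contract)
  expect_false(any(r$fallback))
  # temporal SD of registered series <= unregistered (median over core)
  pre <- matrix(ser$data, nrow = 3)[, as.vector(core)]
  post <- matrix(r$registered$data, nrow = 3)[, as.vector(core)]
  sd_pre <- apply(pre, 2, sd)
  sd_post <- apply(post, 2, sd)
  expect_lte(median(sd_post), median(sd_pre))
})

test_that("region growing segments the phantom lungs and rejects leaks", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), seed = 2)
  truth <- build_phantom(spec)
  vol <- frame_at_phase(truth, spec, 0.4, warp = FALSE)
  seeds <- rbind(round(spec$lungs$left$center),
                 round(spec$lungs$right$center))
  m <- segment_thoracic_cavity(vol, seeds, tolerance = 0.15)
  expect_gte(dice(array(as.logical(m), dim(m)), truth$lung_mask), 0.90)
  # deterministic
  m2 <- segment_thoracic_cavity(vol, seeds, tolerance = 0.15)
  expect_identical(as.logical(m), as.logical(m2))
  # seed in the background air floods the border region -> leak rejection
  expect_error(segment_thoracic_cavity(vol, rbind(c(2, 2, 2)),
                                       tolerance = 0.15), "leak")
  # monotone in tolerance
  m_lo <- segment_thoracic_cavity(vol, seeds, tolerance = 0.05)
  m_hi <- segment_thoracic_cavity(vol, seeds, tolerance = 0.15)
  expect_true(all(!m_lo | m_hi))
  # auto seeds land inside the lungs
  sds <- preful3d:::auto_seeds(vol)
  for (i in seq_len(nrow(sds)))
    expect_true(truth$lung_mask[sds[i, 1], sds[i, 2], sds[i, 3]])
})

test_that("guided filter: identity, mean limit, edge preservation", {
  dm <- c(24, 24, 24)
  cst <- array(3.7, dm)
  expect_equal(guided_filter3d(cst, cst, radius = 2, eps = 1e-3), cst,
               tolerance = 1e-9)
  # eps -> Inf: a -> 0, b -> local mean, so the closed-form limit is the
  # box mean of the box mean
  set.seed(8)
  img <- array(rnorm(prod(dm)), dm)
  out <- guided_filter3d(img, img, radius = 2, eps = 1e12)
  expect_equal(out, preful3d:::box_mean3(preful3d:::box_mean3(img, 2), 2),
               tolerance = 1e-6)
  # step edge + noise: edge gradient kept >= 0.8x, flat variance cut >= 4x
  step <- array(0, dm)
  step[13:24, , ] <- 1
  noisy <- step + array(rnorm(prod(dm), sd = 0.05), dm)
  filt <- guided_filter3d(noisy, noisy, radius = 2, eps = 0.01)
  grad_pre <- mean(noisy[13, , ] - noisy[12, , ])
  grad_post <- mean(filt[13, , ] - filt[12, , ])
  expect_gte(grad_post / grad_pre, 0.8)
  flat <- array(FALSE, dm); flat[4:9, 4:21, 4:21] <- TRUE
  expect_gte(var(noisy[flat] - step[flat]) /
               var(filt[flat] - step[flat]), 4)
})
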