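#' Ventilating digital thorax phantom
#'
#' A 3D digital thorax used as ground truth for the whole pipeline: an
#' ellipsoidal body containing two ellipsoidal lungs whose parenchymal
#' signal density oscillates with respiration (proton density falls as the
#' lung inflates), optionally carrying spherical ventilation defects where
#' the oscillation is scaled down or absent.  Axis convention, used
#' package-wide: axis 1 x (right to left), axis 2 y (anterior to
#' posterior), axis 3 z (inferior to superior).
#'
#' @param grid_shape integer(3), all entries >= 16.
#' @param voxel_size_mm isotropic voxel size.
#' @param body list with `center` (voxel, 1-based), `semi_axes` (voxels),
#'   `intensity`.
#' @param lungs list of two lists with `center`, `semi_axes`; plus
#'   `parenchyma_intensity`.
#' @param defects list of defects, each `list(center=, radius_vox=,
#'   ventilation_scale=)` with scale in `[0,1]` (1 normal, 0 none).
#' @param breathing list: `period_s`, `inspiration_fraction` (raised-cosine
#'   asymmetric cycle), `diaphragm_shift_vox` (max superior-inferior
#'   displacement), `alpha` (tidal fractional density change, default 0.3).
#' @param drift multiplicative slow receiver-gain model:
#'   `list(amplitude=, period_s=)`.
#' @param noise_sigma complex-noise SD relative to the peak object
#'   intensity, on the image-equivalent scale (see vignette).
#' @param n_coils number of receive coils (>= 1).
#' @param seed integer RNG seed.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), voxel_size_mm = 4,
                         body = NULL, lungs = NULL, defects = list(),
                         breathing = list(), drift = list(),
                         noise_sigma = 0.05, n_coils = 4, seed = 1) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 16), n_coils >= 1,
            noise_sigma >= 0)
  g <- as.integer(grid_shape)
  c0 <- (g + 1) / 2
  if (is.null(body))
    body <- list(center = c0, semi_axes = 0.45 * g, intensity = 1.0)
  if (is.null(lungs))
    lungs <- list(
      left = list(center = c0 + c(0.22, 0, 0.05) * g,
                  semi_axes = c(0.16, 0.28, 0.30) * g),
      right = list(center = c0 + c(-0.22, 0, 0.05) * g,
                   semi_axes = c(0.16, 0.28, 0.30) * g),
      parenchyma_intensity = 0.5)
  br <- utils::modifyList(list(period_s = 4, inspiration_fraction = 0.4,
                               diaphragm_shift_vox = 0.05 * g[3],
                               alpha = 0.3, amplitude = 1), breathing)
  dr <- utils::modifyList(list(amplitude = 0.2, period_s = 600), drift)
  for (d in defects)
    stopifnot(!is.null(d$center), !is.null(d$radius_vox),
              d$ventilation_scale >= 0, d$ventilation_scale <= 1)
  structure(list(grid_shape = g, voxel_size_mm = voxel_size_mm, body = body,
                 lungs = lungs, defects = defects, breathing = br,
                 drift = dr, noise_sigma = noise_sigma,
                 n_coils = as.integer(n_coils), seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipsoid_mask <- function(dm, center, semi) {
  g <- coord_grids(dm)
  ((g$x - center[1]) / semi[1])^2 + ((g$y - center[2]) / semi[2])^2 +
    ((g$z - center[3]) / semi[3])^2 <= 1
}

#' Build the phantom ground truth
#'
#' Ventilation amplitude is 1 inside the lungs, multiplied by each defect's
#' `ventilation_scale` within its sphere, 0 outside the lungs.  A defect
#' whose sphere leaves the lungs is rejected.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_truth`: `vent_amplitude_map`, `lung_mask`,
#'   `defect_mask`, `true_vdp_percent` (and `phase_of_spoke` once an
#'   acquisition has been simulated).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  body <- ellipsoid_mask(dm, spec$body$center, spec$body$semi_axes)
  lung <- ellipsoid_mask(dm, spec$lungs$left$center, spec$lungs$left$semi_axes) |
    ellipsoid_mask(dm, spec$lungs$right$center, spec$lungs$right$semi_axes)
  lung <- lung & body
  vent <- array(0, dm)
  vent[lung] <- 1
  defect <- array(FALSE, dm)
  g <- coord_grids(dm)
  for (d in spec$defects) {
    sph <- (g$x - d$center[1])^2 + (g$y - d$center[2])^2 +
      (g$z - d$center[3])^2 <= d$radius_vox^2
    if (any(sph & !lung))
      stop("defect at (", paste(d$center, collapse = ","),
           ") extends outside the lungs")
    vent[sph] <- vent[sph] * d$ventilation_scale
    defect <- defect | sph
  }
  structure(list(vent_amplitude_map = vent, lung_mask = lung,
                 defect_mask = defect, body_mask = body,
                 true_vdp_percent = 100 * sum(defect) / sum(lung),
                 phase_of_spoke = NULL),
            class = "phantom_truth")
}

#' Breathing amplitude model
#'
#' Raised-cosine respiratory cycle, asymmetric between inspiration and
#' expiration: `b` rises 0 to 1 over `inspiration_fraction` of the period
#' and falls back over the remainder.  `b = 0` is end-expiration (maximum
#' parenchymal density), `b = 1` end-inspiration.
#'
#' @param t time(s) in seconds.
#' @param breathing the breathing sub-list of a [phantom_spec()].
#' @return amplitudes in `[0, 1]`.
#' @export
breathing_amplitude <- function(t, breathing) {
  T <- breathing$period_s
  fi <- breathing$inspiration_fraction
  tau <- t %% T
  ifelse(tau < fi * T,
         0.5 * (1 - cos(pi * tau / (fi * T))),
         0.5 * (1 + cos(pi * (tau - fi * T) / ((1 - fi) * T))))
}

#' Render the phantom at a respiratory amplitude
#'
#' Parenchymal intensity is `rho * (1 - alpha * v(x) * b)` (density drops
#' on inflation where ventilation `v` is preserved), composited over the
#' body background; the frame is then warped by a smooth superior-inferior
#' displacement field scaled by `b * diaphragm_shift_vox`.  `b = 0` returns
#' the unwarped end-expiration reference exactly.
#'
#' @param truth from [build_phantom()].
#' @param spec the matching [phantom_spec()].
#' @param b respiratory amplitude in `[0, 1]`.
#' @param warp apply the diaphragm displacement (default TRUE).
#' @return 3D real image.
#' @export
frame_at_phase <- function(truth, spec, b, warp = TRUE) {
  stopifnot(b >= 0, b <= 1)
  dm <- spec$grid_shape
  img <- array(0, dm)
  img[truth$body_mask] <- spec$body$intensity
  rho <- spec$lungs$parenchyma_intensity
  a <- spec$breathing$alpha
  v <- truth$vent_amplitude_map
  img[truth$lung_mask] <- rho * (1 - a * v[truth$lung_mask] * b)
  if (!warp || b == 0 || spec$breathing$diaphragm_shift_vox == 0)
    return(img)
  uz <- diaphragm_field(dm) * (b * spec$breathing$diaphragm_shift_vox)
  array(warp_trilinear(as.vector(img), dm, 0, 0, as.vector(uz)), dm)
}

# Smooth SI displacement profile: maximal at the lung base, decaying to 0
# at the apex and below the diaphragm (raised-cosine in z).
diaphragm_field <- function(dm) {
  z <- seq_len(dm[3])
  z0 <- 0.35 * dm[3]           # diaphragm dome
  w <- 0.35 * dm[3]
  prof <- ifelse(abs(z - z0) < w, 0.5 * (1 + cos(pi * (z - z0) / w)), 0)
  array(rep(prof, each = dm[1] * dm[2]), dm)
}

#' Simulate the radial UTE acquisition of a breathing phantom
#'
#' Spoke `n` is acquired at `t = (n-1) * TR_s`; its samples are the
#' non-uniform Fourier transform of the phantom frame at `b(t)` weighted by
#' each coil map, multiplied by the slow receiver-gain drift `g(t) = 1 +
#' A sin(2 pi t / T_d)`, plus complex Gaussian noise.  To keep simulation
#' tractable, `b(t)` is quantized to `n_levels` frames (forward-model
#' approximation, documented in the vignette); `phase_of_spoke` records the
#' unquantized truth.
#'
#' @param truth,spec phantom truth and spec.
#' @param traj a [radial_trajectory()] with at least `n_spokes` directions.
#' @param n_spokes number of spokes to simulate.
#' @param TR_s repetition time (spoke spacing) in seconds.
#' @param n_levels quantization levels for the breathing amplitude.
#' @return a `radial_acquisition`: `kdata [n_spokes x n_readout x n_coils]`,
#'   `traj`, `timestamp_s`, `coil_maps [X Y Z x n_coils]`, `meta`; the input
#'   `truth` is returned with `phase_of_spoke` filled in as attribute
#'   `truth`.
#' @export
simulate_acquisition <- function(truth, spec, traj, n_spokes = 20000,
                                 TR_s = 0.0019, n_levels = 64) {
  stopifnot(inherits(traj, "radial_trajectory"),
            traj$n_spokes >= n_spokes, n_spokes > 0)
  dm <- spec$grid_shape
  t <- (seq_len(n_spokes) - 1) * TR_s
  b <- breathing_amplitude(t, spec$breathing) * spec$breathing$amplitude
  bq <- round(b * (n_levels - 1)) / (n_levels - 1)
  maps <- coil_maps(dm, spec$n_coils, spec$seed)
  plan <- nufft_plan(dm)
  nr <- traj$n_readout
  kdata <- array(0i, dim = c(n_spokes, nr, spec$n_coils))
  for (lev in sort(unique(bq))) {
    sp <- which(bq == lev)
    img <- frame_at_phase(truth, spec, lev)
    co <- traj_coords(traj, sp)            # readout fastest
    for (c in seq_len(spec$n_coils)) {
      y <- nufft_forward(plan, img * maps[, , , c], co)
      kdata[sp, , c] <- t(matrix(y, nrow = nr))
    }
  }
  g <- 1 + spec$drift$amplitude * sin(2 * pi * t / spec$drift$period_s)
  kdata <- kdata * array(rep(g, nr * spec$n_coils), dim(kdata))
  if (spec$noise_sigma > 0) {
    # image-equivalent noise scale: sigma_k = noise_sigma * peak * sqrt(Nvox)
    peak <- max(spec$body$intensity, spec$lungs$parenchyma_intensity)
    sig <- spec$noise_sigma * peak * sqrt(prod(dm))
    nse <- with_seed(stage_seed(spec$seed, "acquisition"), {
      n <- length(kdata)
      complex(real = rnorm(n, sd = sig / sqrt(2)),
              imaginary = rnorm(n, sd = sig / sqrt(2)))
    })
    kdata <- kdata + array(nse, dim(kdata))
  }
  truth$phase_of_spoke <- b
  structure(list(kdata = kdata, traj = traj, timestamp_s = t,
                 coil_maps = maps,
                 meta = list(grid_shape = dm,
                             voxel_size_mm = spec$voxel_size_mm,
                             seed = spec$seed, TR_s = TR_s,
                             n_spokes = as.integer(n_spokes)),
                 truth = truth),
            class = "radial_acquisition")
}

#' Smooth complex coil sensitivity maps
#'
#' Gaussian magnitude bumps centred on `n_coils` points around the torso
#' with a mild per-coil linear phase ramp; deterministic given the seed.
#'
#' @param dm grid shape; @param n_coils coil count; @param seed RNG seed.
#' @return complex array `[X, Y, Z, n_coils]`.
#' @export
coil_maps <- function(dm, n_coils, seed = 1) {
  g <- coord_grids(dm)
  c0 <- (dm + 1) / 2
  ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils + pi / n_coils
  maps <- array(0i, dim = c(dm, n_coils))
  ph <- with_seed(stage_seed(seed, "phantom"),
                  matrix(runif(n_coils * 3, -0.5, 0.5), n_coils))
  for (c in seq_len(n_coils)) {
    cc <- c0 + c(0.55 * dm[1] * cos(ang[c]), 0.55 * dm[2] * sin(ang[c]), 0)
    r2 <- ((g$x - cc[1]) / (0.8 * dm[1]))^2 +
      ((g$y - cc[2]) / (0.8 * dm[2]))^2 + ((g$z - cc[3]) / (1.2 * dm[3]))^2
    mag <- exp(-r2)
    phase <- 2 * pi * (ph[c, 1] * g$x / dm[1] + ph[c, 2] * g$y / dm[2] +
                         ph[c, 3] * g$z / dm[3]) * 0.2
    maps[, , , c] <- mag * exp(1i * phase)
  }
  maps
}

#' Synthesize a hyperpolarized-gas style ventilation volume
#'
#' Intensity proportional to the ventilation amplitude inside the lung,
#' zero outside, averaged over anterior-posterior slabs of `slab_mm`
#' (emulating thick-slice ventilation imaging), multiplied by a smooth
#' second-order polynomial bias field of relative amplitude
#' `bias_amplitude`, plus Gaussian noise.
#'
#' @param truth,spec phantom truth and spec.
#' @param slab_mm slab thickness; must be a multiple of the voxel size and
#'   no thicker than the lung extent along y.
#' @param noise_sigma Gaussian noise SD relative to the mean in-lung signal.
#' @param bias_amplitude relative amplitude of the bias field.
#' @return list with `image` (3D), `mask` (slab-consistent lung mask) and
#'   `slab_vox`.
#' @export
simulate_xe_volume <- function(truth, spec, slab_mm = NULL, noise_sigma = 0,
                               bias_amplitude = 0) {
  dm <- spec$grid_shape
  if (is.null(slab_mm)) slab_mm <- spec$voxel_size_mm
  k <- slab_mm / spec$voxel_size_mm
  stopifnot(abs(k - round(k)) < 1e-9)
  k <- as.integer(round(k))
  ext <- range(which(apply(truth$lung_mask, 2, any)))
  if (k > diff(ext) + 1) stop("slab thicker than the lung extent")
  img <- truth$vent_amplitude_map
  img[!truth$lung_mask] <- 0
  img <- slab_average(img, k, axis = 2)
  mask <- slab_average(truth$lung_mask + 0, k, axis = 2) >= 0.5
  if (bias_amplitude > 0) {
    g <- coord_grids(dm)
    u <- (g$x - dm[1] / 2) / dm[1]; v <- (g$y - dm[2] / 2) / dm[2]
    w <- (g$z - dm[3] / 2) / dm[3]
    raw <- 0.9 * u + 0.6 * w - 1.2 * u * w + 1.5 * v^2 - 0.8 * u^2
    bias <- 1 + bias_amplitude * (raw - mean(raw[mask])) /
      max(abs(raw[mask] - mean(raw[mask])))
    img <- img * bias
  }
  if (noise_sigma > 0) {
    mu <- mean(img[mask & img > 0])
    img <- img + with_seed(stage_seed(spec$seed, "xe"),
                           array(rnorm(prod(dm), sd = noise_sigma * mu), dm))
  }
  list(image = img, mask = mask, slab_vox = k)
}

# Non-overlapping mean pooling along one axis, broadcast back to full size
# (each voxel carries its slab mean).
slab_average <- function(a, k, axis = 2) {
  if (k == 1) return(a)
  apply_along(a, axis, function(m) {
    n <- nrow(m)
    nf <- (n %/% k) * k
    out <- m
    idx <- rep(seq_len(nf %/% k), each = k)
    for (s in seq_len(nf %/% k)) {
      rows <- ((s - 1) * k + 1):(s * k)
      out[rows, ] <- rep(colMeans(m[rows, , drop = FALSE]),
                         each = length(rows))
    }
    if (nf < n)
      out[(nf + 1):n, ] <- rep(colMeans(m[(nf + 1):n, , drop = FALSE]),
                               each = n - nf)
    out
  })
}

#' Find a defect radius covering a target fraction of the lung
#'
#' Binary search over the sphere radius (at fixed centre) so that the
#' sphere's voxel count is as close as possible to `frac` of the lung
#' volume; errors if no suitable radius keeps the sphere inside the lungs.
#'
#' @param truth a `phantom_truth` (defect-free geometry is fine).
#' @param center sphere centre (1-based voxel coordinates).
#' @param frac target fraction of lung voxels in `(0, 1)`.
#' @return radius in voxels.
#' @export
defect_radius_search <- function(truth, center, frac) {
  dm <- dim(truth$lung_mask)
  g <- coord_grids(dm)
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  target <- frac * sum(truth$lung_mask)
  lo <- 1; hi <- max(dm)
  # largest radius keeping the sphere inside the lung
  r_max <- sqrt(min(d2[!truth$lung_mask]))
  hi <- min(hi, r_max * 0.999)
  if (sum(d2 <= hi^2) < target)
    stop("target fraction unreachable inside the lung from this centre")
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (sum(d2 <= mid^2) < target) lo <- mid else hi <- mid
  }
  hi
}
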