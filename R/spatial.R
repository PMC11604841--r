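#' Register respiratory states to the mid-respiration state
#'
#' The mid state is the one whose amplitude is closest to 0.5 (robust to
#' uneven state occupancy).  Every other state is aligned to it with a
#' multi-resolution free-form deformation: a displacement field defined on
#' a coarse control grid (trilinearly interpolated to the voxel grid),
#' optimized by gradient descent on the intensity SSD with an analytic
#' gradient, coarse-to-fine over `levels` resolutions.  If registration
#' fails to reduce the SSD for a state, that state falls back to the
#' identity transform (recorded in `fallback`).
#'
#' @param series an `image_series` from [reconstruct_states()].
#' @param levels multi-resolution levels (default 2).
#' @param spacing control-point spacing in voxels at full resolution.
#' @param iters gradient-descent iterations per level.
#' @return list: `registered` (an `image_series`), `fields` (per state,
#'   list of `ux, uy, uz` voxel displacement volumes mapping state
#'   coordinates to mid-state coordinates), `mid_state`, `fallback`.
#' @export
register_to_mid <- function(series, levels = 2, spacing = 12, iters = 30) {
  ns <- dim(series$data)[1]
  stopifnot(ns >= 2)
  mid <- which.min(abs(series$state_amplitude - 0.5))
  dm <- dim(series$data)[-1]
  fixed <- series$data[mid, , , ]
  reg <- series
  fields <- vector("list", ns)
  fallback <- logical(ns)
  zero <- array(0, dm)
  for (s in seq_len(ns)) {
    if (s == mid) {
      fields[[s]] <- list(ux = zero, uy = zero, uz = zero)
      next
    }
    moving <- series$data[s, , , ]
    r <- ffd_register(fixed, moving, levels, spacing, iters)
    if (r$final_ssd > r$initial_ssd) {
      warning("registration failed for state ", s, "; identity fallback")
      fields[[s]] <- list(ux = zero, uy = zero, uz = zero)
      fallback[s] <- TRUE
    } else {
      fields[[s]] <- r$field
      reg$data[s, , , ] <- r$warped
    }
  }
  list(registered = reg, fields = fields, mid_state = mid,
       fallback = fallback)
}

# Free-form deformation registration of moving onto fixed.
ffd_register <- function(fixed, moving, levels = 2, spacing = 12,
                         iters = 30) {
  dm <- dim(fixed)
  ssd0 <- sum((moving - fixed)^2)
  # control grid at full resolution
  nc <- pmax(ceiling(dm / spacing) + 1, 2)
  ctrl <- lapply(1:3, function(d) array(0, nc))
  for (lev in rev(seq_len(levels))) {
    f <- 2^(lev - 1)
    fx <- downsample3(fixed, f)
    mv <- downsample3(moving, f)
    ctrl <- ffd_optimize(fx, mv, ctrl, nc, f, iters)
  }
  u <- lapply(1:3, function(d) upsample_ctrl(ctrl[[d]], nc, dm))
  warped <- array(warp_trilinear(as.vector(moving), dm, as.vector(u[[1]]),
                                 as.vector(u[[2]]), as.vector(u[[3]])), dm)
  list(field = list(ux = u[[1]], uy = u[[2]], uz = u[[3]]), warped = warped,
       initial_ssd = ssd0, final_ssd = sum((warped - fixed)^2))
}

# Control displacements are stored in full-resolution voxel units; at a
# level downsampled by f they act as u / f.
ffd_optimize <- function(fixed, moving, ctrl, nc, f, iters) {
  grad_m <- central_gradients(moving)
  scale <- f
  pts <- upsample_pts(nc, dim(fixed))
  step <- 1
  cur <- ffd_cost(fixed, moving, ctrl, nc, scale, pts)
  for (it in seq_len(iters)) {
    g <- ffd_grad(fixed, moving, grad_m, ctrl, nc, scale, cur)
    gmax <- max(abs(unlist(g)))
    if (gmax == 0) break
    repeat {
      cand <- lapply(1:3, function(d) ctrl[[d]] - step * g[[d]])
      new <- ffd_cost(fixed, moving, cand, nc, scale, pts)
      if (new$ssd <= cur$ssd || step < 1e-8) break
      step <- step / 2
    }
    if (new$ssd > cur$ssd) break
    improved <- (cur$ssd - new$ssd) / max(cur$ssd, 1e-300)
    ctrl <- cand
    cur <- new
    step <- step * 1.4
    if (improved < 1e-4) break     # converged
  }
  ctrl
}

# Interpolate control-point displacements to the voxel grid of shape dm
# (control grid spans the full volume).  upsample_pts precomputes the
# sampling coordinates so repeated cost evaluations stay cheap.
upsample_pts <- function(nc, dm) {
  pts <- coord_grids(dm)
  cbind(as.vector((pts$x - 1) / pmax(dm[1] - 1, 1) * (nc[1] - 1)),
        as.vector((pts$y - 1) / pmax(dm[2] - 1, 1) * (nc[2] - 1)),
        as.vector((pts$z - 1) / pmax(dm[3] - 1, 1) * (nc[3] - 1)))
}

upsample_ctrl <- function(ctrl, nc, dm, pts = NULL) {
  if (is.null(pts)) pts <- upsample_pts(nc, dm)
  array(sample_points(as.vector(ctrl), nc, pts), dm)
}

ffd_cost <- function(fixed, moving, ctrl, nc, scale, pts = NULL) {
  dm <- dim(fixed)
  u <- lapply(1:3, function(d) upsample_ctrl(ctrl[[d]], nc, dm, pts) / scale)
  w <- array(warp_trilinear(as.vector(moving), dm, as.vector(u[[1]]),
                            as.vector(u[[2]]), as.vector(u[[3]])), dm)
  list(ssd = sum((w - fixed)^2), warped = w, u = u)
}

ffd_grad <- function(fixed, moving, grad_m, ctrl, nc, scale, cc) {
  dm <- dim(fixed)
  resid <- 2 * (cc$warped - fixed)
  # dSSD/du_d(voxel) = resid * dmoving/dx_d at warped position
  out <- vector("list", 3)
  for (d in 1:3) {
    gd <- array(warp_trilinear(as.vector(grad_m[[d]]), dm,
                               as.vector(cc$u[[1]]), as.vector(cc$u[[2]]),
                               as.vector(cc$u[[3]])), dm)
    vox_grad <- resid * gd / scale
    out[[d]] <- downsample_to_ctrl(vox_grad, nc)
  }
  # normalize so steps are in voxel units
  nrm <- max(abs(unlist(out)))
  if (nrm > 0) out <- lapply(out, function(a) a / nrm)
  out
}

# Adjoint of upsample_ctrl: accumulate voxel gradients onto control points
# with the same trilinear weights (approximated by box aggregation).
downsample_to_ctrl <- function(vox, nc) {
  dm <- dim(vox)
  sx <- (seq_len(dm[1]) - 1) / pmax(dm[1] - 1, 1) * (nc[1] - 1)
  sy <- (seq_len(dm[2]) - 1) / pmax(dm[2] - 1, 1) * (nc[2] - 1)
  sz <- (seq_len(dm[3]) - 1) / pmax(dm[3] - 1, 1) * (nc[3] - 1)
  ix <- pmin(round(sx), nc[1] - 1) + 1
  iy <- pmin(round(sy), nc[2] - 1) + 1
  iz <- pmin(round(sz), nc[3] - 1) + 1
  out <- array(0, nc)
  idx <- cbind(rep(ix, times = dm[2] * dm[3]),
               rep(rep(iy, each = dm[1]), times = dm[3]),
               rep(iz, each = dm[1] * dm[2]))
  lin <- (idx[, 3] - 1) * nc[1] * nc[2] + (idx[, 2] - 1) * nc[1] + idx[, 1]
  acc <- tapply(as.vector(vox), lin, sum)
  out[as.integer(names(acc))] <- acc
  out
}

central_gradients <- function(a) {
  dm <- dim(a)
  g <- vector("list", 3)
  for (d in 1:3) {
    hi <- lapply(dm, seq_len); lo <- lapply(dm, seq_len)
    hi[[d]] <- pmin(hi[[d]] + 1, dm[d]); lo[[d]] <- pmax(lo[[d]] - 1, 1)
    g[[d]] <- (do.call(`[`, c(list(a), hi)) - do.call(`[`, c(list(a), lo))) / 2
  }
  g
}

downsample3 <- function(a, f) {
  if (f == 1) return(a)
  dm <- dim(a)
  nd <- dm %/% f
  a <- a[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f)]
  ds1 <- function(x, f) {
    d <- dim(x)
    array(colMeans(array(x, c(f, d[1] %/% f, d[2], d[3]))),
          c(d[1] %/% f, d[2], d[3]))
  }
  a <- ds1(a, f)
  a <- aperm(ds1(aperm(a, c(2, 1, 3)), f), c(2, 1, 3))
  aperm(ds1(aperm(a, c(3, 2, 1)), f), c(3, 2, 1))
}

#' Segment the thoracic cavity by seeded region growing
#'
#' 6-connected region growing from the given seeds, accepting voxels whose
#' intensity is within `tolerance * robust_range` of the running regional
#' mean (robust range = inner 98% intensity spread of the volume), followed
#' by morphological closing (radius 1) and hole filling.  A region that
#' touches more than 10% of the image border is rejected as a leak.
#'
#' @param volume 3D image (typically the mid-respiration magnitude image).
#' @param seeds list/matrix of 1-based voxel coordinates, or `"auto"` to
#'   seed at the two largest dark connected components inside the body.
#' @param tolerance acceptance tolerance as a fraction of the robust range.
#' @return a `thoracic_mask`: logical 3D array with attributes `seeds` and
#'   `tolerance`.
#' @export
segment_thoracic_cavity <- function(volume, seeds, tolerance = 0.15) {
  dm <- dim(volume)
  if (identical(seeds, "auto")) seeds <- auto_seeds(volume)
  if (is.list(seeds)) seeds <- do.call(rbind, seeds)
  seeds <- matrix(as.numeric(seeds), ncol = 3)
  stopifnot(nrow(seeds) >= 1)
  lin <- as.integer((seeds[, 3] - 1) * dm[1] * dm[2] +
                      (seeds[, 2] - 1) * dm[1] + seeds[, 1] - 1)
  rng <- quantile(volume, c(0.01, 0.99), names = FALSE)
  tol_abs <- tolerance * (rng[2] - rng[1])
  m <- array(region_grow6(as.vector(volume), dm, lin, tol_abs), dm)
  border <- array(FALSE, dm)
  border[c(1, dm[1]), , ] <- TRUE
  border[, c(1, dm[2]), ] <- TRUE
  border[, , c(1, dm[3])] <- TRUE
  if (sum(m & border) > 0.1 * sum(border))
    stop("region growing leaked to the image border")
  m <- morph_close(m)
  m <- fill_holes(m)
  structure(m, class = c("thoracic_mask", class(m)),
            seeds = seeds, tolerance = tolerance)
}

# Seeds at the two largest dark connected components inside the body:
# voxels below half the median positive intensity, away from the border.
auto_seeds <- function(volume) {
  dm <- dim(volume)
  mx <- stats::quantile(volume, 0.99, names = FALSE)
  thr <- 0.5 * stats::median(volume[volume > 0.1 * mx])
  # body support: bright voxels with interior holes (the lungs) filled in,
  # so background air cannot be mistaken for a dark lung component
  body <- fill_holes(morph_close(volume >= thr))
  dark <- volume < thr & body
  lab <- label_components(dark)
  if (max(lab) < 1) stop("auto seeding found no dark components")
  sizes <- tabulate(lab[lab > 0])
  top <- order(sizes, decreasing = TRUE)[seq_len(min(2, length(sizes)))]
  do.call(rbind, lapply(top, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    round(colMeans(idx))
  }))
}

# 6-connected component labelling (BFS via region_grow6 on a binary image).
label_components <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  nextlab <- 0L
  todo <- which(mask & lab == 0)
  while (length(todo) > 0) {
    s <- todo[1]
    comp <- array(region_grow6(as.vector(mask) + 0, dm, s - 1L, 0.5), dm)
    nextlab <- nextlab + 1L
    lab[comp & mask] <- nextlab
    todo <- which(mask & lab == 0L)
  }
  lab
}

morph_close <- function(m) erode1(dilate1(m))

dilate1 <- function(m) {
  out <- m
  dm <- dim(m)
  for (d in 1:3) {
    hi <- lapply(dm, seq_len); lo <- lapply(dm, seq_len)
    hi[[d]] <- pmin(hi[[d]] + 1, dm[d]); lo[[d]] <- pmax(lo[[d]] - 1, 1)
    out <- out | do.call(`[`, c(list(m), hi)) | do.call(`[`, c(list(m), lo))
  }
  out
}

erode1 <- function(m) !dilate1(!m)

fill_holes <- function(m) {
  dm <- dim(m)
  bg <- !m
  # flood the background from a border voxel union: grow from all border
  # background voxels
  border_idx <- which(bg & {
    b <- array(FALSE, dm)
    b[c(1, dm[1]), , ] <- TRUE; b[, c(1, dm[2]), ] <- TRUE
    b[, , c(1, dm[3])] <- TRUE
    b
  })
  if (length(border_idx) == 0) return(m)
  outside <- array(region_grow6(as.vector(bg) + 0, dm,
                                as.integer(border_idx - 1L), 0.5), dm)
  m | (!outside & bg)
}

#' Edge-preserving guided filter (3D)
#'
#' Local linear model `a * guide + b` fitted in a box window of the given
#' radius with ridge regularization `eps`; the classic guided filter
#' extended to 3D.  With `guide == image` (self-guided) it smooths flat
#' regions while preserving edges.
#'
#' @param image 3D array to filter.
#' @param guide guidance image, same shape (default: self-guided).
#' @param radius box window radius in voxels.
#' @param eps regularization (in squared intensity units).
#' @return filtered image.
#' @export
guided_filter3d <- function(image, guide = image, radius = 2, eps = 0.01) {
  stopifnot(all(dim(image) == dim(guide)))
  mean_i <- box_mean3(image, radius)
  mean_g <- box_mean3(guide, radius)
  corr_gi <- box_mean3(guide * image, radius)
  corr_gg <- box_mean3(guide * guide, radius)
  cov_gi <- corr_gi - mean_g * mean_i
  var_g <- corr_gg - mean_g * mean_g
  a <- cov_gi / (var_g + eps)
  b <- mean_i - a * mean_g
  box_mean3(a, radius) * guide + box_mean3(b, radius)
}
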