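#' Polynomial surrogate bias-field correction
#'
#' Fits the log-intensity inside the mask with a full 3D polynomial of the
#' given order by least squares, divides the image by the exponentiated
#' fit, and rescales to preserve the masked mean.  A lightweight surrogate
#' for dedicated bias-field tools (which are out of scope here); phantom
#' ventilation volumes can also simply be generated bias-free.
#'
#' @param volume 3D image.
#' @param mask logical mask (non-empty).
#' @param order polynomial order (default 2).
#' @return corrected volume; attribute `offset` records any additive
#'   offset applied to make masked intensities positive.
#' @export
bias_correct <- function(volume, mask, order = 2) {
  stopifnot(any(mask))
  offset <- 0
  mn <- min(volume[mask])
  if (mn <= 0) {
    offset <- -mn + 1e-6 * diff(range(volume[mask]))
    if (offset == 0) offset <- 1e-6
    volume <- volume + offset
    warning("non-positive intensities inside mask; offset ", signif(offset, 4),
            " applied before log fit")
  }
  dm <- dim(volume)
  g <- coord_grids(dm)
  u <- (g$x - (dm[1] + 1) / 2) / dm[1]
  v <- (g$y - (dm[2] + 1) / 2) / dm[2]
  w <- (g$z - (dm[3] + 1) / 2) / dm[3]
  pows <- expand.grid(i = 0:order, j = 0:order, k = 0:order)
  pows <- pows[rowSums(pows) <= order, , drop = FALSE]
  X <- vapply(seq_len(nrow(pows)), function(r)
    (u[mask]^pows$i[r]) * (v[mask]^pows$j[r]) * (w[mask]^pows$k[r]),
    numeric(sum(mask)))
  cf <- qr.solve(X, log(volume[mask]))
  fit_full <- array(0, dm)
  for (r in seq_len(nrow(pows)))
    fit_full <- fit_full + cf[r] * u^pows$i[r] * v^pows$j[r] * w^pows$k[r]
  corr <- volume / exp(fit_full)
  corr <- corr * (mean(volume[mask]) / mean(corr[mask])) - offset
  attr(corr, "offset") <- offset
  corr
}

#' Threshold ventilation defect percentage
#'
#' Defect voxels are masked voxels with intensity strictly below
#' `frac` times the mean masked intensity (voxels exactly at the threshold
#' count as healthy); VDP is the defect volume as a percentage of the lung
#' volume.  Scale-invariant by construction.
#'
#' @param volume 3D ventilation-weighted image.
#' @param mask logical lung mask (non-empty).
#' @param frac threshold fraction of the masked mean (default 0.60).
#' @return a `defect_result` with `method = "threshold"`.
#' @export
threshold_vdp <- function(volume, mask, frac = 0.60) {
  stopifnot(any(mask))
  thr <- frac * mean(volume[mask])
  defect <- mask & (volume < thr)
  structure(list(defect_mask = defect,
                 vdp_percent = 100 * sum(defect) / sum(mask),
                 cluster_means = NULL, method = "threshold", frac = frac,
                 threshold = thr),
            class = "defect_result")
}

#' Rigid (6-DOF) alignment by mutual information
#'
#' Multi-resolution Nelder-Mead optimization of the negative mutual
#' information between the fixed image and the rigidly transformed moving
#' image (rotations about the volume centre plus translations, linear
#' resampling).  If the optimum is no better than the identity, the
#' identity is returned with a warning.
#'
#' @param moving,fixed 3D images of identical shape.
#' @param bins histogram bins for MI (default 32).
#' @return list: `aligned`, `params` (3 rotations rad, 3 translations vox),
#'   `mi` (achieved), `mi_identity`.
#' @export
rigid_align <- function(moving, fixed, bins = 32) {
  stopifnot(all(dim(moving) == dim(fixed)))
  neg_mi <- function(par, mv, fx) -mutual_information(
    rigid_transform(mv, par), fx, bins)
  par <- rep(0, 6)
  for (f in c(2, 1)) {
    mv <- downsample3(moving, f); fx <- downsample3(fixed, f)
    sc <- par; sc[4:6] <- sc[4:6] / f
    opt <- stats::optim(sc, neg_mi, mv = mv, fx = fx,
                        method = "Nelder-Mead",
                        control = list(maxit = 150, reltol = 1e-7))
    par <- opt$par; par[4:6] <- par[4:6] * f
  }
  mi_id <- mutual_information(moving, fixed, bins)
  mi_opt <- -neg_mi(par, moving, fixed)
  if (mi_opt < mi_id) {
    warning("rigid alignment did not improve mutual information; identity")
    par <- rep(0, 6)
    mi_opt <- mi_id
  }
  list(aligned = rigid_transform(moving, par), params = par, mi = mi_opt,
       mi_identity = mi_id)
}

# Apply a rigid transform: out(i) = moving(R (i - c) + c + t).
rigid_transform <- function(vol, par) {
  dm <- dim(vol)
  cx <- (dm + 1) / 2
  ca <- cos(par[1:3]); sa <- sin(par[1:3])
  Rx <- rbind(c(1, 0, 0), c(0, ca[1], -sa[1]), c(0, sa[1], ca[1]))
  Ry <- rbind(c(ca[2], 0, sa[2]), c(0, 1, 0), c(-sa[2], 0, ca[2]))
  Rz <- rbind(c(ca[3], -sa[3], 0), c(sa[3], ca[3], 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  g <- coord_grids(dm)
  P <- cbind(as.vector(g$x) - cx[1], as.vector(g$y) - cx[2],
             as.vector(g$z) - cx[3])
  Q <- P %*% t(R)
  tgt <- cbind(Q[, 1] + cx[1] + par[4] - 1, Q[, 2] + cx[2] + par[5] - 1,
               Q[, 3] + cx[3] + par[6] - 1)
  array(sample_points(as.vector(vol), dm, tgt), dm)
}

mutual_information <- function(a, b, bins = 32) {
  ra <- range(a); rb <- range(b)
  ia <- pmin(floor((a - ra[1]) / max(diff(ra), 1e-12) * bins) + 1, bins)
  ib <- pmin(floor((b - rb[1]) / max(diff(rb), 1e-12) * bins) + 1, bins)
  joint <- tabulate((ib - 1) * bins + ia, nbins = bins * bins)
  p <- joint / sum(joint)
  px <- rowSums(matrix(p, bins)); py <- colSums(matrix(p, bins))
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (as.vector(outer(px, py)))[nz]))
}
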