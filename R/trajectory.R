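#' Center-out 3D golden-means radial ("koosh-ball") trajectory
#'
#' Spoke directions follow the 3D golden-means construction: for spoke
#' index m (0-based), `z = 1 - 2 frac(m phi1)` and azimuth
#' `theta = 2 pi frac(m phi2)` with the golden means
#' `phi1 = 0.4656145`, `phi2 = 0.6823278` of the modified Fibonacci
#' construction.  Any contiguous block of spokes covers the sphere
#' quasi-uniformly, which is what makes retrospective respiratory binning
#' of arbitrary spoke subsets possible.
#'
#' @param n_spokes number of spokes.
#' @return matrix `n_spokes x 3` of unit direction vectors.
#' @export
golden_means_directions <- function(n_spokes) {
  stopifnot(n_spokes >= 1)
  phi1 <- 0.4656145
  phi2 <- 0.6823278
  m <- seq_len(n_spokes) - 1
  z <- 1 - 2 * ((m * phi1) %% 1)
  th <- 2 * pi * ((m * phi2) %% 1)
  s <- sqrt(pmax(1 - z^2, 0))
  unname(cbind(s * cos(th), s * sin(th), z))
}

#' Ramped center-out readout radii
#'
#' Radius grows quadratically over the first `ramp_fraction` of the readout
#' (gradient ramp-up), then linearly at the plateau slope; continuous in
#' value and slope, starting at 0 and reaching the Nyquist radius 0.5 at
#' the last sample.
#'
#' @param n_readout number of readout samples per spoke (>= 2).
#' @param ramp_fraction fraction of the readout acquired on the ramp,
#'   in `[0, 1)`.
#' @return numeric vector of length `n_readout`, strictly increasing in
#'   `[0, 0.5]`.
#' @export
ramped_radii <- function(n_readout, ramp_fraction = 0.3) {
  stopifnot(n_readout >= 2, ramp_fraction >= 0, ramp_fraction < 1)
  t <- seq(0, 1, length.out = n_readout)
  t0 <- ramp_fraction
  if (t0 == 0) return(0.5 * t)
  a <- 0.5 / (2 * t0 - t0^2)
  r <- ifelse(t <= t0, a * t^2, a * t0^2 + 2 * a * t0 * (t - t0))
  r
}

#' Analytic density compensation for 3D radial sampling
#'
#' Sample weight proportional to `r^2 dr` (spherical shell volume), with
#' `dr` from central finite differences of the radius profile, normalized
#' to sum to 1 along each spoke.
#'
#' @param radii readout radius profile from [ramped_radii()].
#' @return numeric weights, one per readout sample, `sum(dcf) == 1`.
#' @export
density_compensation <- function(radii) {
  n <- length(radii)
  dr <- numeric(n)
  dr[1] <- radii[2] - radii[1]
  dr[n] <- radii[n] - radii[n - 1]
  if (n > 2) dr[2:(n - 1)] <- (radii[3:n] - radii[1:(n - 2)]) / 2
  w <- radii^2 * dr
  w / sum(w)
}

#' Assemble a radial trajectory object
#'
#' @param n_spokes number of spokes.
#' @param n_readout readout samples per spoke.
#' @param ramp_fraction see [ramped_radii()].
#' @return a `radial_trajectory` with directions, radii and dcf.
#' @export
radial_trajectory <- function(n_spokes, n_readout = 64, ramp_fraction = 0.3) {
  radii <- ramped_radii(n_readout, ramp_fraction)
  structure(list(directions = golden_means_directions(n_spokes),
                 radii = radii, ramp_fraction = ramp_fraction,
                 dcf = density_compensation(radii),
                 n_spokes = as.integer(n_spokes),
                 n_readout = as.integer(n_readout)),
            class = "radial_trajectory")
}

#' k-space coordinates for a subset of spokes
#'
#' @param traj a [radial_trajectory()].
#' @param spokes integer spoke indices (1-based); default all.
#' @return matrix `(length(spokes) * n_readout) x 3` in cycles/voxel;
#'   readout varies fastest.
#' @export
traj_coords <- function(traj, spokes = seq_len(traj$n_spokes)) {
  d <- traj$directions[spokes, , drop = FALSE]
  r <- traj$radii
  nr <- length(r)
  ns <- nrow(d)
  # readout fastest: rows (sample, spoke)
  cbind(as.vector(outer(r, d[, 1])),
        as.vector(outer(r, d[, 2])),
        as.vector(outer(r, d[, 3])))
}
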