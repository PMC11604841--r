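#' Interpolate equidistant respiratory phases by non-parametric regression
#'
#' Voxel-wise local-linear kernel regression of intensity on respiratory
#' amplitude (Gaussian kernel), evaluated at `n_out` equidistant phase
#' points spanning the observed amplitude range.  Local-linear weights
#' reproduce any signal that is exactly linear in amplitude, and the whole
#' operation is a single `n_out x n_states` weight matrix applied to the
#' state stack.
#'
#' @param registered an `image_series` (registered to mid-respiration).
#' @param n_out number of output phases (default 15).
#' @param bandwidth kernel bandwidth on the amplitude axis; default 1.5x
#'   the output phase spacing.
#' @return a `phase_series`: `data [n_out, X, Y, Z]`, `phase_grid`.
#' @export
interpolate_phases <- function(registered, n_out = 15, bandwidth = NULL) {
  amp <- registered$state_amplitude
  ns <- length(amp)
  stopifnot(ns >= 3)
  grid <- seq(min(amp), max(amp), length.out = n_out)
  if (is.null(bandwidth)) bandwidth <- 1.5 * diff(grid[1:2])
  if (bandwidth <= 0) stop("bandwidth must be positive")
  W <- local_linear_weights(amp, grid, bandwidth)
  dm <- dim(registered$data)[-1]
  flat <- matrix(registered$data, nrow = ns)
  out <- W %*% flat
  structure(list(data = array(out, c(n_out, dm)), phase_grid = grid,
                 bandwidth = bandwidth,
                 voxel_size_mm = registered$voxel_size_mm),
            class = "phase_series")
}

# Local-linear (degree-1) kernel regression equivalent weights:
# rows = evaluation points, cols = design points.
local_linear_weights <- function(x, grid, h) {
  t(vapply(grid, function(t0) {
    u <- x - t0
    k <- exp(-0.5 * (u / h)^2)
    s0 <- sum(k); s1 <- sum(k * u); s2 <- sum(k * u^2)
    den <- s0 * s2 - s1^2
    if (abs(den) < 1e-300 * max(s2, 1)) k / s0
    else k * (s2 - u * s1) / den
  }, numeric(length(x))))
}

#' Voxel-wise regional ventilation (RVent)
#'
#' End-expiration is the end of the phase grid with the larger mean lung
#' signal (parenchymal density is maximal at expiration), end-inspiration
#' the opposite end.  Under the default `"exp-denominator"` convention
#' `RVent = (S_ex - S_in) / S_ex` (fractional ventilation relative to the
#' expiratory signal); `"insp-denominator"` computes
#' `(S_ex - S_in) / S_in`.  Masked voxels with non-positive `S_ex` are
#' flagged invalid and excluded from downstream VDP denominators.
#'
#' @param phases a `phase_series` from [interpolate_phases()].
#' @param mask logical 3D lung / thoracic-cavity mask.
#' @param convention `"exp-denominator"` (default) or `"insp-denominator"`.
#' @return an `rvent_map`: `map` (3D, `NA` outside mask), `valid` (logical),
#'   `n_invalid`, `convention`.
#' @export
compute_rvent <- function(phases, mask,
                          convention = c("exp-denominator",
                                         "insp-denominator")) {
  convention <- match.arg(convention)
  np <- dim(phases$data)[1]
  stopifnot(np >= 2)
  dm <- dim(phases$data)[-1]
  stopifnot(all(dim(mask) == dm))
  first <- phases$data[1, , , ]
  last <- phases$data[np, , , ]
  if (mean(first[mask]) >= mean(last[mask])) {
    s_ex <- first; s_in <- last
  } else {
    s_ex <- last; s_in <- first
  }
  valid <- mask & (s_ex > 0)
  n_invalid <- sum(mask) - sum(valid)
  map <- array(NA_real_, dm)
  if (convention == "exp-denominator")
    map[valid] <- (s_ex[valid] - s_in[valid]) / s_ex[valid]
  else
    map[valid] <- (s_ex[valid] - s_in[valid]) / s_in[valid]
  rng <- range(map[valid])
  flag <- rng[1] < -0.5 || rng[2] > 1.5
  structure(list(map = map, valid = valid, n_invalid = n_invalid,
                 convention = convention, out_of_range = flag),
            class = "rvent_map")
}

#' Ventilation defect percentage by k-means clustering
#'
#' k-means (many restarts, fixed internal seed for determinism) on the
#' RVent values inside the mask; clusters are sorted by mean and the union
#' of the lowest `defect_clusters` clusters is the defect region.  `"3D"`
#' mode clusters the whole volume; `"2D"` mode pools coronal-slice data
#' (identical values to 3D on the same input) unless `per_slice = TRUE`,
#' which clusters each coronal slice independently.
#'
#' @param rvent an `rvent_map` (or bare numeric array).
#' @param mask logical mask; defaults to the rvent map's valid voxels.
#' @param k number of clusters (default 4).
#' @param defect_clusters how many of the lowest clusters form the defect.
#' @param mode `"3D"` or `"2D"`.
#' @param per_slice cluster each coronal slice separately (2D mode only).
#' @param clip_negative treat negative RVent as zero ventilation before
#'   clustering (default TRUE): negative fractional ventilation is
#'   unphysical measurement noise, and letting a small far-negative outlier
#'   group capture the "lowest cluster" slot would hide the true defect.
#' @param seed RNG seed for the k-means restarts.
#' @return a `defect_result`: `defect_mask`, `vdp_percent`, `cluster_means`,
#'   `method = "kmeans"`.
#' @export
vdp_kmeans <- function(rvent, mask = NULL, k = 4, defect_clusters = 1,
                       mode = c("3D", "2D"), per_slice = FALSE,
                       clip_negative = TRUE, seed = 7) {
  mode <- match.arg(mode)
  vals_arr <- if (inherits(rvent, "rvent_map")) rvent$map else rvent
  if (clip_negative) vals_arr <- pmax(vals_arr, 0)
  if (is.null(mask)) {
    stopifnot(inherits(rvent, "rvent_map"))
    mask <- rvent$valid
  }
  if (inherits(rvent, "rvent_map")) mask <- mask & rvent$valid
  dm <- dim(vals_arr)
  defect <- array(FALSE, dm)
  cluster_means <- NULL
  assign_defect <- function(idx) {
    v <- vals_arr[idx]
    if (length(v) < k) stop("fewer than k masked voxels")
    if (length(unique(v)) < k)
      stop("fewer than k distinct values in mask")
    km <- with_seed(seed, kmeans(v, centers = k, nstart = 50,
                                 iter.max = 200, algorithm = "Lloyd"))
    o <- order(km$centers)
    cluster_means <<- sort(as.numeric(km$centers))
    low <- o[seq_len(defect_clusters)]
    idx[km$cluster %in% low]
  }
  if (mode == "2D" && per_slice) {
    for (y in seq_len(dm[2])) {
      sl <- array(FALSE, dm); sl[, y, ] <- TRUE
      idx <- which(mask & sl)
      if (length(idx) >= k && length(unique(vals_arr[idx])) >= k)
        defect[assign_defect(idx)] <- TRUE
    }
  } else {
    defect[assign_defect(which(mask))] <- TRUE
  }
  vdp <- 100 * sum(defect & mask) / sum(mask)
  structure(list(defect_mask = defect, vdp_percent = vdp,
                 cluster_means = cluster_means, method = "kmeans",
                 mode = mode, k = k, defect_clusters = defect_clusters),
            class = "defect_result")
}

#' Exhaustive 1D k-means oracle
#'
#' Optimal 1D k-means is a contiguous partition of the sorted values; this
#' enumerates all contiguous partitions and returns the global optimum.
#' Used as an independent check of [vdp_kmeans()] on small inputs.
#'
#' @param v numeric values (<= a few dozen).
#' @param k clusters.
#' @return list: `cluster` (assignment in sorted-mean order), `centers`,
#'   `withinss_total`.
#' @export
kmeans_oracle_1d <- function(v, k) {
  n <- length(v)
  o <- order(v)
  s <- v[o]
  cuts <- utils::combn(n - 1, k - 1)
  best <- NULL; best_ss <- Inf
  for (j in seq_len(ncol(cuts))) {
    br <- c(0, cuts[, j], n)
    ss <- 0
    for (g in seq_len(k)) {
      seg <- s[(br[g] + 1):br[g + 1]]
      ss <- ss + sum((seg - mean(seg))^2)
    }
    if (ss < best_ss) { best_ss <- ss; best <- br }
  }
  cl <- integer(n)
  ctr <- numeric(k)
  for (g in seq_len(k)) {
    sel <- (best[g] + 1):best[g + 1]
    cl[o[sel]] <- g
    ctr[g] <- mean(s[sel])
  }
  list(cluster = cl, centers = ctr, withinss_total = best_ss)
}
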