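#' DC self-gating: extract the respiratory waveform
#'
#' The respiratory navigator is the average magnitude of the first
#' `n_points` readout samples of every spoke (the k-space centre, i.e. the
#' DC signal, proportional to total image signal and so modulated by the
#' breathing-driven parenchymal density change).  With `coil = "auto"` the
#' coil whose candidate waveform has the largest spectral power in the
#' respiratory band (0.1-0.5 Hz) is selected, standing in for the manual
#' "coil closest to the diaphragm" choice.
#'
#' @param acq a `radial_acquisition`.
#' @param n_points readout points to average (default 5).
#' @param coil coil index or `"auto"`.
#' @return list: `raw` waveform (per spoke), `coil_index_used`.
#' @export
extract_dc <- function(acq, n_points = 5, coil = "auto") {
  nr <- dim(acq$kdata)[2]
  nc <- dim(acq$kdata)[3]
  stopifnot(n_points <= nr)
  cand <- function(ci) {
    rowMeans(Mod(acq$kdata[, seq_len(n_points), ci, drop = FALSE]))
  }
  if (identical(coil, "auto")) {
    TRs <- acq$meta$TR_s
    n <- dim(acq$kdata)[1]
    f <- (seq_len(n) - 1) / (n * TRs)
    band <- f >= 0.1 & f <= 0.5
    pw <- vapply(seq_len(nc), function(ci) {
      w <- cand(ci)
      sum(Mod(stats::fft(w - mean(w)))[band]^2)
    }, numeric(1))
    coil <- which.max(pw)
  }
  if (coil < 1 || coil > nc) stop("coil index out of range")
  list(raw = cand(coil), coil_index_used = as.integer(coil))
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing.  Interior points use the
#' standard SG convolution kernel; each endpoint is the value of a
#' polynomial fit on its truncated window.
#'
#' @param raw numeric waveform.
#' @param window odd window length, `> polyorder` and `<= length(raw)`.
#' @param polyorder polynomial order.
#' @return smoothed waveform, same length.
#' @export
smooth_waveform <- function(raw, window = 51, polyorder = 3) {
  n <- length(raw)
  stopifnot(window %% 2 == 1, window > polyorder)
  if (window > n) stop("window longer than the waveform")
  h <- (window - 1) / 2
  ker <- sg_kernel(window, polyorder)
  out <- stats::filter(raw, ker, sides = 2)
  out <- as.numeric(out)
  # endpoints: polynomial fit on the truncated window
  for (i in which(is.na(out))) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    xs <- (lo:hi) - i
    A <- outer(xs, 0:min(polyorder, length(xs) - 1), "^")
    cf <- qr.solve(A, raw[lo:hi])
    out[i] <- cf[1]
  }
  out
}

# SG convolution kernel: centre row of the least-squares smoothing matrix.
sg_kernel <- function(window, polyorder) {
  h <- (window - 1) / 2
  x <- -h:h
  A <- outer(x, 0:polyorder, "^")
  H <- A %*% solve(crossprod(A), t(A))
  H[h + 1, ]
}

#' De-drift by block-wise rescaling
#'
#' Slow receiver-gain drift is removed by rescaling the waveform to
#' `[0, 1]` using the minimum and maximum within consecutive blocks of
#' `block_size` spokes (the last block may be short; a constant block maps
#' to 0.5).
#'
#' @param smooth numeric waveform.
#' @param block_size spokes per block (>= 2).
#' @return normalized waveform in `[0, 1]`.
#' @export
rescale_blocks <- function(smooth, block_size = 5000) {
  stopifnot(block_size >= 2)
  n <- length(smooth)
  out <- numeric(n)
  starts <- seq(1, n, by = block_size)
  for (s in starts) {
    e <- min(s + block_size - 1, n)
    x <- smooth[s:e]
    rng <- range(x)
    out[s:e] <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else 0.5
  }
  out
}

#' Bin spokes into respiratory states with weighted spoke sharing
#'
#' The amplitude axis is divided into `n_states` equal-count (quantile)
#' bins from expiration (0) to inspiration (1).  Each state additionally
#' receives the nearest `shared_fraction * core_size` spokes from each
#' neighbouring bin, down-weighted by a decaying exponential
#' `w = exp(-decay_rate * d)` in the spoke's amplitude distance `d` from
#' the bin edge (normalized by the receiving bin's width); core spokes have
#' weight 1.
#'
#' @param normalized waveform in `[0, 1]` from [rescale_blocks()].
#' @param n_states number of respiratory states (>= 2).
#' @param shared_fraction fraction of a core bin shared from each
#'   neighbour, `[0, 1)`.
#' @param decay_rate exponential decay of shared-spoke weights.
#' @return a `phase_binning`: `membership` (per state, data.frame
#'   `spoke`/`weight`), `state_amplitude`, `n_states`, `shared_fraction`.
#' @export
bin_phases <- function(normalized, n_states = 30, shared_fraction = 0.30,
                       decay_rate = 3.0) {
  n <- length(normalized)
  stopifnot(n_states >= 2, shared_fraction >= 0, shared_fraction < 1)
  if (n < n_states) stop("fewer spokes than states")
  ord <- order(normalized)
  bounds <- round(seq(0, n, length.out = n_states + 1))
  core <- lapply(seq_len(n_states), function(j)
    ord[(bounds[j] + 1):bounds[j + 1]])
  amp <- vapply(core, function(ix) stats::median(normalized[ix]), numeric(1))
  membership <- vector("list", n_states)
  for (j in seq_len(n_states)) {
    sp <- core[[j]]
    wt <- rep(1, length(sp))
    cj <- normalized[core[[j]]]
    bw <- max(max(cj) - min(cj), 1e-12)
    n_share <- round(shared_fraction * length(core[[j]]))
    if (n_share > 0) {
      if (j > 1) {   # nearest spokes from the lower neighbour
        don <- core[[j - 1]]
        don <- don[order(normalized[don], decreasing = TRUE)]
        take <- don[seq_len(min(n_share, length(don)))]
        edge <- min(cj)
        d <- (edge - normalized[take]) / bw
        sp <- c(sp, take); wt <- c(wt, exp(-decay_rate * pmax(d, 0)))
      }
      if (j < n_states) {
        don <- core[[j + 1]]
        don <- don[order(normalized[don])]
        take <- don[seq_len(min(n_share, length(don)))]
        edge <- max(cj)
        d <- (normalized[take] - edge) / bw
        sp <- c(sp, take); wt <- c(wt, exp(-decay_rate * pmax(d, 0)))
      }
    }
    membership[[j]] <- data.frame(spoke = sp, weight = wt)
  }
  o <- order(amp)
  structure(list(n_states = as.integer(n_states),
                 membership = membership[o],
                 state_amplitude = amp[o],
                 shared_fraction = shared_fraction,
                 decay_rate = decay_rate),
            class = "phase_binning")
}

#' Estimate the slow receiver-gain envelope from the DC waveform
#'
#' The respiratory oscillation rides on a slowly drifting baseline
#' (receiver gain, gradient heating).  Per block of `block_size` spokes the
#' baseline is taken as the mid-envelope `(min + max) / 2` of the smoothed
#' DC signal (which removes the breathing oscillation to first order), then
#' linearly interpolated across block centres and normalized to mean 1.
#' Dividing the k-space data by this gain before reconstruction removes the
#' within-state gain inconsistency that amplitude binning would otherwise
#' mix into each respiratory state.
#'
#' @param smooth smoothed DC waveform.
#' @param block_size spokes per block (as in [rescale_blocks()]).
#' @return per-spoke multiplicative gain estimate, mean 1.
#' @export
estimate_drift_gain <- function(smooth, block_size = 5000) {
  n <- length(smooth)
  starts <- seq(1, n, by = block_size)
  centers <- pmin(starts + (block_size - 1) / 2, n)
  base <- vapply(starts, function(s) {
    x <- smooth[s:min(s + block_size - 1, n)]
    (min(x) + max(x)) / 2
  }, numeric(1))
  g <- stats::approx(centers, base, xout = seq_len(n), rule = 2)$y
  g / mean(g)
}

#' Full self-gating chain
#'
#' [extract_dc()] then [smooth_waveform()], [rescale_blocks()] (block size
#' defaults to `max(n_spokes / 8, 500)` at desk scale) and [bin_phases()].
#'
#' @param acq a `radial_acquisition`.
#' @param n_states,shared_fraction,decay_rate see [bin_phases()].
#' @param window,polyorder see [smooth_waveform()].
#' @param block_size see [rescale_blocks()]; `NULL` for the desk-scale
#'   default.
#' @return list: `waveform` (raw, smooth, normalized, coil_index_used,
#'   block_size), `binning`.
#' @export
self_gate <- function(acq, n_states = 10, shared_fraction = 0.30,
                      decay_rate = 3.0, window = NULL, polyorder = 3,
                      block_size = NULL) {
  dc <- extract_dc(acq)
  n <- length(dc$raw)
  if (is.null(window)) {
    # ~0.4 s of spokes, forced odd
    window <- max(2 * floor(0.2 / acq$meta$TR_s) + 1, polyorder + 2)
    if (window %% 2 == 0) window <- window + 1
    window <- min(window, if (n %% 2 == 1) n else n - 1)
  }
  if (is.null(block_size)) block_size <- max(round(n / 8), 500)
  sm <- smooth_waveform(dc$raw, window, polyorder)
  nm <- rescale_blocks(sm, block_size)
  list(waveform = list(raw = dc$raw, smooth = sm, normalized = nm,
                       coil_index_used = dc$coil_index_used,
                       block_size = block_size),
       drift_gain = estimate_drift_gain(sm, block_size),
       binning = bin_phases(nm, n_states, shared_fraction, decay_rate))
}
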