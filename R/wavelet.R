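#' Orthogonal 3D Symlet-4 wavelet transform
#'
#' Separable periodic DWT used as the sparsifying transform Psi in the
#' reconstruction penalty `lambda * ||Psi x||_1`.  The transform is
#' orthogonal, so the proximal operator of the penalty is soft-thresholding
#' of the coefficients.  Array dimensions must be divisible by `2^levels`.
#'
#' @param x real or complex 3D array.
#' @param levels decomposition levels (default 2).
#' @return coefficient array of the same shape (`wav3_forward`), or the
#'   reconstructed array (`wav3_inverse`).
#' @export
wav3_forward <- function(x, levels = 2) {
  dm <- dim(x)
  stopifnot(all(dm %% 2^levels == 0))
  for (l in seq_len(levels)) {
    sub <- dm %/% 2^(l - 1)
    blk <- x[seq_len(sub[1]), seq_len(sub[2]), seq_len(sub[3]), drop = FALSE]
    for (d in 1:3) blk <- dwt_axis(blk, d, inverse = FALSE)
    x[seq_len(sub[1]), seq_len(sub[2]), seq_len(sub[3])] <- blk
  }
  x
}

#' @rdname wav3_forward
#' @export
wav3_inverse <- function(x, levels = 2) {
  dm <- dim(x)
  stopifnot(all(dm %% 2^levels == 0))
  for (l in rev(seq_len(levels))) {
    sub <- dm %/% 2^(l - 1)
    blk <- x[seq_len(sub[1]), seq_len(sub[2]), seq_len(sub[3]), drop = FALSE]
    for (d in 1:3) blk <- dwt_axis(blk, d, inverse = TRUE)
    x[seq_len(sub[1]), seq_len(sub[2]), seq_len(sub[3])] <- blk
  }
  x
}

# Symlet-4 decomposition low-pass filter (8 taps).
sym4_lo <- c(-0.07576571478927333, -0.02963552764599851,
             0.49761866763201545, 0.80373875180591614,
             0.29785779560527736, -0.09921954357684722,
             -0.01260396726203783, 0.03222310060404270)

# One periodic DWT level along axis d of a 3D array (or its inverse).
dwt_axis <- function(a, d, inverse = FALSE) {
  lo <- sym4_lo
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L))       # QMF high-pass
  apply_along(a, d, function(m) {
    n <- nrow(m)
    h <- n %/% 2
    if (!inverse) {
      out <- m
      # approximation a[k] = sum_j lo[j] x[(2k + j - 1) mod n]
      for (k in seq_len(h)) {
        idx <- ((2 * (k - 1) + seq_len(L) - 1) %% n) + 1
        out[k, ] <- lo %*% m[idx, , drop = FALSE]
        out[h + k, ] <- hi %*% m[idx, , drop = FALSE]
      }
      out
    } else {
      out <- m * 0
      for (k in seq_len(h)) {
        idx <- ((2 * (k - 1) + seq_len(L) - 1) %% n) + 1
        out[idx, ] <- out[idx, ] + outer(lo, m[k, ]) + outer(hi, m[h + k, ])
      }
      out
    }
  })
}

# Complex soft-threshold.
soft_threshold <- function(x, tau) {
  m <- Mod(x)
  s <- pmax(1 - tau / pmax(m, .Machine$double.eps), 0)
  x * s
}
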