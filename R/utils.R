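#' @useDynLib preful3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif sd var quantile pt pf median optimize optim kmeans complete.cases
#' @importFrom utils write.csv read.csv
NULL

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

# Derive a per-stage seed from the global seed; documented fan-out hash,
# kept below 2^31.
stage_seed <- function(seed, stage) {
  stages <- c(phantom = 1L, acquisition = 2L, gating = 3L, recon = 4L,
              spatial = 5L, preful = 6L, xe = 7L, compare = 8L)
  k <- if (is.character(stage)) stages[[stage]] else as.integer(stage)
  as.integer((as.double(seed) * 48271 + k * 101) %% 2147483647)
}

# Moving-sum box filter along each axis of a 3D array (window 2r+1,
# zero-padded), via cumulative sums.  Returns the *sum*, not the mean.
box_sum3 <- function(a, r) {
  if (r == 0) return(a)
  for (d in 1:3) {
    a <- apply_along(a, d, function(m) {
      n <- nrow(m)
      cs <- rbind(0, apply(m, 2, cumsum))
      hi <- pmin(seq_len(n) + r, n) + 1
      lo <- pmax(seq_len(n) - r, 1)
      cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
    })
  }
  a
}

# Box mean with matching window-size normalization (edge-aware).
box_mean3 <- function(a, r) {
  box_sum3(a, r) / box_sum3(array(1, dim(a)), r)
}

# Apply f to a 3D array unfolded so axis d is the rows; f must keep shape.
apply_along <- function(a, d, f) {
  dm <- dim(a)
  perm <- c(d, setdiff(1:3, d))
  b <- aperm(a, perm)
  dim(b) <- c(dm[d], prod(dm[-d]))
  b <- f(b)
  dim(b) <- dm[perm]
  aperm(b, order(perm))
}

# Coordinate grids (1-based voxel index) for a 3D shape.
coord_grids <- function(dm) {
  list(x = array(rep(seq_len(dm[1]), times = dm[2] * dm[3]), dm),
       y = array(rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]), dm),
       z = array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dm))
}

nrmse <- function(x, ref) {
  sqrt(mean((x - ref)^2)) / (max(ref) - min(ref))
}
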