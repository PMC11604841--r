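#' Non-uniform Fourier (gridding) operator
#'
#' Type-2 (image to non-Cartesian k-space) and type-1 (adjoint) transforms
#' built on Kaiser-Bessel gridding with an oversampled FFT grid.  Sample
#' locations are given in normalized k-space units, cycles per voxel of the
#' reconstruction grid, so coordinates live in `[-0.5, 0.5]^3`.
#'
#' The forward model evaluated is
#' \deqn{y(k) = \sum_i x(i)\, e^{-2\pi i\, k \cdot (i - N/2)}}
#' with the image centred on the grid, so the k-space centre sample equals
#' the plain sum of the image.  `nufft_adjoint()` is the exact conjugate
#' transpose of `nufft_forward()` (the spreading and interpolation kernels
#' share one lookup table), which the adjoint dot-product test verifies to
#' machine precision.
#'
#' @param grid_shape integer(3), image grid size.
#' @param osf oversampling factor for the FFT grid (default 1.25).
#' @param width Kaiser-Bessel kernel width in oversampled grid units.
#' @return a plan object used by [nufft_forward()] and [nufft_adjoint()].
#' @export
nufft_plan <- function(grid_shape, osf = 1.25, width = 5) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4))
  n_os <- vapply(grid_shape, function(n) good_fft_size(ceiling(n * osf)),
                 integer(1))
  beta <- pi * sqrt((width^2 / osf^2) * (osf - 0.5)^2 - 0.8)
  hw <- width / 2
  m <- 4096L
  r <- seq(0, hw, length.out = m)
  ktab <- besselI(beta * sqrt(pmax(1 - (r / hw)^2, 0)), 0) / besselI(beta, 0)
  ktab[m] <- 0
  # Deapodization: continuous Fourier transform of the KB kernel evaluated
  # at centred image positions, per axis.
  # Image voxel i (0-based) sits at wrapped grid index (i - N/2) mod n_os,
  # so the centred exponent exp(-2 pi i k (i - N/2)) is realized by the FFT
  # directly; deapodization is evaluated at the signed position (i - N/2).
  deap <- vector("list", 3)
  emb <- vector("list", 3)
  for (d in 1:3) {
    p <- seq_len(grid_shape[d]) - 1 - grid_shape[d] %/% 2
    deap[[d]] <- kb_ft(p / n_os[d], width, beta)
    emb[[d]] <- (p %% n_os[d]) + 1L
  }
  structure(list(N = as.integer(grid_shape), n_os = as.integer(n_os),
                 emb = emb,
                 ktab = ktab, halfwidth = hw, beta = beta, width = width,
                 deapod = outer3(deap[[1]], deap[[2]], deap[[3]])),
            class = "nufft_plan")
}

# Fourier transform of the Kaiser-Bessel kernel of width W (grid samples)
# at frequency nu (cycles/sample); integral normalization.
kb_ft <- function(nu, W, beta) {
  a2 <- beta^2 - (pi * W * nu)^2
  out <- numeric(length(a2))
  pos <- a2 > 0
  out[pos] <- sinh(sqrt(a2[pos])) / sqrt(a2[pos])
  neg <- a2 < 0
  out[neg] <- sin(sqrt(-a2[neg])) / sqrt(-a2[neg])
  out[a2 == 0] <- 1
  out * W / besselI(beta, 0)
}

good_fft_size <- function(n) {
  n <- as.integer(n)
  if (n %% 2 == 1L) n <- n + 1L
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 2L
  }
}

outer3 <- function(a, b, c) {
  array(outer(outer(a, b), c), dim = c(length(a), length(b), length(c)))
}

#' @rdname nufft_plan
#' @param plan a plan from [nufft_plan()].
#' @param image complex (or real) 3D array of dimension `grid_shape`.
#' @param coords S x 3 matrix of k-space locations in cycles/voxel
#'   (`[-0.5, 0.5]`).
#' @export
nufft_forward <- function(plan, image, coords) {
  stopifnot(inherits(plan, "nufft_plan"))
  N <- plan$N; n_os <- plan$n_os
  x <- array(as.complex(image) / as.vector(plan$deapod), dim = N)
  big <- array(0i, dim = n_os)
  big[plan$emb[[1]], plan$emb[[2]], plan$emb[[3]]] <- x
  X <- stats::fft(big)
  g <- sweep(coords, 2, n_os, "*")
  nufft_interp3(g, as.vector(X), n_os, plan$ktab, plan$halfwidth)
}

#' @rdname nufft_plan
#' @param data complex vector of non-Cartesian samples (length `nrow(coords)`).
#' @export
nufft_adjoint <- function(plan, data, coords) {
  stopifnot(inherits(plan, "nufft_plan"))
  N <- plan$N; n_os <- plan$n_os
  g <- sweep(coords, 2, n_os, "*")
  grid <- nufft_spread3(g, as.complex(data), n_os, plan$ktab, plan$halfwidth)
  X <- stats::fft(array(grid, dim = n_os), inverse = TRUE)
  x <- X[plan$emb[[1]], plan$emb[[2]], plan$emb[[3]]]
  x / plan$deapod
}

#' Exact (slow) non-uniform discrete Fourier transform, used as an oracle.
#' @inheritParams nufft_forward
#' @keywords internal
#' @export
nudft_forward <- function(image, coords) {
  N <- dim(image)
  idx <- as.matrix(expand.grid(0:(N[1] - 1), 0:(N[2] - 1), 0:(N[3] - 1)))
  ctr <- sweep(idx, 2, N / 2, "-")
  x <- as.complex(image)
  vapply(seq_len(nrow(coords)), function(s) {
    ph <- exp(-2i * pi * as.vector(ctr %*% coords[s, ]))
    sum(x * ph)
  }, complex(1))
}

# Multi-coil forward/adjoint: one tap computation serves all coils.
# images: [X, Y, Z, C]; data: S x C matrix.
nufft_forward_multi <- function(plan, images, coords) {
  N <- plan$N; n_os <- plan$n_os
  nc <- dim(images)[4]
  big <- array(0i, dim = c(n_os, nc))
  for (c in seq_len(nc)) {
    x <- array(as.complex(images[, , , c]) / as.vector(plan$deapod), dim = N)
    tmp <- array(0i, dim = n_os)
    tmp[plan$emb[[1]], plan$emb[[2]], plan$emb[[3]]] <- x
    big[, , , c] <- stats::fft(tmp)
  }
  g <- sweep(coords, 2, n_os, "*")
  nufft_interp3_multi(g, as.vector(big), n_os, nc, plan$ktab, plan$halfwidth)
}

nufft_adjoint_multi <- function(plan, data, coords) {
  N <- plan$N; n_os <- plan$n_os
  nc <- ncol(data)
  g <- sweep(coords, 2, n_os, "*")
  grids <- nufft_spread3_multi(g, data, n_os, plan$ktab, plan$halfwidth)
  grids <- array(grids, dim = c(n_os, nc))
  out <- array(0i, dim = c(N, nc))
  for (c in seq_len(nc)) {
    X <- stats::fft(grids[, , , c], inverse = TRUE)
    out[, , , c] <- X[plan$emb[[1]], plan$emb[[2]], plan$emb[[3]]] /
      plan$deapod
  }
  out
}
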