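#' Direct non-uniform DFT (exact, small grids)
#'
#' Brute-force evaluation of \eqn{s_j = \sum_x I(x)\,e^{-2\pi i k_j \cdot x / N}}
#' with image indices centered on the matrix center (DC at the center pixel,
#' index \code{floor(N/2)} zero-based) and k in cycles per field of view.
#' This is the package's fixed coordinate convention and the exact oracle for
#' the fast gridding transform; it is restricted to grids of at most 64 x 64.
#'
#' @param image complex (or numeric) \code{N x N} matrix.
#' @param kx,ky sample coordinates in cycles/FOV.
#' @return complex vector of samples.
#' @export
nudft_forward <- function(image, kx, ky) {
  n <- nrow(image)
  if (n != ncol(image)) stop("image must be square")
  if (n > 64) stop("grid larger than 64 x 64: use the fast gridding transform (nufft_plan/nufft_forward)")
  idx <- seq_len(n) - 1 - floor(n / 2)
  # phase e^{-2pi i (kx*x + ky*y)/N}; rows = y, cols = x
  ex <- exp(-2i * pi * outer(kx, idx) / n)  # n_samp x N over x
  ey <- exp(-2i * pi * outer(ky, idx) / n)  # n_samp x N over y
  # s_j = sum_y ey[j,y] * sum_x image[y,x] * ex[j,x]
  tmp <- ex %*% t(image)   # n_samp x N (over y)
  rowSums(tmp * ey)
}

#' Direct adjoint non-uniform DFT (exact, small grids)
#'
#' Exact conjugate-transpose of \code{\link{nudft_forward}}:
#' \eqn{I(x) = \sum_j s_j\,e^{+2\pi i k_j \cdot x / N}}.
#'
#' @param samples complex vector.
#' @param kx,ky sample coordinates in cycles/FOV.
#' @param n image matrix size (N, square grid, at most 64).
#' @return complex \code{N x N} matrix.
#' @export
nudft_adjoint <- function(samples, kx, ky, n) {
  if (n > 64) stop("grid larger than 64 x 64: use the fast gridding transform (nufft_plan/nufft_adjoint)")
  idx <- seq_len(n) - 1 - floor(n / 2)
  ex <- exp(2i * pi * outer(idx, kx) / n)  # N x n_samp, over x
  ey <- exp(2i * pi * outer(idx, ky) / n)  # N x n_samp, over y
  # I[y, x] = sum_j samples[j] * ey[y, j] * ex[x, j]
  ey %*% (samples * t(ex))
}

#' Plan a fast non-uniform FFT for a set of sample coordinates
#'
#' Kaiser-Bessel gridding NUFFT: the image is deapodized, zero-padded onto a
#' 2x oversampled Cartesian grid, FFT'd, and interpolated at the non-uniform
#' coordinates with a width-6 Kaiser-Bessel kernel (shape parameter from the
#' standard minimal-aliasing-error formula). The interpolation is stored as a
#' sparse matrix so forward and adjoint are exact conjugate transposes of one
#' another; relative accuracy against the direct NUDFT is ~1e-6.
#'
#' @param kx,ky sample coordinates in cycles/FOV.
#' @param n image matrix size N (square).
#' @param osf grid oversampling factor (default 2).
#' @param width kernel width in oversampled grid cells (default 6).
#' @return a plan object (list) for \code{\link{nufft_forward}} /
#'   \code{\link{nufft_adjoint}}.
#' @export
nufft_plan <- function(kx, ky, n, osf = 2, width = 6) {
  g <- as.integer(round(osf * n))
  beta <- pi * sqrt((width / osf)^2 * (osf - 0.5)^2 - 0.8)
  half <- width / 2
  ns <- length(kx)
  # fine-grid positions (grid spacing 1/osf cycles/FOV); fftshift convention:
  # fine-grid index m (0..g-1) carries frequency m cycles on the padded array
  px <- osf * kx
  py <- osf * ky
  offs <- seq_len(width) # kernel taps per dimension
  rows <- integer(0)
  # build triplets vectorized
  mx0 <- floor(px - half) # first tap (can be negative; wrap mod g)
  my0 <- floor(py - half)
  tapx <- outer(mx0, offs, "+")            # ns x width, integer grid coords
  tapy <- outer(my0, offs, "+")
  kbx <- .kb_kernel(tapx - px, half, beta) # ns x width
  kby <- .kb_kernel(tapy - py, half, beta)
  # combine into ns x width^2 weights and wrapped linear indices
  w2 <- array(0, dim = c(ns, width, width))
  lin <- array(0L, dim = c(ns, width, width))
  gx <- (tapx %% g)       # column index (x), 0-based
  gy <- (tapy %% g)       # row index (y), 0-based
  for (a in seq_len(width)) for (b in seq_len(width)) {
    w2[, a, b] <- kbx[, a] * kby[, b]
    lin[, a, b] <- gy[, b] + 1L + g * gx[, a]  # column-major [row=y, col=x]
  }
  P <- Matrix::sparseMatrix(
    i = rep(seq_len(ns), times = width * width),
    j = as.integer(lin),
    x = as.numeric(w2),
    dims = c(ns, g * g)
  )
  # deapodization on the N x N image grid (centered indices)
  idx <- seq_len(n) - 1 - floor(n / 2)
  apod1 <- .kb_ft(idx / g, half, beta)
  apod <- outer(apod1, apod1)  # [y, x]
  list(P = P, apod = apod, n = n, g = g, ns = ns, kx = kx, ky = ky)
}

# Kaiser-Bessel interpolation kernel, support |u| <= half (fine-grid cells)
.kb_kernel <- function(u, half, beta) {
  z <- 1 - (u / half)^2
  out <- numeric(length(u))
  ok <- z > 0
  out[ok] <- besselI(beta * sqrt(z[ok]), 0)
  dim(out) <- dim(u)
  out
}

# Continuous Fourier transform of .kb_kernel (deapodization); x in units of
# cycles per fine-grid cell (evaluate at pixel_index / g). True FT pair of
# the kernel above, so interpolation + deapodization carries no scale error.
.kb_ft <- function(x, half, beta) {
  arg <- beta^2 - (2 * pi * half * x)^2
  ifelse(arg > 0,
         2 * half * sinh(sqrt(pmax(arg, 0))) / sqrt(pmax(arg, 1e-300)),
         2 * half * sinc_c(sqrt(pmax(-arg, 0))))
}

sinc_c <- function(t) ifelse(t == 0, 1, sin(t) / t)

#' Fast NUFFT forward transform
#'
#' @param image complex \code{N x N} matrix (rows = y, cols = x).
#' @param plan from \code{\link{nufft_plan}}.
#' @return complex samples, same convention as \code{\link{nudft_forward}}.
#' @export
nufft_forward <- function(image, plan) {
  n <- plan$n; g <- plan$g
  a <- image / plan$apod
  big <- matrix(0 + 0i, g, g)
  idx <- ((seq_len(n) - 1 - floor(n / 2)) %% g) + 1L  # centered -> wrapped
  big[idx, idx] <- a
  K <- stats::fft(big)                 # K[m1+1, m2+1] = sum a e^{-2pi i (m.y + m.x)/g}
  v <- as.vector(K)
  # Matrix sparse products are real-valued: apply to Re and Im separately
  complex(real = as.vector(plan$P %*% Re(v)),
          imaginary = as.vector(plan$P %*% Im(v)))
}

#' Fast NUFFT adjoint transform
#'
#' Exact conjugate transpose of \code{\link{nufft_forward}}.
#'
#' @param samples complex vector.
#' @param plan from \code{\link{nufft_plan}}.
#' @return complex \code{N x N} image.
#' @export
nufft_adjoint <- function(samples, plan) {
  n <- plan$n; g <- plan$g
  K <- matrix(complex(
    real = as.vector(Matrix::crossprod(plan$P, Re(samples))),
    imaginary = as.vector(Matrix::crossprod(plan$P, Im(samples)))), g, g)
  big <- stats::fft(K, inverse = TRUE)  # unnormalized: adjoint of fft
  idx <- ((seq_len(n) - 1 - floor(n / 2)) %% g) + 1L
  big[idx, idx] / plan$apod
}
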