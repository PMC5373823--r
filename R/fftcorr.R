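# Low-level 2D cross-correlation sums via FFT.
#
# xcorr2_shift(A, B) returns S(d) = sum_p A(p) * B(p + d) for integer pixel
# displacements d. Non-periodic correlations zero-pad so that opposing edges
# never wrap; periodic correlations (Ising snapshots) use the raw FFT.
# Both analysis routes (direct pair counting and image FFT) and the mask
# edge correction are built on this one primitive, which keeps them exactly
# comparable.

xcorr2_shift <- function(A, B, max_shift, periodic = FALSE) {
  nx <- nrow(A); ny <- ncol(A)
  stopifnot(nrow(B) == nx, ncol(B) == ny)
  K <- as.integer(max_shift)
  if (periodic) {
    FA <- stats::fft(A); FB <- stats::fft(B)
    S <- Re(stats::fft(Conj(FA) * FB, inverse = TRUE)) / (nx * ny)
    px <- nx; py <- ny
    if (2 * K + 1 > min(nx, ny)) stop("max_shift too large for periodic grid")
  } else {
    px <- stats::nextn(nx + K, c(2, 3, 5))
    py <- stats::nextn(ny + K, c(2, 3, 5))
    Ap <- matrix(0, px, py); Ap[1:nx, 1:ny] <- A
    Bp <- matrix(0, px, py); Bp[1:nx, 1:ny] <- B
    FA <- stats::fft(Ap); FB <- stats::fft(Bp)
    S <- Re(stats::fft(Conj(FA) * FB, inverse = TRUE)) / (px * py)
  }
  # S index (i, j) holds displacement d = (i-1, j-1) modulo grid
  ix <- c(px - (K:1) + 1, 1:(K + 1))   # dx = -K..K
  iy <- c(py - (K:1) + 1, 1:(K + 1))
  out <- S[ix, iy]
  dimnames(out) <- NULL
  out
}

# Radial bin index (0-based) for integer pixel displacements.
# bin = floor(|d| * pixel_nm / dr_nm); identical formula in every route.
radial_bin_index <- function(K, pixel_nm, dr_nm) {
  d <- -K:K
  r <- sqrt(outer(d^2, d^2, "+")) * pixel_nm
  matrix(as.integer(floor(r / dr_nm + 1e-12)), 2 * K + 1, 2 * K + 1)
}

# Gaussian blur of a raster with a truncated (+-4 sigma) kernel, via
# zero-padded FFT convolution. sigma_px in pixels; sigma_px = 0 is identity.
blur_raster <- function(A, sigma_px, periodic = FALSE) {
  if (sigma_px <= 0) return(A)
  half <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(-half:half, sd = sigma_px)
  k <- k / sum(k)
  nx <- nrow(A); ny <- ncol(A)
  if (periodic) {
    kx <- numeric(nx); ix <- ((-half:half) %% nx) + 1
    for (i in seq_along(ix)) kx[ix[i]] <- kx[ix[i]] + k[i]
    ky <- numeric(ny); iy <- ((-half:half) %% ny) + 1
    for (i in seq_along(iy)) ky[iy[i]] <- ky[iy[i]] + k[i]
    Fk <- outer(stats::fft(kx), stats::fft(ky))
    out <- Re(stats::fft(stats::fft(A) * Fk, inverse = TRUE)) / (nx * ny)
  } else {
    px <- stats::nextn(nx + 2 * half, c(2, 3, 5))
    py <- stats::nextn(ny + 2 * half, c(2, 3, 5))
    Ap <- matrix(0, px, py); Ap[1:nx, 1:ny] <- A
    kxv <- numeric(px); kxv[((-half:half) %% px) + 1] <- k
    kyv <- numeric(py); kyv[((-half:half) %% py) + 1] <- k
    Fk <- outer(stats::fft(kxv), stats::fft(kyv))
    out <- Re(stats::fft(stats::fft(Ap) * Fk, inverse = TRUE)) / (px * py)
    out <- out[1:nx, 1:ny]
  }
  out
}
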