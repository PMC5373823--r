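#' @useDynLib smlmcorr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Shared correlation core.
#
# Pair counts are accumulated on the mask's pixel grid over integer
# displacements d, and the expected counts under a random co-distribution
# are computed from the mask raster's discrete autocorrelation M(d) (the
# number of in-mask pixel pairs at displacement d):
#
#   C(d) = X(d) * Npix^2 / (N1 * N2 * M(d)),
#
# with X(d) the cross pair count. Radial bins collect displacements by
# floor(|d| * pixel / dr); bin 0 is the "r < dr" bin. This discretization is
# shared verbatim by the direct pair-counting route and the FFT image
# route, which therefore agree to floating-point precision for any ROI
# shape. dC_raw is the standard error of the mean over the 2D C(d) values
# falling in each radial ring (undefined for rings with a single pixel,
# notably bin 0 when dr equals the pixel size).
corr_core_ <- function(X, M, N1, N2, npix, pixel_nm, dr_nm, r_max_nm,
                       sigma_psf_nm = 30, n1 = NA_real_, n2 = NA_real_,
                       area_um2 = NA_real_) {
  K <- (nrow(X) - 1) / 2
  nbins <- floor(r_max_nm / dr_nm)
  binidx <- radial_bin_index(K, pixel_nm, dr_nm)
  valid <- M > 0.5 & binidx < nbins
  c2d <- matrix(NA_real_, nrow(X), ncol(X))
  c2d[valid] <- X[valid] * npix^2 / (N1 * N2 * M[valid])
  f <- factor(binidx[valid], levels = 0:(nbins - 1))
  counts <- as.numeric(tapply(X[valid], f, sum, default = 0))
  expected <- as.numeric(tapply(M[valid], f, sum, default = 0)) *
    N1 * N2 / npix^2
  nring <- as.numeric(table(f))
  Cr <- ifelse(expected > 0, counts / expected, NA_real_)
  sdring <- as.numeric(tapply(c2d[valid], f, stats::sd))
  dC_raw <- ifelse(nring > 1, sdring / sqrt(nring), NA_real_)
  r_lo <- (0:(nbins - 1)) * dr_nm
  res <- structure(list(
    r_lo = r_lo, r_hi = r_lo + dr_nm, r_mid = r_lo + dr_nm / 2,
    counts = counts, expected = expected, C = Cr,
    dC_raw = dC_raw, dC1 = NULL, dC2 = NULL,
    c2d = c2d,
    meta = list(N1 = N1, N2 = N2, n1 = n1, n2 = n2, npix_mask = npix,
                area_um2 = area_um2, pixel_nm = pixel_nm, dr_nm = dr_nm,
                sigma_psf_nm = sigma_psf_nm, offset_subtracted = 0)),
    class = "corr_result")
  res$dC1 <- variance_dc1(res)$dC1
  res
}

check_rmax_ <- function(r_max_nm, mask) {
  ext <- min(dim(mask$mask)) * mask$pixel_nm
  if (r_max_nm > ext) {
    warning("r_max (", r_max_nm, " nm) exceeds the mask extent (", ext,
            " nm); truncated")
    r_max_nm <- ext
  }
  r_max_nm
}

#' Cross-correlation of two localization channels by direct pair counting
#'
#' Tabulates the histogram of pairwise channel-A to channel-B separations
#' on the ROI pixel grid and normalizes each radial bin by the pair count
#' expected for a random co-distribution at the same channel totals inside
#' the same mask. The edge correction uses the mask's spatial
#' autocorrelation, so a random co-distribution gives C(r) = 1 regardless
#' of ROI shape. By default ungrouped tables are used: cross-correlations
#' are unaffected by blinking overcounting, and skipping the grouping step
#' avoids its failure modes.
#'
#' @param locsA,locsB single-channel [loc_table()]s (non-empty).
#' @param mask a [roi_mask()].
#' @param dr_nm radial bin width (nm), default 25.
#' @param r_max_nm largest separation analyzed (nm).
#' @param sigma_psf_nm localization precision used by the variance model
#'   (nm), default 30.
#' @return a `corr_result` with bins, counts, expected counts, `C`,
#'   `dC_raw` and `dC1` (see [variance_dc1()]; [variance_dc2()] adds `dC2`
#'   once channel densities are known).
#' @export
crosscorr_direct <- function(locsA, locsB, mask, dr_nm = 25, r_max_nm = 1000,
                             sigma_psf_nm = 30) {
  if (nrow(locsA) == 0) stop("channel A is empty")
  if (nrow(locsB) == 0) stop("channel B is empty")
  stopifnot(inherits(mask, "roi_mask"))
  r_max_nm <- check_rmax_(r_max_nm, mask)
  p <- mask$pixel_nm
  K <- as.integer(ceiling(r_max_nm / p)) + 1L
  pix <- function(locs) {
    px <- floor((locs$x_nm - mask$origin_nm[1]) / p) + 1
    py <- floor((locs$y_nm - mask$origin_nm[2]) / p) + 1
    ok <- px >= 1 & px <= nrow(mask$mask) & py >= 1 & py <= ncol(mask$mask)
    ok[ok] <- mask$mask[cbind(px[ok], py[ok])]
    list(px = as.integer(px[ok]), py = as.integer(py[ok]))
  }
  A <- pix(locsA); B <- pix(locsB)
  if (length(A$px) == 0) stop("channel A has no localizations inside the mask")
  if (length(B$px) == 0) stop("channel B has no localizations inside the mask")
  X <- pair_disp_hist_cpp(A$px, A$py, B$px, B$py, K)
  M <- xcorr2_shift(mask$mask * 1, mask$mask * 1, K)
  corr_core_(X, M, length(A$px), length(B$px), sum(mask$mask), p, dr_nm,
             r_max_nm, sigma_psf_nm, area_um2 = mask_area_um2(mask))
}

#' Cross-correlation of two reconstructed images via FFT
#'
#' Computes the 2D cross-correlation of two masked count images by fast
#' Fourier transform, normalizes it by the mask autocorrelation and the
#' channel totals, and averages over angles to obtain C(r). Numerically
#' equivalent to [crosscorr_direct()] on the same binning; the FFT route is
#' preferred for large images.
#'
#' @param imgA,imgB `recon_image`s on the same grid (see
#'   [reconstruct_image()]).
#' @param mask the [roi_mask()] both images were reconstructed with.
#' @param dr_nm,r_max_nm,sigma_psf_nm as in [crosscorr_direct()].
#' @param periodic treat the grid as a torus (used for simulation
#'   snapshots); the mask must then be all-TRUE.
#' @return a `corr_result`; element `c2d` carries the full 2D C(r, theta).
#' @export
crosscorr_fft <- function(imgA, imgB, mask, dr_nm = 25, r_max_nm = 1000,
                          sigma_psf_nm = 30, periodic = FALSE) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!all(dim(imgA$counts) == dim(imgB$counts)) ||
      !all(dim(imgA$counts) == dim(mask$mask)) ||
      imgA$pixel_nm != imgB$pixel_nm)
    stop("images and mask must share one pixel grid")
  r_max_nm <- check_rmax_(r_max_nm, mask)
  p <- mask$pixel_nm
  K <- as.integer(ceiling(r_max_nm / p)) + 1L
  if (periodic && 2 * K + 1 > min(dim(mask$mask)))
    K <- (min(dim(mask$mask)) - 1) %/% 2
  A <- imgA$counts; B <- imgB$counts
  N1 <- sum(A); N2 <- sum(B)
  if (N1 == 0) stop("channel A image is empty")
  if (N2 == 0) stop("channel B image is empty")
  X <- xcorr2_shift(A, B, K, periodic = periodic)
  M <- xcorr2_shift(mask$mask * 1, mask$mask * 1, K, periodic = periodic)
  corr_core_(X, M, N1, N2, sum(mask$mask), p, dr_nm, r_max_nm,
             sigma_psf_nm, area_um2 = mask_area_um2(mask))
}

#' Autocorrelation of one channel (self-pairs excluded)
#'
#' Same machinery as [crosscorr_fft()] with both images equal; the trivial
#' self-pair contribution at zero displacement is removed before
#' normalization so that G(r) reflects only distinct-localization pairs.
#'
#' @inheritParams crosscorr_fft
#' @param img a `recon_image`.
#' @return a `corr_result` for G(r).
#' @export
autocorr_fft <- function(img, mask, dr_nm = 25, r_max_nm = 1000,
                         sigma_psf_nm = 30, periodic = FALSE) {
  stopifnot(inherits(mask, "roi_mask"))
  r_max_nm <- check_rmax_(r_max_nm, mask)
  p <- mask$pixel_nm
  K <- as.integer(ceiling(r_max_nm / p)) + 1L
  if (periodic && 2 * K + 1 > min(dim(mask$mask)))
    K <- (min(dim(mask$mask)) - 1) %/% 2
  A <- img$counts
  N <- sum(A)
  if (N == 0) stop("image is empty")
  X <- xcorr2_shift(A, A, K, periodic = periodic)
  X[K + 1, K + 1] <- X[K + 1, K + 1] - N   # remove self-pairs
  M <- xcorr2_shift(mask$mask * 1, mask$mask * 1, K, periodic = periodic)
  corr_core_(X, M, N, N, sum(mask$mask), p, dr_nm, r_max_nm, sigma_psf_nm,
             area_um2 = mask_area_um2(mask))
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf("<corr_result> %d bins, dr = %g nm, r < %g nm\n",
              length(x$C), x$meta$dr_nm, max(x$r_hi)))
  cat(sprintf("  N1 = %d, N2 = %d; C(first bin) = %.3f\n",
              x$meta$N1, x$meta$N2, x$C[1]))
  invisible(x)
}

#' Convert a correlation result to a data.frame
#' @param x a `corr_result`.
#' @param ... unused.
#' @return data.frame with r bins, counts, expected, C and variance columns.
#' @export
as.data.frame.corr_result <- function(x, ...) {
  data.frame(r_lo_nm = x$r_lo, r_mid_nm = x$r_mid, r_hi_nm = x$r_hi,
             counts = x$counts, expected = x$expected, C = x$C,
             dC_raw = x$dC_raw,
             dC1 = if (is.null(x$dC1)) NA_real_ else x$dC1,
             dC2 = if (is.null(x$dC2)) NA_real_ else x$dC2)
}

#' Write a correlation result as CSV plus JSON metadata
#' @param x a `corr_result`.
#' @param path CSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_corr <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  jsonlite::write_json(x$meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
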