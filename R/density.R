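#' Surface density from the autocorrelation of one channel
#'
#' A reversibly photoswitching fluorophore is localized many times, so the
#' raw localization density grossly overcounts the molecule density and the
#' single-channel autocorrelation G(r) is inflated at short r by
#' same-molecule localization pairs. When blinking is (approximately)
#' Poisson and molecules are near-randomly distributed, the area under
#' G(r) - 1 is inversely proportional to the true molecule surface density:
#' fitting G(r) = 1 + A exp(-r^2 / (2 sigma^2)) gives
#'
#'   rho = 1 / (2 pi sigma^2 A),
#'
#' independent of how many times each molecule was observed. Grouped
#' localizations are expected (grouping makes per-molecule sampling closer
#' to Poisson); for strongly self-clustered proteins the estimate is better
#' interpreted as the density of clusters, not of individual molecules.
#'
#' @param locs a grouped single-channel [loc_table()] (see
#'   [group_sequential()]); a warning is issued for ungrouped input.
#' @param mask a [roi_mask()].
#' @param fit_window_nm radial window for the Gaussian fit (nm); the
#'   zero-lag bin never enters. Default 50-500 nm.
#' @param dr_nm radial bin width, default 25 nm.
#' @return a `density_estimate`: list with `A` (amplitude), `sigma_nm`,
#'   `rho_um2` (molecules per um^2), `n_roi` (molecules in the ROI,
#'   `rho * area`), `n_locs`, `overcounting` (localizations per molecule)
#'   and the fit object.
#' @export
density_from_autocorr <- function(locs, mask, fit_window_nm = c(50, 500),
                                  dr_nm = 25) {
  stopifnot(inherits(locs, "loc_table"), inherits(mask, "roi_mask"))
  if (!isTRUE(attr(locs, "grouped")))
    warning("localizations do not appear to be grouped; ",
            "density estimates assume grouped input")
  img <- reconstruct_image(locs, mask, grouped = TRUE)
  r_max_nm <- fit_window_nm[2] + 2 * dr_nm
  ac <- autocorr_fft(img, mask, dr_nm = dr_nm, r_max_nm = r_max_nm)
  sel <- which(ac$r_mid >= fit_window_nm[1] & ac$r_mid <= fit_window_nm[2] &
                 is.finite(ac$C))
  if (length(sel) < 4) stop("fit window contains too few usable bins")
  # The binned G(r) is a mask-weighted average of the pair kernel over the
  # integer displacement pixels of each radial ring; fitting the Gaussian
  # evaluated at bin centers mis-states that average when sigma is
  # comparable to the pixel, so the model is ring-averaged explicitly.
  p <- mask$pixel_nm
  K <- as.integer(ceiling(r_max_nm / p)) + 1L
  M <- xcorr2_shift(mask$mask * 1, mask$mask * 1, K)
  binidx <- radial_bin_index(K, p, dr_nm)
  dvec <- -K:K
  d2 <- outer(dvec^2, dvec^2, "+") * p^2
  ring <- lapply(sel, function(k) {
    idx <- binidx == (k - 1L) & M > 0.5
    list(d2 = d2[idx], w = M[idx])
  })
  ring_mean <- function(sigma) {
    vapply(ring, function(rg)
      sum(rg$w * exp(-rg$d2 / (2 * sigma^2))) / sum(rg$w), numeric(1))
  }
  df <- data.frame(g = ac$C[sel] - 1)
  a0 <- max(df$g[1] / max(ring_mean(60)[1], 1e-6), 0.05)
  fit <- try(minpack.lm::nlsLM(
    g ~ A * ring_mean(sigma), data = df,
    start = list(A = a0, sigma = 60),
    lower = c(A = 1e-8, sigma = 1), upper = c(A = Inf, sigma = 2000),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("autocorrelation fit failed; distribution inconsistent with ",
         "near-random overcounted points")
  co <- stats::coef(fit)
  A <- unname(co["A"]); sigma <- unname(co["sigma"])
  if (A <= 1e-7)
    stop("fitted autocorrelation amplitude is not positive; ",
         "cannot estimate a density")
  rho_um2 <- 1 / (2 * pi * (sigma / 1000)^2 * A)
  area <- mask_area_um2(mask)
  structure(list(A = A, sigma_nm = sigma, rho_um2 = rho_um2,
                 n_roi = rho_um2 * area, n_locs = ac$meta$N1,
                 overcounting = ac$meta$N1 / (rho_um2 * area),
                 fit = fit, autocorr = ac),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf(paste0("<density_estimate> rho = %.2f um^-2 ",
                     "(A = %.3f, sigma = %.1f nm); ~%.1f obs/molecule\n"),
              x$rho_um2, x$A, x$sigma_nm, x$overcounting))
  invisible(x)
}
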