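#' Reconstruct a super-resolved count image from localizations
#'
#' Renders localizations onto the mask's pixel grid by incrementing the
#' pixel containing each localization (half-open bins
#' `[k*p, (k+1)*p)`). Out-of-mask localizations are excluded, so the raster
#' sum equals the number of in-mask localizations rendered.
#'
#' @param locs a [loc_table()] (typically a single channel).
#' @param mask a [roi_mask()] defining grid and ROI.
#' @param grouped logical flag recorded on the result: whether `locs` was
#'   grouped with [group_sequential()].
#' @return a `recon_image`: list with `counts` (matrix `[ix, iy]`),
#'   `pixel_nm`, `origin_nm`, `channel`, `grouped`, `n_locs`.
#' @export
reconstruct_image <- function(locs, mask, grouped = FALSE) {
  stopifnot(inherits(locs, "loc_table"), inherits(mask, "roi_mask"))
  nx <- nrow(mask$mask); ny <- ncol(mask$mask)
  counts <- matrix(0, nx, ny)
  if (nrow(locs) > 0) {
    px <- floor((locs$x_nm - mask$origin_nm[1]) / mask$pixel_nm) + 1
    py <- floor((locs$y_nm - mask$origin_nm[2]) / mask$pixel_nm) + 1
    ok <- px >= 1 & px <= nx & py >= 1 & py <= ny
    ok[ok] <- mask$mask[cbind(px[ok], py[ok])]
    if (any(ok)) {
      tab <- table(px[ok] + nx * (py[ok] - 1))
      idx <- as.integer(names(tab))
      counts[idx] <- as.numeric(tab)
    }
  }
  structure(list(counts = counts, pixel_nm = mask$pixel_nm,
                 origin_nm = mask$origin_nm,
                 channel = if (nrow(locs)) locs$channel[1] else NA_character_,
                 grouped = grouped, n_locs = sum(counts)),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> %d x %d px (%g nm/px), %d localizations%s\n",
              nrow(x$counts), ncol(x$counts), x$pixel_nm, x$n_locs,
              if (isTRUE(x$grouped)) ", grouped" else ""))
  invisible(x)
}
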