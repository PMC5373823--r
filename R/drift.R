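#' Correct stage drift from the localizations themselves
#'
#' Frames are split into consecutive blocks (default 500 frames). Each block
#' is reconstructed as a count raster, and the relative shift between
#' successive blocks is estimated as the argmax of their 2D
#' cross-correlation, refined to sub-pixel precision by a 3x3 parabolic fit
#' of the correlation peak. Per-block shifts are accumulated into a drift
#' trajectory, interpolated linearly between block midpoints (held constant
#' beyond the first/last midpoint), and subtracted from every localization.
#'
#' Blocks with fewer than `min_locs` localizations contribute no estimate;
#' their shift is interpolated from neighboring blocks with a warning.
#'
#' @param locs a [loc_table()] (all channels pooled for estimation).
#' @param block_frames block size in frames (default 500).
#' @param pixel_nm raster pixel for the block images (default 25 nm).
#' @param max_shift_nm largest drift searched between successive blocks.
#' @param min_locs minimum localizations for a usable block.
#' @return list with `locs` (drift-corrected `loc_table`), `trace`
#'   (data.frame `frame`, `dx_nm`, `dy_nm` for every frame present) and
#'   `block_shifts` (cumulative shift at each block midpoint).
#' @export
correct_drift <- function(locs, block_frames = 500, pixel_nm = 25,
                          max_shift_nm = 500, min_locs = 20) {
  stopifnot(inherits(locs, "loc_table"))
  if (nrow(locs) == 0) stop("empty localization table")
  fmin <- min(locs$frame); fmax <- max(locs$frame)
  nblock <- floor((fmax - fmin) / block_frames) + 1
  if (nblock < 2) stop("need at least 2 blocks of frames for drift estimation")
  bid <- floor((locs$frame - fmin) / block_frames) + 1

  x0 <- min(locs$x_nm); y0 <- min(locs$y_nm)
  nx <- floor((max(locs$x_nm) - x0) / pixel_nm) + 1
  ny <- floor((max(locs$y_nm) - y0) / pixel_nm) + 1
  rasters <- lapply(seq_len(nblock), function(b) {
    sel <- bid == b
    counts <- matrix(0, nx, ny)
    if (any(sel)) {
      px <- floor((locs$x_nm[sel] - x0) / pixel_nm) + 1
      py <- floor((locs$y_nm[sel] - y0) / pixel_nm) + 1
      tab <- table(px + nx * (py - 1))
      counts[as.integer(names(tab))] <- as.numeric(tab)
    }
    counts
  })
  nlocs_block <- tabulate(bid, nblock)

  K <- max(1L, ceiling(max_shift_nm / pixel_nm))
  step <- matrix(NA_real_, nblock, 2)  # shift of block b relative to b-1
  step[1, ] <- 0
  for (b in 2:nblock) {
    if (nlocs_block[b] < min_locs || nlocs_block[b - 1] < min_locs) next
    S <- xcorr2_shift(rasters[[b - 1]], rasters[[b]], max_shift = K)
    step[b, ] <- peak_subpixel_(S) * pixel_nm
  }
  bad <- which(is.na(step[, 1]))
  if (length(bad)) {
    warning(length(bad), " block step(s) had too few localizations; ",
            "interpolated from neighbors")
    for (j in 1:2) {
      v <- step[, j]
      ok <- which(!is.na(v))
      step[, j] <- stats::approx(ok, v[ok], xout = seq_len(nblock),
                                 rule = 2)$y
    }
  }
  cum <- apply(step, 2, cumsum)
  if (nblock == 2) cum <- matrix(cum, ncol = 2)
  mid <- fmin + (seq_len(nblock) - 0.5) * block_frames

  frames <- sort(unique(locs$frame))
  dx <- stats::approx(mid, cum[, 1], xout = frames, rule = 2)$y
  dy <- stats::approx(mid, cum[, 2], xout = frames, rule = 2)$y
  trace <- data.frame(frame = frames, dx_nm = dx, dy_nm = dy)

  idx <- match(locs$frame, frames)
  corrected <- locs
  corrected$x_nm <- locs$x_nm - dx[idx]
  corrected$y_nm <- locs$y_nm - dy[idx]
  list(locs = corrected, trace = trace,
       block_shifts = data.frame(frame_mid = mid,
                                 dx_nm = cum[, 1], dy_nm = cum[, 2]))
}

# Sub-pixel argmax by separable parabolic fit through the 3x3 neighborhood
# of the discrete correlation peak. S is indexed by displacement -K..K.
peak_subpixel_ <- function(S) {
  K <- (nrow(S) - 1) / 2
  w <- which(S == max(S), arr.ind = TRUE)[1, ]
  i <- w[1]; j <- w[2]
  dx <- i - K - 1; dy <- j - K - 1
  sub <- function(a, b) S[min(max(a, 1), nrow(S)), min(max(b, 1), ncol(S))]
  if (i > 1 && i < nrow(S)) {
    den <- sub(i - 1, j) - 2 * sub(i, j) + sub(i + 1, j)
    if (den < 0) dx <- dx + 0.5 * (sub(i - 1, j) - sub(i + 1, j)) / den
  }
  if (j > 1 && j < ncol(S)) {
    den <- sub(i, j - 1) - 2 * sub(i, j) + sub(i, j + 1)
    if (den < 0) dy <- dy + 0.5 * (sub(i, j - 1) - sub(i, j + 1)) / den
  }
  c(dx, dy)
}
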