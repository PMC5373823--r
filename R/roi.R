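#' Region-of-interest masks
#'
#' An ROI mask is a binary raster restricting analysis to a region of the
#' coverslip, e.g. the flat, attached part of a cell footprint. The mask
#' raster is stored as a logical matrix indexed `[ix, iy]`: element
#' `[i, j]` covers the half-open pixel
#' `x in [origin_x + (i-1)*p, origin_x + i*p)`, likewise in y, with
#' `p = pixel_nm`. All correlation normalizations in the package are
#' mask-aware, so arbitrarily shaped (including hole-punched) ROIs give
#' unbiased C(r).
#'
#' @param mask logical (or 0/1) matrix, `TRUE` inside the ROI.
#' @param pixel_nm raster pixel size in nm (default 25).
#' @param origin_nm length-2 numeric, nm coordinates of the lower-left
#'   corner of pixel `[1, 1]`.
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(mask, pixel_nm = 25, origin_nm = c(0, 0)) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (pixel_nm <= 0) stop("pixel_nm must be positive")
  if (sum(mask) == 0) stop("mask must contain at least one TRUE pixel")
  structure(list(mask = mask, pixel_nm = pixel_nm,
                 origin_nm = as.numeric(origin_nm)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d px at %g nm/px; area %.3f um^2\n",
              nrow(x$mask), ncol(x$mask), x$pixel_nm, mask_area_um2(x)))
  invisible(x)
}

#' Mask area in square micrometers
#' @param mask a [roi_mask()].
#' @return area in um^2.
#' @export
mask_area_um2 <- function(mask) {
  sum(mask$mask) * (mask$pixel_nm / 1000)^2
}

#' Rectangular mask covering a field of view
#'
#' With a nonzero `margin_nm` the mask covers only the interior of the
#' field, mirroring experimental practice: the analysis ROI is drawn inside
#' the labeled cell, away from its boundary, so probes also exist just
#' outside the ROI. For synthetic scenes this avoids the artificial
#' intensity taper at the field edge (molecules near the edge lose part of
#' their localization cloud), which otherwise injects a weak long-range
#' correlation shared by every channel.
#'
#' @param width_nm,height_nm field-of-view extent in nm.
#' @param pixel_nm raster pixel size (nm).
#' @param margin_nm border excluded on every side (nm, default 0).
#' @return a [roi_mask()] that is TRUE everywhere inside the margin.
#' @export
rect_mask <- function(width_nm, height_nm, pixel_nm = 25, margin_nm = 0) {
  mpx <- floor(margin_nm / pixel_nm)
  nx <- max(1L, ceiling(width_nm / pixel_nm)) - 2L * mpx
  ny <- max(1L, ceiling(height_nm / pixel_nm)) - 2L * mpx
  if (nx < 1 || ny < 1) stop("margin leaves no mask area")
  roi_mask(matrix(TRUE, nx, ny), pixel_nm = pixel_nm,
           origin_nm = c(mpx, mpx) * pixel_nm)
}

#' Test which localizations fall inside a mask
#' @param locs a [loc_table()].
#' @param mask a [roi_mask()].
#' @return logical vector, one element per localization.
#' @export
in_mask <- function(locs, mask) {
  px <- floor((locs$x_nm - mask$origin_nm[1]) / mask$pixel_nm) + 1
  py <- floor((locs$y_nm - mask$origin_nm[2]) / mask$pixel_nm) + 1
  ok <- px >= 1 & px <= nrow(mask$mask) & py >= 1 & py <= ncol(mask$mask)
  inside <- rep(FALSE, nrow(locs))
  inside[ok] <- mask$mask[cbind(px[ok], py[ok])]
  inside
}

#' Loose and tight masks around a membrane-topology defect
#'
#' Emulates a cell whose membrane has locally detached from the coverslip:
#' inside the detached "hole" no probes are visualized. Analyzing with a
#' loose ROI that still includes the hole makes the two channels spuriously
#' correlated at long distances (both are absent from the same region); a
#' tight ROI that excludes the hole restores a flat C(r) for random scenes.
#'
#' @param width_nm,height_nm field of view in nm.
#' @param hole `NULL` for no hole, else a list with `center_nm` (length 2)
#'   and `radius_nm`.
#' @param pixel_nm raster pixel size (nm).
#' @return list with elements `loose` and `tight`, both [roi_mask()]s.
#'   With no hole the two are identical.
#' @export
generate_topology_mask <- function(width_nm, height_nm, hole = NULL,
                                   pixel_nm = 25) {
  loose <- rect_mask(width_nm, height_nm, pixel_nm)
  if (is.null(hole)) return(list(loose = loose, tight = loose))
  cx <- hole$center_nm[1]; cy <- hole$center_nm[2]; r <- hole$radius_nm
  if (cx - r < 0 || cx + r > width_nm || cy - r < 0 || cy + r > height_nm)
    stop("hole must lie inside the field of view")
  xc <- (seq_len(nrow(loose$mask)) - 0.5) * pixel_nm
  yc <- (seq_len(ncol(loose$mask)) - 0.5) * pixel_nm
  d2 <- outer(xc, yc, function(x, y) (x - cx)^2 + (y - cy)^2)
  tightm <- loose$mask & (d2 > r^2)
  list(loose = loose, tight = roi_mask(tightm, pixel_nm))
}

#' Write a mask as a single-plane TIFF
#' @param mask a [roi_mask()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  # TIFF rasters are row-major from the top; transpose and flip y
  img <- t(mask$mask[, rev(seq_len(ncol(mask$mask))), drop = FALSE])
  tiff::writeTIFF(matrix(as.numeric(img), nrow(img), ncol(img)), path)
  invisible(path)
}

#' Read a mask from a single-plane TIFF
#' @param path TIFF path.
#' @param pixel_nm pixel size in nm to attach (TIFF carries none).
#' @param origin_nm origin to attach.
#' @return a [roi_mask()].
#' @export
read_mask <- function(path, pixel_nm = 25, origin_nm = c(0, 0)) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- t(img)[, rev(seq_len(nrow(img))), drop = FALSE]
  roi_mask(m > 0.5, pixel_nm = pixel_nm, origin_nm = origin_nm)
}
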