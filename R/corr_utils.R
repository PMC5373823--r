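#' Average correlation curves across cells
#'
#' Population curves are the unweighted per-bin mean of single-cell C(r)
#' curves; error bars are the standard error of the mean between cells.
#' With fewer than two cells the SEM is undefined and flagged.
#'
#' @param results list of `corr_result`s with identical binning.
#' @return list with `r_mid`, `C_mean`, `sem`, `n_cells`, and `per_cell`
#'   (bins x cells matrix of the individual curves).
#' @export
average_cells <- function(results) {
  if (!length(results)) stop("no correlation results supplied")
  r0 <- results[[1]]$r_mid
  for (res in results)
    if (length(res$r_mid) != length(r0) || any(res$r_mid != r0))
      stop("correlation results must share identical binning")
  per_cell <- vapply(results, function(r) r$C, numeric(length(r0)))
  per_cell <- matrix(per_cell, nrow = length(r0))
  C_mean <- rowMeans(per_cell, na.rm = TRUE)
  n <- length(results)
  if (n >= 2) {
    sem <- apply(per_cell, 1, stats::sd, na.rm = TRUE) / sqrt(n)
  } else {
    warning("only one cell: SEM undefined")
    sem <- rep(NA_real_, length(r0))
  }
  list(r_mid = r0, C_mean = C_mean, sem = sem, n_cells = n,
       per_cell = per_cell)
}

#' Subtract the long-distance offset of a correlation curve
#'
#' Long-range structure (e.g. density gradients across the footprint) can
#' hold C(r) slightly away from 1 even at large r. When that long-range
#' contribution is not under study it is removed by subtracting the mean
#' deviation from 1 over a user-chosen tail window; the adjustment is
#' recorded in the result metadata.
#'
#' @param x a `corr_result`.
#' @param tail_window_nm length-2 numeric: the r range whose mean defines
#'   the offset.
#' @return `x` with `C` shifted so the tail mean is 1.
#' @export
subtract_offset <- function(x, tail_window_nm) {
  stopifnot(inherits(x, "corr_result"))
  sel <- x$r_mid >= tail_window_nm[1] & x$r_mid <= tail_window_nm[2] &
    is.finite(x$C)
  if (!any(sel)) stop("tail window contains no usable bins")
  off <- mean(x$C[sel]) - 1
  x$C <- x$C - off
  x$meta$offset_subtracted <- x$meta$offset_subtracted + off
  x
}

#' Potential of mean force from a correlation curve
#'
#' The effective interaction free energy between the two labeled species
#' at separation r, in units of kB*T: PMF(r) = -ln C(r). C = 1 maps to 0
#' (no interaction), C > 1 to negative PMF (attraction), C < 1 to positive
#' PMF (repulsion). Bins with C <= 0 are masked with a warning.
#'
#' @param x a `corr_result` (or list with `r_mid` and `C`).
#' @return data.frame with `r_nm` and `pmf_kt`.
#' @export
pmf_from_corr <- function(x) {
  C <- x$C
  bad <- !is.finite(C) | C <= 0
  if (any(bad & is.finite(C)))
    warning(sum(bad & is.finite(C)), " bin(s) with C <= 0 masked out")
  pmf <- rep(NA_real_, length(C))
  pmf[!bad] <- -log(C[!bad])
  data.frame(r_nm = x$r_mid, pmf_kt = pmf)
}
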