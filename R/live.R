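#' Steady-state cross-correlation of a live-cell stream
#'
#' Frame-resolved localizations are cross-correlated for every frame pair
#' separated by at most `tau_max` frames. Over the short delay windows used
#' here the per-lag curves do not decay, so they are averaged (unweighted)
#' into one steady-state C(r). To remove long-range structure, e.g. the
#' edge-brightening caused by probes diffusing into the TIRF field, the
#' averaged curve is divided by the cross-correlation of the two channels'
#' masked average images after blurring with a sigma = 1 um Gaussian
#' (truncated at 4 sigma), which filters structure larger than ~1 um.
#'
#' @param locsA,locsB frame-resolved single-channel [loc_table()]s.
#' @param mask a [roi_mask()].
#' @param tau_max largest frame lag (default 50); truncated with a warning
#'   if the stream is shorter.
#' @param dr_nm,r_max_nm radial binning as in [crosscorr_direct()].
#' @param sigma_blur_nm blur for the normalization images (default 1000).
#' @return a `steadystate_corr`: list with `r_mid`, `C` (normalized
#'   steady-state curve), `C_tau` (bins x lags matrix before
#'   normalization), `C_tavg`, `C_norm` (the divisor curve), `tau_max`.
#' @export
steadystate_crosscorr <- function(locsA, locsB, mask, tau_max = 50,
                                  dr_nm = 25, r_max_nm = 1000,
                                  sigma_blur_nm = 1000) {
  stopifnot(inherits(locsA, "loc_table"), inherits(locsB, "loc_table"),
            inherits(mask, "roi_mask"))
  nfr <- max(locsA$frame, locsB$frame) + 1
  if (tau_max >= nfr) {
    warning("tau_max exceeds stream length; truncated to ", nfr - 1)
    tau_max <- nfr - 1
  }
  r_max_nm <- check_rmax_(r_max_nm, mask)
  p <- mask$pixel_nm
  K <- as.integer(ceiling(r_max_nm / p)) + 1L
  pix <- function(locs) {
    px <- floor((locs$x_nm - mask$origin_nm[1]) / p) + 1
    py <- floor((locs$y_nm - mask$origin_nm[2]) / p) + 1
    ok <- px >= 1 & px <= nrow(mask$mask) & py >= 1 & py <= ncol(mask$mask)
    ok[ok] <- mask$mask[cbind(px[ok], py[ok])]
    list(px = as.integer(px[ok]), py = as.integer(py[ok]),
         frame = as.integer(locs$frame[ok]))
  }
  A <- pix(locsA); B <- pix(locsB)
  if (!length(A$px) || !length(B$px)) stop("a channel is empty inside the mask")
  res <- tau_pair_hist_cpp(A$px, A$py, A$frame, B$px, B$py, B$frame,
                           as.integer(tau_max), K)
  M <- xcorr2_shift(mask$mask * 1, mask$mask * 1, K)
  npix <- sum(mask$mask)
  nbins <- floor(r_max_nm / dr_nm)
  binidx <- radial_bin_index(K, p, dr_nm)
  valid <- M > 0.5 & binidx < nbins
  f <- factor(binidx[valid], levels = 0:(nbins - 1))
  Mbin <- as.numeric(tapply(M[valid], f, sum, default = 0))
  C_tau <- matrix(NA_real_, nbins, tau_max + 1)
  for (tau in 0:tau_max) {
    X <- res$hist[[tau + 1]]
    cnt <- as.numeric(tapply(X[valid], f, sum, default = 0))
    expected <- res$npairs[tau + 1] * Mbin / npix^2
    C_tau[, tau + 1] <- ifelse(expected > 0, cnt / expected, NA_real_)
  }
  C_tavg <- rowMeans(C_tau)

  # normalization: cross-correlation of the blurred masked average images.
  # The blur is a normalized convolution (divided by the blurred mask) so
  # that ROI edges do not imprint an artificial shared taper.
  imgA <- reconstruct_image(locsA, mask)
  imgB <- reconstruct_image(locsB, mask)
  sig_px <- sigma_blur_nm / p
  wM <- blur_raster(mask$mask * 1, sig_px)
  wM[wM < 1e-9] <- 1
  blA <- imgA; blA$counts <- blur_raster(imgA$counts, sig_px) / wM * mask$mask
  blB <- imgB; blB$counts <- blur_raster(imgB$counts, sig_px) / wM * mask$mask
  norm <- crosscorr_fft(blA, blB, mask, dr_nm = dr_nm, r_max_nm = r_max_nm)
  C <- C_tavg / norm$C
  r_lo <- (0:(nbins - 1)) * dr_nm
  structure(list(r_lo = r_lo, r_mid = r_lo + dr_nm / 2, C = C,
                 C_tau = C_tau, C_tavg = C_tavg, C_norm = norm$C,
                 tau_max = tau_max,
                 meta = list(dr_nm = dr_nm, sigma_blur_nm = sigma_blur_nm,
                             N1 = length(A$px), N2 = length(B$px))),
            class = "steadystate_corr")
}

#' Link frame-resolved localizations into trajectories
#'
#' Greedy nearest-neighbor tracker: a trajectory head in frame t is linked
#' to a localization in frame t+1 only when exactly one candidate lies
#' within `max_step_nm` of the head and that candidate has no competing
#' head within the same radius. Any ambiguity (two candidates for one
#' head, or two heads for one candidate) terminates all trajectories
#' involved; the ambiguous localizations then seed new trajectories.
#'
#' @param locs single-channel frame-resolved [loc_table()].
#' @param max_step_nm linking radius, default 500 nm.
#' @return a `track_set`: data.frame with `track_id`, `frame`, `x_nm`,
#'   `y_nm` plus the linking radius as attribute `max_step_nm`.
#' @export
link_tracks <- function(locs, max_step_nm = 500) {
  stopifnot(inherits(locs, "loc_table"))
  if (length(unique(locs$channel)) > 1)
    stop("link_tracks expects a single channel")
  ord <- order(locs$frame)
  x <- locs$x_nm[ord]; y <- locs$y_nm[ord]; fr <- locs$frame[ord]
  frames <- sort(unique(fr))
  idx_by_frame <- split(seq_along(fr), fr)
  track_of <- integer(length(x))
  next_id <- 0L
  # active heads: localization index of each open trajectory's last point
  heads <- integer(0)
  head_frame <- integer(0)
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    cand <- idx_by_frame[[as.character(f)]]
    live <- head_frame == f - 1L
    open_heads <- heads[live]
    assigned <- rep(FALSE, length(cand))
    new_heads <- integer(0)
    if (length(open_heads) && length(cand)) {
      d2 <- outer(x[open_heads], x[cand], "-")^2 +
        outer(y[open_heads], y[cand], "-")^2
      within <- d2 <= max_step_nm^2
      n_cand_per_head <- rowSums(within)
      n_head_per_cand <- colSums(within)
      for (h in seq_along(open_heads)) {
        if (n_cand_per_head[h] != 1L) next           # 0 = ends, >1 = ambiguous
        ci <- which(within[h, ])
        if (n_head_per_cand[ci] != 1L) next          # competing heads
        j <- cand[ci]
        track_of[j] <- track_of[open_heads[h]]
        assigned[ci] <- TRUE
        new_heads <- c(new_heads, j)
      }
    }
    for (ci in which(!assigned)) {
      next_id <- next_id + 1L
      track_of[cand[ci]] <- next_id
      new_heads <- c(new_heads, cand[ci])
    }
    heads <- c(heads[!live], new_heads)
    head_frame <- c(head_frame[!live], rep(f, length(new_heads)))
  }
  out <- data.frame(track_id = track_of, frame = fr, x_nm = x, y_nm = y)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  attr(out, "max_step_nm") <- max_step_nm
  class(out) <- c("track_set", "data.frame")
  out
}

#' Per-frame step sizes of a track set
#'
#' @param tracks a [link_tracks()] result.
#' @return numeric vector of single-frame displacements (nm); its empirical
#'   cumulative distribution is the step-size distribution. Attribute
#'   `n_tracks` records the contributing trajectories.
#' @export
step_sizes <- function(tracks) {
  stopifnot(inherits(tracks, "track_set"))
  steps <- unlist(lapply(split(tracks, tracks$track_id), function(tr) {
    if (nrow(tr) < 2) return(numeric(0))
    keep <- diff(tr$frame) == 1L
    sqrt(diff(tr$x_nm)^2 + diff(tr$y_nm)^2)[keep]
  }), use.names = FALSE)
  attr(steps, "n_tracks") <- length(unique(tracks$track_id))
  steps
}

#' Mean squared displacement and diffusion coefficient of a track set
#'
#' MSD(lag) is averaged over all trajectory segments; a straight line
#' MSD = 4 D t + 4 sigma_loc^2 is fitted over the first `max_lag` lags,
#' which removes the static localization-noise offset from the slope.
#'
#' @param tracks a [link_tracks()] result.
#' @param dt_s frame interval (s).
#' @param max_lag largest lag (frames) used in the fit, default 4.
#' @return list with `msd` (data.frame lag, msd_nm2, n), `d_um2_s`, and
#'   `sigma_loc_nm` implied by the intercept (NA if negative).
#' @export
msd_diffusion <- function(tracks, dt_s, max_lag = 4) {
  stopifnot(inherits(tracks, "track_set"))
  by_tr <- split(tracks, tracks$track_id)
  msd <- vapply(seq_len(max_lag), function(lag) {
    acc <- 0; n <- 0
    for (tr in by_tr) {
      if (nrow(tr) <= lag) next
      i <- seq_len(nrow(tr) - lag)
      ok <- tr$frame[i + lag] - tr$frame[i] == lag
      if (!any(ok)) next
      acc <- acc + sum((tr$x_nm[i + lag] - tr$x_nm[i])[ok]^2 +
                         (tr$y_nm[i + lag] - tr$y_nm[i])[ok]^2)
      n <- n + sum(ok)
    }
    c(acc / max(n, 1), n)
  }, numeric(2))
  df <- data.frame(lag = seq_len(max_lag), msd_nm2 = msd[1, ], n = msd[2, ])
  fit <- stats::lm(msd_nm2 ~ lag, data = df, weights = df$n)
  slope <- unname(stats::coef(fit)[2])   # nm^2 per lag = 4 D dt
  icpt <- unname(stats::coef(fit)[1])    # 4 sigma^2
  list(msd = df, d_um2_s = slope / (4 * dt_s) * 1e-6,
       sigma_loc_nm = if (icpt > 0) sqrt(icpt / 4) else NA_real_)
}

#' Step sizes of probe localizations proximal to a reference channel
#'
#' Finds every trajectory point that lies within `radius_nm` of any
#' same-frame reference localization and collects the displacements from
#' that central point to the immediately preceding and following points of
#' its trajectory. Comparing this conditional step-size distribution to the
#' whole population's reveals whether probes near the reference structure
#' (e.g. clustered receptors) are slowed.
#'
#' @param tracks probe [link_tracks()] result.
#' @param locs_ref reference-channel [loc_table()] sharing the frame clock.
#' @param radius_nm proximity radius, default 100 nm.
#' @return numeric vector of step sizes (nm); attribute `n_central` counts
#'   proximal central localizations. Empty (with a message attribute) if no
#'   proximal instance exists.
#' @export
correlated_steps <- function(tracks, locs_ref, radius_nm = 100) {
  stopifnot(inherits(tracks, "track_set"), inherits(locs_ref, "loc_table"))
  ref_by_frame <- split(seq_len(nrow(locs_ref)), locs_ref$frame)
  steps <- numeric(0)
  n_central <- 0L
  for (tr in split(tracks, tracks$track_id)) {
    if (nrow(tr) < 2) next
    for (i in seq_len(nrow(tr))) {
      refs <- ref_by_frame[[as.character(tr$frame[i])]]
      if (is.null(refs)) next
      d2 <- (locs_ref$x_nm[refs] - tr$x_nm[i])^2 +
        (locs_ref$y_nm[refs] - tr$y_nm[i])^2
      if (min(d2) > radius_nm^2) next
      n_central <- n_central + 1L
      if (i > 1 && tr$frame[i] - tr$frame[i - 1] == 1L)
        steps <- c(steps, sqrt((tr$x_nm[i] - tr$x_nm[i - 1])^2 +
                                 (tr$y_nm[i] - tr$y_nm[i - 1])^2))
      if (i < nrow(tr) && tr$frame[i + 1] - tr$frame[i] == 1L)
        steps <- c(steps, sqrt((tr$x_nm[i + 1] - tr$x_nm[i])^2 +
                                 (tr$y_nm[i + 1] - tr$y_nm[i])^2))
    }
  }
  if (n_central == 0L)
    attr(steps, "note") <- "no probe localization proximal to the reference"
  attr(steps, "n_central") <- n_central
  steps
}
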