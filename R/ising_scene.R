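#' Sample an imaging scene from a lattice simulation state
#'
#' Bridges the simulator and the imaging analysis: channel 1 is the
#' receptor pixels (by default the clustered subset, i.e. receptors inside
#' the applied field disc, mirroring a labeled protein in a stabilized
#' domain; set `ch1 = "receptors"` for all of them, or `"ordered"` for the
#' ordered spin class), channel 2 is a random subset of one spin species
#' sampled at a finite probe density, emulating the sparse labeling of an
#' SMLM experiment. Optional Gaussian blur of sd `blur_sigma_nm` is applied
#' as a random displacement of each point, mimicking finite localization
#' precision (30 nm) or conventional diffraction-limited imaging (220 nm).
#' The fully sampled species raster is returned for oracle comparisons.
#'
#' @param state an `ising_state` (or snapshot with `spin`/`species`).
#' @param probe_density_um2 channel-2 sampling density (default 400 um^-2,
#'   about 100 points per 512 x 512 nm box).
#' @param blur_sigma_nm Gaussian displacement sd (nm); 0, 30 and 220 are
#'   the canonical settings.
#' @param ch1 `"clustered_receptors"`, `"receptors"` or `"ordered"`.
#' @param species2 spin class sampled in channel 2 (default
#'   `"disordered"`, whose short-range depletion around ordered proteins is
#'   the canonical readout; `"ordered"` gives the enrichment view).
#' @param seed integer seed.
#' @return list with `locs` (two-channel [loc_table()], channels `ch1`,
#'   `ch2`), `raster_ch1` and `raster_ch2_full` (full unblurred rasters),
#'   `pixel_nm`, and `box_nm` (lattice extent).
#' @export
sample_ising_scene <- function(state, probe_density_um2 = 400,
                               blur_sigma_nm = 0,
                               ch1 = c("clustered_receptors", "receptors",
                                       "ordered"),
                               species2 = c("disordered", "ordered"),
                               seed = NULL) {
  ch1 <- match.arg(ch1)
  species2 <- match.arg(species2)
  if (probe_density_um2 <= 0) stop("probe_density_um2 must be positive")
  if (!is.null(seed)) set.seed(seed)
  snap <- if (inherits(state, "ising_state"))
    list(spin = state$spin, species = state$species, field = state$field)
  else state
  L <- nrow(snap$spin)
  pixel_nm <- if (inherits(state, "ising_state"))
    state$params$pixel_nm else 2
  box_nm <- L * pixel_nm

  r1 <- species_raster_(snap, if (ch1 == "ordered") "ordered" else "receptor")
  if (ch1 == "clustered_receptors") {
    if (is.null(snap$field) || all(snap$field == 0))
      warning("no field on state; using all receptors as channel 1")
    else r1 <- r1 * (snap$field != 0)
  }
  r2full <- species_raster_(snap, species2)

  # channel-2 under-sampling: keep each species pixel independently with
  # the probability that matches the requested probe density
  p_keep <- min(1, probe_density_um2 * (pixel_nm / 1000)^2 *
                  L^2 / max(1, sum(r2full)))
  n_avail <- sum(r2full)
  n_target <- probe_density_um2 * (box_nm / 1000)^2
  if (n_target > n_avail)
    stop("probe density exceeds available species pixels")
  keep <- which(r2full > 0)[stats::runif(n_avail) < p_keep]

  centers <- function(idx) {
    cbind(((idx - 1) %% L + 0.5) * pixel_nm,
          ((idx - 1) %/% L + 0.5) * pixel_nm)
  }
  p1 <- centers(which(r1 > 0))
  p2 <- centers(keep)
  jitter <- function(p) {
    if (blur_sigma_nm > 0 && nrow(p) > 0) {
      p[, 1] <- (p[, 1] + stats::rnorm(nrow(p), 0, blur_sigma_nm)) %% box_nm
      p[, 2] <- (p[, 2] + stats::rnorm(nrow(p), 0, blur_sigma_nm)) %% box_nm
    }
    p
  }
  p1 <- jitter(p1); p2 <- jitter(p2)
  locs <- loc_table(c(p1[, 1], p2[, 1]), c(p1[, 2], p2[, 2]),
                    frame = 0L,
                    channel = rep(c("ch1", "ch2"), c(nrow(p1), nrow(p2))))
  list(locs = locs, raster_ch1 = r1, raster_ch2_full = r2full,
       pixel_nm = pixel_nm, box_nm = box_nm)
}

#' Periodic cross-correlation of two point sets on the lattice box
#'
#' Rasterizes two point channels onto the lattice grid (wrapping at the
#' box edge) and runs the standard FFT correlation with periodic
#' boundaries, as appropriate for simulation-derived scenes.
#'
#' @param locs two-channel [loc_table()] from [sample_ising_scene()], or a
#'   list of two rasters.
#' @param box_nm lattice extent (nm).
#' @param pixel_nm raster pixel (nm).
#' @param dr_nm,r_max_nm radial binning.
#' @return a `corr_result`.
#' @export
ising_scene_crosscorr <- function(locs, box_nm, pixel_nm = 2, dr_nm = 2,
                                  r_max_nm = 100) {
  L <- round(box_nm / pixel_nm)
  mask <- roi_mask(matrix(TRUE, L, L), pixel_nm = pixel_nm)
  rasterize <- function(x, y) {
    px <- floor((x %% box_nm) / pixel_nm) + 1
    py <- floor((y %% box_nm) / pixel_nm) + 1
    counts <- matrix(0, L, L)
    tab <- table(px + L * (py - 1))
    counts[as.integer(names(tab))] <- as.numeric(tab)
    counts
  }
  if (inherits(locs, "loc_table")) {
    chs <- unique(locs$channel)
    A <- rasterize(locs$x_nm[locs$channel == chs[1]],
                   locs$y_nm[locs$channel == chs[1]])
    B <- rasterize(locs$x_nm[locs$channel == chs[2]],
                   locs$y_nm[locs$channel == chs[2]])
  } else {
    A <- locs[[1]]; B <- locs[[2]]
  }
  imA <- structure(list(counts = A, pixel_nm = pixel_nm,
                        origin_nm = c(0, 0)), class = "recon_image")
  imB <- structure(list(counts = B, pixel_nm = pixel_nm,
                        origin_nm = c(0, 0)), class = "recon_image")
  crosscorr_fft(imA, imB, mask, dr_nm = dr_nm, r_max_nm = r_max_nm,
                periodic = TRUE)
}
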