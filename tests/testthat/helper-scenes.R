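# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so single test files stay in the seconds range.

small_random_scene <- function(seed, density = 15, fov = 4000) {
  generate_scene(scene_spec("random", fov_nm = c(fov, fov),
                            density_um2 = density), seed = seed)
}

small_cocluster_locs <- function(seed, fov = 4000) {
  sc <- generate_scene(scene_spec("co_clustered", fov_nm = c(fov, fov),
                                  n_discs = 8, disc_radius_nm = 50,
                                  mols_per_disc = 6), seed = seed)
  sample_localizations(sc, blink_model(mean_obs = 8, n_frames = 800,
                                       sigma_nm = 20), seed = seed + 1)
}

# O(N^2) reference pair correlation: bins pixelized displacements exactly
# like the production code but through an independent, elementary path.
brute_corr <- function(locsA, locsB, mask, dr_nm = 25, r_max_nm = 500) {
  p <- mask$pixel_nm
  pix <- function(l) {
    px <- floor((l$x_nm - mask$origin_nm[1]) / p) + 1
    py <- floor((l$y_nm - mask$origin_nm[2]) / p) + 1
    ok <- px >= 1 & px <= nrow(mask$mask) & py >= 1 & py <= ncol(mask$mask)
    ok[ok] <- mask$mask[cbind(px[ok], py[ok])]
    cbind(px[ok], py[ok])
  }
  A <- pix(locsA); B <- pix(locsB)
  nb <- floor(r_max_nm / dr_nm)
  counts <- numeric(nb)
  for (i in seq_len(nrow(A))) {
    d <- sqrt((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2) * p
    k <- floor(d / dr_nm) + 1
    k <- k[k <= nb]
    if (length(k)) {
      t <- tabulate(k, nb)
      counts <- counts + t
    }
  }
  # expected counts from the mask autocorrelation, independently by
  # brute force over mask pixel pairs (masks here are small)
  idx <- which(mask$mask, arr.ind = TRUE)
  expct <- numeric(nb)
  for (i in seq_len(nrow(idx))) {
    d <- sqrt((idx[, 1] - idx[i, 1])^2 + (idx[, 2] - idx[i, 2])^2) * p
    k <- floor(d / dr_nm) + 1
    k <- k[k <= nb]
    if (length(k)) expct <- expct + tabulate(k, nb)
  }
  expct <- expct * nrow(A) * nrow(B) / nrow(idx)^2
  list(counts = counts, expected = expct, C = counts / expct)
}
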