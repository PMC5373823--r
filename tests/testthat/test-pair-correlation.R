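test_that("direct pair counting matches an elementary O(N^2) oracle", {
  locs <- small_cocluster_locs(31)
  mask <- rect_mask(4000, 4000)
  la <- split_channel(locs, "ch1"); lb <- split_channel(locs, "ch2")
  got <- crosscorr_direct(la, lb, mask, dr_nm = 25, r_max_nm = 400)
  ref <- brute_corr(la, lb, mask, dr_nm = 25, r_max_nm = 400)
  expect_equal(got$counts, ref$counts)
  expect_equal(got$expected, ref$expected, tolerance = 1e-9)
  expect_equal(got$C, ref$C, tolerance = 1e-9)
  # co-clustering: enriched at short r, decaying toward 1
  expect_gt(got$C[1], 3)
  expect_lt(abs(mean(got$C[13:16]) - 1), 1)
})

test_that("direct and FFT routes agree to numerical precision", {
  locs <- small_cocluster_locs(32)
  masks <- generate_topology_mask(4000, 4000,
                                  hole = list(center_nm = c(2000, 2000),
                                              radius_nm = 400))
  la <- split_channel(locs, "ch1"); lb <- split_channel(locs, "ch2")
  for (mask in masks) {
    cd <- crosscorr_direct(la, lb, mask, r_max_nm = 600)
    cf <- crosscorr_fft(reconstruct_image(la, mask),
                        reconstruct_image(lb, mask), mask, r_max_nm = 600)
    ok <- is.finite(cd$C) & cd$expected > 0
    expect_lt(max(abs(cd$C[ok] - cf$C[ok]) / pmax(cf$C[ok], 1e-9)), 1e-6)
  }
})

test_that("identical channels give the discrete zero-lag closed form", {
  # N points duplicated into channel B, one per pixel: the first (r < dr)
  # bin holds only the zero displacement, so C = Npix_mask / N on the
  # shared pixel grid
  set.seed(40)
  mask <- rect_mask(2000, 2000)
  pix <- sample.int(6400, 100)
  x <- ((pix - 1) %% 80 + runif(100, 0.1, 0.9)) * 25
  y <- ((pix - 1) %/% 80 + runif(100, 0.1, 0.9)) * 25
  la <- loc_table(x, y, channel = "a")
  lb <- loc_table(x, y, channel = "b")
  cc <- crosscorr_direct(la, lb, mask, dr_nm = 25, r_max_nm = 300)
  expect_equal(cc$C[1], sum(mask$mask) / 100, tolerance = 1e-9)
})

test_that("flat images and random co-distributions normalize to C = 1", {
  mask <- rect_mask(2500, 2500)
  img <- structure(list(counts = matrix(4, 100, 100), pixel_nm = 25,
                        origin_nm = c(0, 0)), class = "recon_image")
  cc <- crosscorr_fft(img, img, mask, r_max_nm = 500)
  expect_true(all(abs(cc$C - 1) < 1e-9))
  # seeded random channels: C within 3 dC_raw of 1 nearly everywhere
  sc <- small_random_scene(41, density = 30)
  l <- sample_localizations(sc, blink_model(mean_obs = 10, n_frames = 2000,
                                            sigma_nm = 20), seed = 42)
  m2 <- rect_mask(4000, 4000, margin_nm = 100)
  cc2 <- crosscorr_fft(reconstruct_image(split_channel(l, "ch1"), m2),
                       reconstruct_image(split_channel(l, "ch2"), m2),
                       m2, r_max_nm = 500, sigma_psf_nm = 20)
  sel <- which(cc2$r_mid >= 25)
  z <- abs(cc2$C[sel] - 1) / cc2$dC1[sel]
  expect_lt(mean(z > 3), 0.02)
  # ROI shape invariance: a hole-punched mask stays flat too
  masks <- generate_topology_mask(4000, 4000,
                                  hole = list(center_nm = c(2000, 2000),
                                              radius_nm = 500))
  cc3 <- crosscorr_fft(reconstruct_image(split_channel(l, "ch1"), masks$tight),
                       reconstruct_image(split_channel(l, "ch2"), masks$tight),
                       masks$tight, r_max_nm = 500, sigma_psf_nm = 20)
  expect_lt(abs(mean(cc3$C[sel], na.rm = TRUE) - 1), 0.05)
})

test_that("membrane-topology holes fake long-range correlation under a loose ROI", {
  # both channels absent from the detached region: the loose ROI reports
  # C > 1 at large r, the tight ROI that excludes the hole does not
  sp <- scene_spec("random", fov_nm = c(5000, 5000), density_um2 = 40,
                   hole = list(center_nm = c(2500, 2500), radius_nm = 1100))
  sc <- generate_scene(sp, seed = 43)
  l <- sample_localizations(sc, blink_model(mean_obs = 10, n_frames = 2000,
                                            sigma_nm = 20), seed = 44)
  masks <- generate_topology_mask(5000, 5000,
                                  hole = list(center_nm = c(2500, 2500),
                                              radius_nm = 1100))
  band <- function(mask) {
    cc <- crosscorr_fft(reconstruct_image(split_channel(l, "ch1"), mask),
                        reconstruct_image(split_channel(l, "ch2"), mask),
                        mask, r_max_nm = 800, sigma_psf_nm = 20)
    mean(cc$C[cc$r_mid > 100 & cc$r_mid < 600])
  }
  expect_gt(band(masks$loose), 1.05)
  expect_lt(abs(band(masks$tight) - 1), 0.04)
  expect_gt(band(masks$loose) - band(masks$tight), 0.04)
})

test_that("overcounting leaves the cross-correlation unchanged", {
  locs <- small_cocluster_locs(45)
  mask <- rect_mask(4000, 4000)
  la <- split_channel(locs, "ch1"); lb <- split_channel(locs, "ch2")
  cc1 <- crosscorr_direct(la, lb, mask, r_max_nm = 400)
  dup <- function(l, k) loc_table(rep(l$x_nm, k), rep(l$y_nm, k),
                                  rep(l$frame, k), l$channel[1])
  cc3 <- crosscorr_direct(dup(la, 3), dup(lb, 2), mask, r_max_nm = 400)
  expect_equal(cc3$C, cc1$C, tolerance = 1e-12)
})

test_that("variance corrections implement the printed factors", {
  # large-r factor (1 + 2*30/25) = 3.4; doubled at r = 0
  expect_equal(variance_dc1(1, sigma_psf_nm = 30, dr_nm = 25,
                            r_mid_nm = 1e6), 3.4)
  expect_equal(variance_dc1(1, sigma_psf_nm = 30, dr_nm = 25, r_mid_nm = 0),
               6.8)
  # sigma = 0: no correction away from r = 0
  expect_equal(variance_dc1(c(1, 1), sigma_psf_nm = 0, dr_nm = 25,
                            r_mid_nm = c(12.5, 37.5)), c(1, 1))
  # explicit Eq evaluation at a bin center
  r <- 62.5
  expect_equal(variance_dc1(2, sigma_psf_nm = 30, dr_nm = 25, r_mid_nm = r),
               2 * 3.4 * (1 + exp(-r^2 / (4 * 30^2))))
})

test_that("dC2 reduces to dC1 under heavy oversampling and needs densities", {
  locs <- small_cocluster_locs(46)
  mask <- rect_mask(4000, 4000)
  cc <- crosscorr_direct(split_channel(locs, "ch1"),
                         split_channel(locs, "ch2"), mask, r_max_nm = 400)
  expect_error(variance_dc2(cc), "density")
  # huge N^2/n: correction term vanishes
  cc2 <- variance_dc2(cc, n1 = 1e-6, n2 = 1e-6)
  expect_equal(cc2$dC2, cc2$dC1, tolerance = 1e-4)
  # explicit subtraction formula at moderate sampling
  cc3 <- variance_dc2(cc, n1 = 50, n2 = 50)
  s <- cc$meta$sigma_psf_nm
  term <- (4 * pi * s^2 / 25^2) /
    (cc$meta$N1^2 / 50 + cc$meta$N2^2 / 50) *
    (1 + 4 * exp(-cc$r_mid^2 / (4 * s^2)))
  expect_equal(cc3$dC2[-1], pmax(cc3$dC1[-1] - term[-1], 0))
})

test_that("density estimation inverts overcounting for random scenes", {
  mask <- rect_mask(8000, 8000, margin_nm = 150)
  est <- sapply(47:48, function(s) {
    sc <- generate_scene(scene_spec("random", fov_nm = c(8000, 8000),
                                    density_um2 = 10), seed = s)
    l <- sample_localizations(sc, blink_model(mean_obs = 20, n_frames = 5000,
                                              sigma_nm = 30), seed = s + 10)
    g <- group_sequential(split_channel(l, "ch1"))
    density_from_autocorr(g, mask)$rho_um2
  })
  expect_lt(abs(mean(est) / 10 - 1), 0.15)
  sc <- generate_scene(scene_spec("random", fov_nm = c(8000, 8000),
                                  density_um2 = 10), seed = 47)
  l <- sample_localizations(sc, blink_model(mean_obs = 20, n_frames = 5000,
                                            sigma_nm = 30), seed = 57)
  g <- group_sequential(split_channel(l, "ch1"))
  d1 <- density_from_autocorr(g, mask)
  expect_equal(d1$rho_um2, 1 / (2 * pi * (d1$sigma_nm / 1000)^2 * d1$A))
  expect_warning(density_from_autocorr(split_channel(l, "ch1"), mask),
                 "grouped")
})

test_that("cell averaging, offset subtraction and PMF behave arithmetically", {
  locs <- small_cocluster_locs(49)
  mask <- rect_mask(4000, 4000)
  cc <- crosscorr_direct(split_channel(locs, "ch1"),
                         split_channel(locs, "ch2"), mask, r_max_nm = 400)
  # identical curves: SEM exactly zero
  avg <- average_cells(list(cc, cc, cc))
  expect_equal(avg$C_mean, cc$C)
  expect_true(all(avg$sem == 0))
  expect_warning(a1 <- average_cells(list(cc)), "SEM undefined")
  expect_true(all(is.na(a1$sem)))
  # two synthetic curves {1, 2}: mean 1.5, SEM 0.5
  mk <- function(v) { r <- cc; r$C <- rep(v, length(cc$C)); r }
  avg2 <- average_cells(list(mk(1), mk(2)))
  expect_equal(unique(avg2$C_mean), 1.5)
  expect_equal(unique(avg2$sem), 0.5)
  # offset subtraction: flat 1.1 -> exactly 1; flat 1 unchanged
  off <- subtract_offset(mk(1.1), c(200, 400))
  expect_equal(unique(off$C), 1)
  expect_equal(off$meta$offset_subtracted, 0.1)
  expect_identical(subtract_offset(mk(1), c(200, 400))$C, mk(1)$C)
  expect_error(subtract_offset(mk(1), c(1e5, 2e5)), "tail window")
  # PMF closed forms
  pm <- pmf_from_corr(mk(exp(1)))
  expect_equal(unique(pm$pmf_kt), -1)
  expect_equal(unique(pmf_from_corr(mk(1))$pmf_kt), 0)
  expect_equal(unique(pmf_from_corr(mk(0.5))$pmf_kt), log(2))
  bad <- mk(1); bad$C[3] <- -0.2
  expect_warning(pmb <- pmf_from_corr(bad), "masked")
  expect_true(is.na(pmb$pmf_kt[3]))
})

test_that("clustered-both-independent scenes cross-correlate flat", {
  # both channels self-clustered but on independent disc sets: the
  # cross-correlation carries no signal once averaged over scenes
  mask <- rect_mask(6000, 6000, margin_nm = 200)
  curves <- sapply(1:8, function(s) {
    sc <- generate_scene(scene_spec("clustered_both_independent",
                                    fov_nm = c(6000, 6000), n_discs = 20,
                                    disc_radius_nm = 60, mols_per_disc = 8),
                         seed = 50 + s)
    l <- sample_localizations(sc, blink_model(mean_obs = 10, n_frames = 2000,
                                              sigma_nm = 20), seed = 70 + s)
    crosscorr_fft(reconstruct_image(split_channel(l, "ch1"), mask),
                  reconstruct_image(split_channel(l, "ch2"), mask),
                  mask, r_max_nm = 500, sigma_psf_nm = 20)$C
  })
  m <- rowMeans(curves)[-1]
  sem <- apply(curves, 1, sd)[-1] / sqrt(ncol(curves))
  z <- abs(m - 1) / sem
  expect_lt(mean(z > 3), 0.15)
  expect_lt(abs(mean(m) - 1), 0.1)
})
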