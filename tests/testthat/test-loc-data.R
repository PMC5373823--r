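test_that("localization tables validate and sort canonically", {
  lt <- loc_table(c(3, 1, 2), c(1, 2, 3), frame = c(5L, 2L, 9L),
                  channel = c("b", "a", "a"))
  expect_s3_class(lt, "loc_table")
  expect_equal(lt$channel, c("a", "a", "b"))
  expect_equal(lt$frame, c(2L, 9L, 5L))
  # sorting is idempotent
  lt2 <- loc_table(lt$x_nm, lt$y_nm, lt$frame, lt$channel)
  expect_identical(lt2$x_nm, lt$x_nm)
  expect_error(loc_table(c(1, NA), c(1, 2)), "finite")
  expect_error(loc_table(1, 1, frame = -1L), "non-negative")
})

test_that("native CSV round-trips and ThunderSTORM dialect converts units", {
  lt <- loc_table(runif(50, 0, 2000), runif(50, 0, 2000),
                  frame = sample(0:99, 50, TRUE),
                  channel = sample(c("ch1", "ch2"), 50, TRUE),
                  sigma_nm = 25)
  f <- tempfile(fileext = ".csv")
  write_localizations(lt, f)
  back <- read_localizations(f)
  expect_equal(back$x_nm, lt$x_nm, tolerance = 1e-12)
  expect_equal(back$channel, lt$channel)

  # ThunderSTORM-style export in micrometers
  f2 <- tempfile(fileext = ".csv")
  df <- data.frame(check.names = FALSE,
                   "x [um]" = c(1.5, 0.25), "y [um]" = c(0.5, 2),
                   frame = c(0L, 3L))
  write.csv(df, f2, row.names = FALSE)
  ts <- read_localizations(f2, dialect = "thunderstorm")
  expect_equal(ts$x_nm, c(1500, 250))
  expect_equal(ts$y_nm, c(500, 2000))

  # empty file: empty table plus a warning
  f3 <- tempfile(fileext = ".csv")
  writeLines("x_nm,y_nm,frame,channel", f3)
  expect_warning(e <- read_localizations(f3), "empty")
  expect_equal(nrow(e), 0)

  # missing columns is a format error
  f4 <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), f4, row.names = FALSE)
  expect_error(read_localizations(f4), "missing columns")
})

test_that("sequential-frame grouping merges bursts but not re-activations", {
  # same position, consecutive frames: one localization
  lt <- loc_table(c(100, 100), c(100, 100), frame = c(5L, 6L))
  g <- group_sequential(lt)
  expect_equal(nrow(g), 1)
  expect_equal(g$frame, 5L)
  # a frame gap keeps them separate
  lt2 <- loc_table(c(100, 100), c(100, 100), frame = c(5L, 7L))
  expect_equal(nrow(group_sequential(lt2)), 2)
  # beyond the radius in consecutive frames: separate
  lt3 <- loc_table(c(100, 300), c(100, 100), frame = c(5L, 6L))
  expect_equal(nrow(group_sequential(lt3)), 2)
  # 15-frame burst within the radius collapses to one localization
  set.seed(4)
  lt4 <- loc_table(100 + rnorm(15, 0, 10), 200 + rnorm(15, 0, 10),
                   frame = 10:24, molecule_id = 7L)
  g4 <- group_sequential(lt4)
  expect_equal(nrow(g4), 1)
  expect_equal(g4$molecule_id, 7L)
  expect_equal(g4$x_nm, mean(lt4$x_nm))
  # idempotence
  expect_identical(group_sequential(g4), g4)
  expect_error(group_sequential(lt, radius_nm = 0), "positive")
})

test_that("grouping recovers molecule counts from bursty synthetic data", {
  sc <- small_random_scene(11, density = 5)
  locs <- sample_localizations(
    sc, blink_model(mean_obs = 12, n_frames = 3000, sigma_nm = 15,
                    burst_len = 6), seed = 12)
  ch <- split_channel(locs, "ch1")
  g <- group_sequential(ch)
  n_true <- length(unique(ch$molecule_id))
  # grouped count approaches the burst count, far below raw localizations
  expect_lt(nrow(g), 0.4 * nrow(ch))
  expect_gt(nrow(g), n_true)     # separated re-activations stay distinct
  # every grouped localization maps to a real molecule
  expect_true(all(g$molecule_id %in% ch$molecule_id))
})

test_that("reconstruction conserves in-mask counts", {
  mask <- rect_mask(1000, 1000, pixel_nm = 25)
  # one localization at a pixel center
  img <- reconstruct_image(loc_table(112.5, 37.5), mask)
  expect_equal(sum(img$counts), 1)
  expect_equal(img$counts[5, 2], 1)
  # two in the same pixel add up
  img2 <- reconstruct_image(loc_table(c(112, 113), c(37, 38)), mask)
  expect_equal(max(img2$counts), 2)
  # uniform cloud: sum equals count, out-of-mask dropped
  set.seed(1)
  lt <- loc_table(runif(1000, -50, 1050), runif(1000, -50, 1050))
  img3 <- reconstruct_image(lt, mask)
  expect_equal(sum(img3$counts), sum(in_mask(lt, mask)))
})

test_that("masks are half-open rasters with working TIFF round-trip", {
  masks <- generate_topology_mask(2000, 2000, hole = list(
    center_nm = c(1000, 1000), radius_nm = 300))
  expect_lt(mask_area_um2(masks$tight), mask_area_um2(masks$loose))
  # hole center excluded from tight, included in loose
  ctr <- loc_table(1000, 1000)
  expect_false(in_mask(ctr, masks$tight))
  expect_true(in_mask(ctr, masks$loose))
  # no hole: identical masks
  m2 <- generate_topology_mask(2000, 2000)
  expect_identical(m2$loose, m2$tight)
  expect_error(generate_topology_mask(2000, 2000,
    hole = list(center_nm = c(100, 100), radius_nm = 300)), "inside")
  f <- tempfile(fileext = ".tif")
  write_mask(masks$tight, f)
  back <- read_mask(f)
  expect_identical(back$mask, masks$tight$mask)
})

test_that("drift correction recovers injected drift and is shift-equivariant", {
  sc <- generate_scene(scene_spec("random", fov_nm = c(6000, 6000),
                                  density_um2 = 30), seed = 21)
  l <- sample_localizations(sc, blink_model(mean_obs = 15, n_frames = 4000,
                                            sigma_nm = 20), seed = 22)
  # zero drift: recovered block shifts stay near (0, 0)
  z <- correct_drift(l, block_frames = 500)
  expect_lt(max(abs(as.matrix(z$block_shifts[, 2:3]))), 20)

  # linear drift of (60, -40) nm across the stream, recovered within a pixel
  ld <- l
  ld$x_nm <- l$x_nm + 60 * l$frame / max(l$frame)
  ld$y_nm <- l$y_nm - 40 * l$frame / max(l$frame)
  res <- correct_drift(ld, block_frames = 500)
  got <- unlist(res$block_shifts[nrow(res$block_shifts), 2:3])
  frac <- (res$block_shifts$frame_mid[nrow(res$block_shifts)]) / max(l$frame)
  expect_lt(max(abs(got - c(60, -40) * frac)), 25)
  resid <- sqrt((res$locs$x_nm - l$x_nm)^2 + (res$locs$y_nm - l$y_nm)^2)
  expect_lt(mean(resid), 15)

  # translating every localization by a constant changes nothing recovered
  lt <- ld
  lt$x_nm <- lt$x_nm + 1000
  res2 <- correct_drift(lt, block_frames = 500)
  expect_equal(res2$block_shifts$dx_nm, res$block_shifts$dx_nm,
               tolerance = 1e-6)
  expect_error(correct_drift(loc_table(1, 1, frame = 0L)), "2 blocks")
})
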