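test_that("pole intensity background subtraction matches direct arithmetic", {
  # uniform image: pole equals background, value 0
  z <- matrix(10, 40, 50)
  large <- matrix(TRUE, 40, 50)
  poles <- matrix(FALSE, 40, 50); poles[15:24, 10:19] <- TRUE
  expect_equal(pole_intensity(z, large, poles)$value, 0)

  # constructed case: background 10/px over N1 = 1000, poles 25/px over
  # N2 = 100 -> b = 10, per-pixel value 15
  z2 <- matrix(10, 20, 50)
  p2 <- matrix(FALSE, 20, 50); p2[1:10, 1:10] <- TRUE
  z2[p2] <- 25
  m <- pole_intensity(z2, matrix(TRUE, 20, 50), p2)
  expect_equal(m$N1, 1000L)
  expect_equal(m$N2, 100L)
  expect_equal(m$background, 10)
  expect_equal(m$value, 15)
  # literal difference form, for comparison
  lit <- pole_intensity(z2, matrix(TRUE, 20, 50), p2, per_pixel = FALSE)
  expect_equal(lit$value, 2500 - 10)
})

test_that("pole intensity is invariant to adding a constant to the image", {
  set.seed(17)
  z <- matrix(rnorm(2000, 50, 5), 40, 50)
  large <- matrix(FALSE, 40, 50); large[5:36, 5:46] <- TRUE
  poles <- matrix(FALSE, 40, 50); poles[18:23, 8:13] <- TRUE
  v1 <- pole_intensity(z, large, poles)$value
  v2 <- pole_intensity(z + 123.4, large, poles)$value
  expect_equal(v1, v2)
})

test_that("pole intensity validates its masks", {
  z <- matrix(1, 10, 10)
  all_true <- matrix(TRUE, 10, 10)
  outside <- matrix(FALSE, 10, 10); outside[1, 1] <- TRUE
  small <- matrix(FALSE, 10, 10); small[5, 5] <- TRUE
  restricted <- !outside
  expect_error(pole_intensity(z, restricted, outside), "inside")
  expect_error(pole_intensity(z, all_true, matrix(FALSE, 10, 10)), "empty")
  expect_error(pole_intensity(z, small, small), "N1 > N2")
})

test_that("measured pole amplitude recovers the generator's ground truth", {
  cfg <- image_sim_config(pole_enrichment = 2, noise_sd = 0)
  img <- gen_spindle_image(cfg)
  z <- img$channels$tubulin
  # small discs at the true poles vs a large ROI over the whole image
  disc <- function(cx, cy, r) {
    xs <- matrix(seq_len(ncol(z)), nrow(z), ncol(z), byrow = TRUE)
    ys <- matrix(seq_len(nrow(z)), nrow(z), ncol(z))
    (xs - cx)^2 + (ys - cy)^2 <= r^2
  }
  pole_mask <- disc(img$poles[1, 1], img$poles[1, 2], 3) |
               disc(img$poles[2, 1], img$poles[2, 2], 3)
  got <- pole_intensity(img, matrix(TRUE, nrow(z), ncol(z)), pole_mask)
  # true pole amplitude above cytosol: amplitude * enrichment, less the
  # spindle-interior signal counted as background by the large ROI
  expect_gt(got$value, 0.8 * cfg$amplitude * (cfg$pole_enrichment - 1))
  expect_lt(abs(got$value - cfg$amplitude * cfg$pole_enrichment +
                  got$background - cfg$background),
            0.35 * cfg$amplitude * cfg$pole_enrichment)
})

test_that("chromosome spread handles point masses and excludes small blobs", {
  # single tight blob: near-zero spread
  z <- matrix(0, 60, 150)
  z[30, 75] <- 100
  img <- image_from_matrix(z, name = "chromosomes")
  expect_equal(chromosome_spread(img, threshold = "half_max"), 0)

  # 4th-chromosome proxy: excluding the small blob shrinks the spread
  cfg <- image_sim_config(chromosome_spread = 6, include_fourth = TRUE,
                          noise_sd = 0)
  img4 <- gen_spindle_image(cfg)
  with4 <- chromosome_spread(img4, exclude_smallest = FALSE)
  without4 <- chromosome_spread(img4, exclude_smallest = TRUE)
  expect_gt(with4, without4)
  expect_equal(without4, 6, tolerance = 0.1)

  expect_error(
    chromosome_spread(image_from_matrix(matrix(1, 20, 20), margin_px = 4,
                                        name = "chromosomes")),
    "no chromosome signal")
})

test_that("wild-type-like spreads stay under 8 um while congression-defective ones exceed it", {
  wt <- gen_spindle_image(image_sim_config(chromosome_spread = 4,
                                           noise_sd = 0.05, seed = 31))
  defect <- gen_spindle_image(image_sim_config(chromosome_spread = 10,
                                               noise_sd = 0.05, seed = 32))
  expect_lte(chromosome_spread(wt), 8)
  expect_gt(chromosome_spread(defect), 8)
})

test_that("chromosome spread is invariant to rotating image and axis together", {
  cfg <- image_sim_config(chromosome_spread = 7, noise_sd = 0.02, seed = 5)
  img <- gen_spindle_image(cfg)
  # rotate 90 degrees: new[x, y] = old[y, x] with axes swapped
  rot <- spindle_image(
    lapply(img$channels, t),
    pixel_size = img$pixel_size,
    poles = img$poles[, 2:1],
    provenance = img$provenance)
  expect_equal(chromosome_spread(rot), chromosome_spread(img))
})

test_that("congression correlation obeys its exact identities", {
  d <- tibble::tibble(pole_intensity = exp(seq(1, 3, length.out = 10)),
                      spread_um = -seq(1, 3, length.out = 10) + 10)
  res <- congression_correlation(d)
  expect_equal(res$r, -1)
  expect_equal(res$n, 10L)

  # Pearson r is invariant to the log base
  set.seed(23)
  d2 <- gen_congression_dataset(n = 26, seed = 23)
  r_e <- congression_correlation(d2)$r
  r_10 <- unname(stats::cor.test(d2$spread_um,
                                 log10(d2$pole_intensity))$estimate)
  expect_equal(r_e, r_10)

  expect_error(congression_correlation(d[1:2, ]), "3 records")
  d_bad <- d; d_bad$pole_intensity[1] <- 0
  expect_error(congression_correlation(d_bad), "> 0")
  d_const <- d; d_const$spread_um <- 5
  expect_error(congression_correlation(d_const), "variance")
})

test_that("the correlation sign tracks any monotone-decreasing generator", {
  set.seed(29)
  for (slope in -c(0.3, 0.8, 1.5, 3)) {
    d <- gen_congression_dataset(n = 40, slope = slope,
                                 noise_sd = 0.3, seed = sample.int(1e6, 1))
    expect_lt(congression_correlation(d)$r, 0)
  }
})
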