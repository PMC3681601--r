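test_that("maximum projection equals the per-pixel brute-force maximum", {
  a <- matrix(1:6, 2)
  expect_identical(max_project(list(a)), a)
  expect_equal(max_project(list(a, matrix(0, 2, 3))), a,
               ignore_attr = FALSE)

  set.seed(13)
  stack <- lapply(1:3, function(i) matrix(runif(30), 5))
  proj <- max_project(stack)
  for (r in 1:5) for (c in 1:6)
    expect_identical(proj[r, c], max(stack[[1]][r, c], stack[[2]][r, c],
                                     stack[[3]][r, c]))
  expect_error(max_project(list()), "at least one")
  expect_error(max_project(list(a, matrix(0, 3, 3))), "same dimensions")
})

test_that("line profiles reproduce constant and linear-gradient images", {
  const <- image_from_matrix(matrix(7, 40, 120))
  prof <- extract_line_profile(const)
  expect_true(all(abs(prof$intensity - 7) < 1e-12))

  grad <- image_from_matrix(matrix(rep(seq_len(120), each = 40), 40))
  pg <- extract_line_profile(grad)
  # intensity equals the (interpolated) column index along the scan
  expected <- 10 + pg$position_um / grad$pixel_size
  expect_true(all(abs(pg$intensity - expected) < 1e-9))

  expect_error(spindle_image(list(tubulin = matrix(1, 10, 10)), 0.1,
                             rbind(c(2, 2), c(2, 2 + 1e-12))),
               "distinct")
  expect_error(extract_line_profile(const, width = 2), "odd")
  expect_error(extract_line_profile(const, channel = "nope"), "channel")
})

test_that("profile maxima land at the generator's enriched poles", {
  img <- gen_spindle_image(image_sim_config(pole_enrichment = 1.5,
                                            noise_sd = 0))
  prof <- extract_line_profile(img)
  peak_pos <- prof$position_um[which.max(prof$intensity)]
  ends <- range(prof$position_um)
  expect_true(min(abs(peak_pos - ends)) <= img$pixel_size)
})

test_that("profile normalization maps length to [0,1] and maximum to 1", {
  prof <- profile_from_function(function(u) 3 + u)
  np <- normalize_profile(prof)
  expect_equal(range(np$position), c(0, 1))
  expect_equal(max(np$intensity), 1)
  # scale invariance
  prof2 <- dplyr::mutate(prof, intensity = intensity * 2)
  expect_equal(normalize_profile(prof2), np)
  expect_error(normalize_profile(prof[1:5, ]), "10 samples")
  expect_error(normalize_profile(
    profile_from_function(function(u) rep(0, length(u)))), "> 0")
})

test_that("bin medians partition the samples and match brute-force medians", {
  # uniform intensity: all medians 1
  flat <- normalize_profile(profile_from_function(function(u) rep(2, length(u))))
  bm <- bin_medians(flat)
  expect_equal(bm$bin, 1:10)
  expect_equal(bm$median, rep(1, 10))

  # intensity equal to position: bin i median ~ (2i - 1)/20
  lin <- tibble::tibble(position = seq(0, 1, length.out = 4001),
                        intensity = seq(0, 1, length.out = 4001))
  bml <- bin_medians(lin)
  expect_equal(bml$median, (2 * (1:10) - 1) / 20, tolerance = 1e-3)

  # brute-force partition check: every sample in exactly one bin
  set.seed(3)
  prof <- tibble::tibble(position = runif(500), intensity = runif(500))
  bin_idx <- pmin(floor(prof$position * 10) + 1, 10)
  expect_equal(sum(tabulate(bin_idx, 10)), 500L)
  got <- bin_medians(prof)
  brute <- vapply(1:10, function(b)
    median(prof$intensity[bin_idx == b]), numeric(1))
  expect_equal(got$median, brute)

  sparse <- tibble::tibble(position = c(0.05, 0.5, 0.95),
                           intensity = c(1, 1, 1))
  expect_error(bin_medians(sparse), "empty")
})

test_that("the sub-polar/equator ratio matches direct arithmetic and is symmetric", {
  expect_equal(region_ratio(rep(1, 10)), 1)
  m <- rep(1, 10); m[c(3, 8)] <- 0.8
  expect_equal(region_ratio(m), 0.8)

  # parabolic profile: bins 3 and 8 sit at 0.75, equator near 0.99
  parab <- normalize_profile(
    profile_from_function(function(u) 1 - (2 * u - 1)^2 + 1e-9))
  bm <- bin_medians(parab)
  expect_equal(region_ratio(bm), 0.75 / 0.99, tolerance = 1e-3)

  # orientation reversal and global scaling leave the ratio unchanged
  set.seed(8)
  m2 <- runif(10, 0.5, 1)
  expect_equal(region_ratio(rev(m2)), region_ratio(m2))
  expect_equal(region_ratio(m2 * 13), region_ratio(m2))
  expect_error(region_ratio(rep(0, 10)), "equator")
  expect_error(region_ratio(rep(1, 9)), "10 bin")
})

test_that("group comparison uses the exact rank-sum law where it applies", {
  # fully separated n = 10 vs 10: exact two-sided p = 2 / choose(20, 10)
  a <- 1:10 / 100
  b <- 2 + 1:10 / 100
  res <- compare_groups(a, b)
  expect_equal(res$p_value, 2 / choose(20, 10))
  expect_equal(res$method, "exact rank-sum")
  expect_lt(res$p_value, 0.01)

  expect_warning(same <- compare_groups(rep(1, 5), rep(1, 5)), "identical")
  expect_equal(same$p_value, 1)

  big <- compare_groups(rnorm(30), rnorm(30))
  expect_match(big$method, "normal approximation")
  expect_error(compare_groups(1:2, 1:5), "at least 3")
})

test_that("wild-type vs attenuated sub-polar spindles separate significantly", {
  n <- 24
  seeds <- 100 + seq_len(2 * n)
  wt <- vapply(seeds[1:n], function(s) spindle_region_ratio(
    gen_spindle_image(image_sim_config(noise_sd = 0.05, seed = s))),
    numeric(1))
  mut <- vapply(seeds[n + 1:n], function(s) spindle_region_ratio(
    gen_spindle_image(image_sim_config(subpolar_scale = 0.75,
                                       noise_sd = 0.05, seed = s))),
    numeric(1))
  expect_lt(compare_groups(wt, mut)$p_value, 0.01)
  expect_gt(mean(wt), mean(mut))
})
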