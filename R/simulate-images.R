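#' Configuration for the synthetic spindle-image generator
#'
#' Describes a two-channel maximum-intensity-projection image of one
#' acentrosomal spindle: a tubulin/Augmin channel whose intensity along
#' the pole-to-pole axis is a plateau with Gaussian pole peaks (scaled
#' by `pole_enrichment` and per-pole `pole_asymmetry`, so a weak or
#' missing pole is `pole_asymmetry = c(1, 0.2)` etc.) and an optional
#' multiplicative attenuation of the sub-polar regions
#' (`subpolar_scale < 1` emulates reduced microtubule density near the
#' poles); and a chromosome channel of axis-aligned Gaussian blobs
#' whose half-maximum mask spans `chromosome_spread` micrometres along
#' the axis.
#'
#' @param spindle_length pole-to-pole length, µm.
#' @param pixel_size µm per pixel (default 0.1).
#' @param pole_enrichment ratio of pole peak to equator plateau (>= 0;
#'   1 gives a flat axial profile).
#' @param pole_asymmetry length-2 attenuation of the two pole peaks.
#' @param subpolar_scale multiplicative intensity scale of the
#'   sub-polar regions (around 25% and 75% of the axis); 1 = no change.
#' @param chromosome_spread axial extent of the chromosome mask, µm.
#' @param blob_radius half-maximum radius of each chromosome blob, µm.
#' @param include_fourth add a small extra blob (a 4th-chromosome
#'   proxy) 1 µm beyond one end of the chromosome mass.
#' @param background cytosol intensity (both channels).
#' @param amplitude spindle-signal amplitude above background.
#' @param spindle_sigma_um radial (cross-axis) Gaussian width of the
#'   spindle signal, µm.
#' @param margin_um cytosol margin around the spindle, µm.
#' @param height_um image height, µm.
#' @param noise_sd Gaussian pixel noise sd, as a fraction of `amplitude`.
#' @param seed integer seed.
#' @return A list of class `"image_sim_config"`.
#' @export
image_sim_config <- function(spindle_length = 15,
                             pixel_size = 0.1,
                             pole_enrichment = 1.5,
                             pole_asymmetry = c(1, 1),
                             subpolar_scale = 1,
                             chromosome_spread = 4,
                             blob_radius = 0.5,
                             include_fourth = FALSE,
                             background = 10,
                             amplitude = 100,
                             spindle_sigma_um = 1.5,
                             margin_um = 2,
                             height_um = 8,
                             noise_sd = 0.05,
                             seed = 1L) {
  bad <- function(name, what) stop(sprintf("invalid `%s`: %s", name, what),
                                   call. = FALSE)
  if (!is.numeric(spindle_length) || spindle_length <= 0)
    bad("spindle_length", "must be > 0")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    bad("pixel_size", "must be > 0")
  if (!is.numeric(pole_enrichment) || pole_enrichment <= 0)
    bad("pole_enrichment", "must be > 0")
  if (length(pole_asymmetry) != 2L || any(pole_asymmetry < 0))
    bad("pole_asymmetry", "must be two non-negative factors")
  if (chromosome_spread < 0) bad("chromosome_spread", "must be >= 0")
  if (noise_sd < 0) bad("noise_sd", "must be >= 0")
  if (chromosome_spread > spindle_length)
    bad("chromosome_spread", "must not exceed the spindle length")
  structure(
    list(spindle_length = spindle_length, pixel_size = pixel_size,
         pole_enrichment = pole_enrichment,
         pole_asymmetry = pole_asymmetry,
         subpolar_scale = subpolar_scale,
         chromosome_spread = chromosome_spread,
         blob_radius = blob_radius, include_fourth = include_fourth,
         background = background, amplitude = amplitude,
         spindle_sigma_um = spindle_sigma_um, margin_um = margin_um,
         height_um = height_um, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "image_sim_config")
}

#' Construct a spindle-image container
#'
#' @param channels named list of numeric matrices (row = y, col = x),
#'   all the same dimension.
#' @param pixel_size µm per pixel.
#' @param poles 2x2 matrix of pole coordinates, rows = poles,
#'   columns = (x, y) in pixel units.
#' @param provenance `"projection"` or `"stack"`.
#' @return An object of class `"spindle_image"`.
#' @export
spindle_image <- function(channels, pixel_size, poles,
                          provenance = "projection") {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)))
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L)
    stop("all channels must have the same dimensions", call. = FALSE)
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be > 0", call. = FALSE)
  poles <- as.matrix(poles)
  if (!all(dim(poles) == c(2, 2)))
    stop("`poles` must be a 2x2 matrix (two (x, y) coordinates)",
         call. = FALSE)
  if (sqrt(sum((poles[1, ] - poles[2, ])^2)) < 1e-9)
    stop("the two poles must be distinct", call. = FALSE)
  structure(list(channels = channels, pixel_size = pixel_size,
                 poles = poles, provenance = provenance),
            class = "spindle_image")
}

#' @export
print.spindle_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<spindle_image> %d x %d px (%.1f x %.1f um), channels: %s\n",
              d[2], d[1], d[2] * x$pixel_size, d[1] * x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  poles (px): (%.1f, %.1f) - (%.1f, %.1f) | %s\n",
              x$poles[1, 1], x$poles[1, 2], x$poles[2, 1], x$poles[2, 2],
              x$provenance))
  invisible(x)
}

# unnormalized Gaussian bump, peak 1 at center
gauss_peak <- function(u, center, sigma) exp(-(u - center)^2 / (2 * sigma^2))

# noise-free axial shape on normalized position u (0 = pole 1, 1 = pole 2)
axial_shape <- function(u, cfg) {
  shape <- 1 +
    (cfg$pole_enrichment - 1) * (cfg$pole_asymmetry[1] * gauss_peak(u, 0, 0.08) +
                                 cfg$pole_asymmetry[2] * gauss_peak(u, 1, 0.08))
  window <- 1 - (1 - cfg$subpolar_scale) *
    pmin(1, gauss_peak(u, 0.25, 0.06) + gauss_peak(u, 0.75, 0.06))
  shape * window
}

#' Generate a synthetic two-channel spindle image
#'
#' Renders the configuration of [image_sim_config()] as a 2-D
#' maximum-intensity projection: channel `"tubulin"` is
#' `background + amplitude * axial_shape(x) * radial_envelope(y)` plus
#' noise, with the spindle axis horizontal through the image centre;
#' channel `"chromosomes"` contains the Gaussian chromosome blobs. The
#' true pole coordinates are stored in the returned object.
#'
#' @param cfg an [image_sim_config()].
#' @return A [spindle_image()].
#' @examples
#' img <- gen_spindle_image(image_sim_config(noise_sd = 0, seed = 3))
#' img
#' @export
gen_spindle_image <- function(cfg) {
  stopifnot(inherits(cfg, "image_sim_config"))
  px <- cfg$pixel_size
  width_um <- cfg$spindle_length + 2 * cfg$margin_um
  ncol_ <- round(width_um / px)
  nrow_ <- round(cfg$height_um / px)
  if (cfg$spindle_length >= width_um)
    stop("image too small to contain the spindle plus margin",
         call. = FALSE)
  # pixel-centre physical coordinates
  x_um <- (seq_len(ncol_) - 0.5) * px
  y_um <- (seq_len(nrow_) - 0.5) * px
  cy <- nrow_ * px / 2
  x1 <- cfg$margin_um
  x2 <- cfg$margin_um + cfg$spindle_length
  u <- (x_um - x1) / cfg$spindle_length

  ax <- axial_shape(u, cfg)
  radial <- gauss_peak(y_um, cy, cfg$spindle_sigma_um)
  tub <- cfg$background + cfg$amplitude * outer(radial, ax)

  chrom <- matrix(cfg$background / 2, nrow_, ncol_)
  centers <- chromosome_blob_centers(cfg)
  if (nrow(centers) > 0) {
    xg <- matrix(x_um, nrow_, ncol_, byrow = TRUE)
    yg <- matrix(y_um, nrow_, ncol_)
    for (i in seq_len(nrow(centers))) {
      sigma <- centers$radius[i] / sqrt(2 * log(2))  # half-max at `radius`
      d2 <- (xg - (x1 + centers$x[i]))^2 + (yg - cy)^2
      chrom <- chrom + centers$amp[i] * exp(-d2 / (2 * sigma^2))
    }
  }

  if (cfg$noise_sd > 0) {
    sd_abs <- cfg$noise_sd * cfg$amplitude
    noise <- withr::with_seed(cfg$seed, list(
      tub = matrix(stats::rnorm(nrow_ * ncol_, 0, sd_abs), nrow_, ncol_),
      chrom = matrix(stats::rnorm(nrow_ * ncol_, 0, sd_abs), nrow_, ncol_)
    ))
    tub <- tub + noise$tub
    chrom <- chrom + noise$chrom
  }

  poles <- rbind(c(x1 / px + 0.5, cy / px + 0.5),
                 c(x2 / px + 0.5, cy / px + 0.5))
  spindle_image(list(tubulin = tub, chromosomes = chrom),
                pixel_size = px, poles = poles,
                provenance = "projection")
}

# blob centres as axial offsets (µm) from pole 1, plus radius and amplitude
chromosome_blob_centers <- function(cfg) {
  mid <- cfg$spindle_length / 2
  amp <- 1.2 * cfg$amplitude
  if (cfg$chromosome_spread <= 0) {
    out <- tibble::tibble(x = numeric(), radius = numeric(),
                          amp = numeric())
  } else if (cfg$chromosome_spread < 2 * cfg$blob_radius) {
    # too narrow for two separate blobs: one blob spanning the spread
    out <- tibble::tibble(x = mid, radius = cfg$chromosome_spread / 2,
                          amp = amp)
  } else {
    half <- cfg$chromosome_spread / 2 - cfg$blob_radius
    out <- tibble::tibble(x = mid + c(-half, half),
                          radius = cfg$blob_radius, amp = amp)
  }
  if (cfg$include_fourth && nrow(out) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      x = max(out$x) + out$radius[which.max(out$x)] + 1,
      radius = 0.15, amp = 0.6 * amp))
  }
  out
}

#' Generate a thin z-stack whose projection is a spindle image
#'
#' Wraps [gen_spindle_image()]: each slice is the 2-D image scaled by a
#' per-slice weight (maximum 1 at the central slice) with independent
#' noise, so the noise-free maximum-intensity projection of the stack
#' equals the 2-D image. Exists to exercise [max_project()].
#'
#' @param cfg an [image_sim_config()].
#' @param n_slices number of z slices (default 3, 1 µm apart nominally).
#' @return list with `slices` (list of per-channel matrix lists),
#'   `image` (the underlying [spindle_image()]) and `weights`.
#' @export
gen_spindle_stack <- function(cfg, n_slices = 3L) {
  stopifnot(n_slices >= 1)
  base_cfg <- cfg
  base_cfg$noise_sd <- 0
  img <- gen_spindle_image(base_cfg)
  mid <- (n_slices + 1) / 2
  w <- gauss_peak(seq_len(n_slices), mid, max(1, n_slices / 3))
  w <- w / max(w)
  slices <- withr::with_seed(cfg$seed, lapply(seq_len(n_slices), function(i) {
    lapply(img$channels, function(ch) {
      out <- ch * w[i]
      if (cfg$noise_sd > 0)
        out <- out + matrix(stats::rnorm(length(ch), 0,
                                         cfg$noise_sd * cfg$amplitude),
                            nrow(ch), ncol(ch))
      out
    })
  }))
  list(slices = slices, image = img, weights = w)
}

#' Noise calibration for the congression generator
#'
#' For `spread = intercept + slope * log(intensity) + e` with
#' `log(intensity) ~ Normal(meanlog, sdlog^2)` and
#' `e ~ Normal(0, noise_sd^2)`, the population Pearson correlation of
#' spread with log-intensity is
#' `r = slope * sdlog / sqrt(slope^2 sdlog^2 + noise_sd^2)`. This
#' inverts that relation: the noise standard deviation giving a target
#' population correlation.
#'
#' @param slope µm per log-unit (negative for the congression-promoting
#'   relationship).
#' @param sdlog standard deviation of log-intensity.
#' @param r target population correlation (sign must match `slope`).
#' @return noise standard deviation, µm.
#' @examples
#' calibrate_congression_noise(-1, 1, -0.772)
#' @export
calibrate_congression_noise <- function(slope, sdlog, r) {
  stopifnot(abs(r) > 0, abs(r) < 1, sign(r) == sign(slope))
  abs(slope) * sdlog * sqrt(1 / r^2 - 1)
}

#' Generate a synthetic congression dataset
#'
#' Per-spindle pairs of chromosome spread and background-subtracted
#' pole intensity with a negative spread-vs-log-intensity association:
#' intensities are lognormal and
#' `spread = intercept + slope * log(intensity) + noise`, clipped below
#' at `floor_um`. Defaults give a population correlation of -0.772
#' between spread and log-intensity (see
#' [calibrate_congression_noise()]).
#'
#' @param n number of spindles (>= 3).
#' @param slope µm per log-unit (<= 0).
#' @param intercept µm.
#' @param noise_sd µm; defaults to the calibration for r = -0.772.
#' @param meanlog,sdlog lognormal parameters of the pole intensity.
#' @param floor_um lower clip for the spread.
#' @param seed integer seed.
#' @return tibble with columns `oocyte_id`, `pole_intensity`,
#'   `spread_um`.
#' @export
gen_congression_dataset <- function(n = 26, slope = -1, intercept = 9,
                                    noise_sd = calibrate_congression_noise(
                                      slope, sdlog, -0.772),
                                    meanlog = 3, sdlog = 1,
                                    floor_um = 0.5, seed = 1L) {
  if (n < 3) stop("`n` must be >= 3 (correlation undefined below)",
                  call. = FALSE)
  if (slope > 0) stop("`slope` must be <= 0 (congression-promoting ",
                      "association)", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    intensity <- stats::rlnorm(n, meanlog, sdlog)
    spread <- intercept + slope * log(intensity) +
      stats::rnorm(n, 0, noise_sd)
    tibble::tibble(oocyte_id = sprintf("oocyte_%03d", seq_len(n)),
                   pole_intensity = intensity,
                   spread_um = pmax(spread, floor_um))
  })
}
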