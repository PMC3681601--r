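#' Background-subtracted spindle-pole intensity
#'
#' Two regions of interest are measured on the (projected) image: a
#' large ROI containing the spindle plus surrounding cytosol (summed
#' intensity `I1` over `N1` pixels) and a small ROI covering the two
#' spindle poles (`I2` over `N2` pixels, a subset of the large ROI).
#' The cytosol background per pixel is estimated from the non-pole part
#' of the large ROI, `b = (I1 - I2) / (N1 - N2)`, and the pole
#' intensity above background is reported per pixel as
#' `I2 / N2 - b`. Setting `per_pixel = FALSE` instead returns the
#' literal expression `I2 - (I1 - I2)/(N1 - N2)` (total pole intensity
#' minus one pixel's background) for comparison.
#'
#' @param image a [spindle_image()] (its first channel is used unless
#'   `channel` is given) or a numeric matrix.
#' @param roi_large,roi_poles logical masks of the image dimensions;
#'   `roi_poles` must be a subset of `roi_large`.
#' @param channel channel name when `image` is a [spindle_image()].
#' @param per_pixel report the per-pixel form (default) or the literal
#'   difference form.
#' @return one-row tibble with `I1`, `N1`, `I2`, `N2`, `background`
#'   (per pixel) and `value`.
#' @export
pole_intensity <- function(image, roi_large, roi_poles,
                           channel = NULL, per_pixel = TRUE) {
  z <- if (inherits(image, "spindle_image")) {
    if (is.null(channel)) channel <- names(image$channels)[1]
    image$channels[[channel]]
  } else image
  stopifnot(is.matrix(z), is.logical(roi_large), is.logical(roi_poles))
  if (!all(dim(roi_large) == dim(z)) || !all(dim(roi_poles) == dim(z)))
    stop("ROI masks must match the image dimensions", call. = FALSE)
  if (any(roi_poles & !roi_large))
    stop("`roi_poles` must lie inside `roi_large`", call. = FALSE)
  n1 <- sum(roi_large)
  n2 <- sum(roi_poles)
  if (n2 == 0L) stop("`roi_poles` is empty", call. = FALSE)
  if (n1 <= n2)
    stop("`roi_large` must contain pixels outside the poles (N1 > N2)",
         call. = FALSE)
  i1 <- sum(z[roi_large])
  i2 <- sum(z[roi_poles])
  b <- (i1 - i2) / (n1 - n2)
  value <- if (per_pixel) i2 / n2 - b else i2 - b
  tibble::tibble(I1 = i1, N1 = n1, I2 = i2, N2 = n2,
                 background = b, value = value)
}

#' Axial extent of the chromosome mass
#'
#' Thresholds the chromosome channel (Otsu by default), labels the
#' connected blobs, optionally drops small blobs (below 10% of the
#' largest blob's area — a proxy for excluding the small 4th
#' chromosome), projects the remaining mask pixels onto the spindle
#' axis and returns the extent (max minus min projected coordinate)
#' in micrometres.
#'
#' @param image a [spindle_image()] with a chromosome channel; its
#'   `poles` define the axis.
#' @param channel channel name (default `"chromosomes"`).
#' @param exclude_smallest drop blobs with area < 10% of the largest.
#' @param threshold `"otsu"` or `"half_max"` (halfway between the
#'   channel minimum and maximum).
#' @return spread in µm (0 for a single-pixel mass).
#' @export
chromosome_spread <- function(image, channel = "chromosomes",
                              exclude_smallest = FALSE,
                              threshold = c("otsu", "half_max")) {
  stopifnot(inherits(image, "spindle_image"))
  threshold <- match.arg(threshold)
  z <- image$channels[[channel]]
  if (is.null(z)) stop(sprintf("no channel `%s`", channel), call. = FALSE)
  rng <- range(z)
  if (diff(rng) < 1e-12)
    stop("no chromosome signal: channel is constant", call. = FALSE)
  zn <- (z - rng[1]) / diff(rng)
  th <- if (threshold == "otsu") EBImage::otsu(zn, range = c(0, 1))
        else 0.5
  mask <- zn > th
  if (!any(mask))
    stop("no chromosome signal above threshold", call. = FALSE)
  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.integer(labels)
  areas <- tabulate(lab[lab > 0])
  keep <- seq_along(areas)
  if (exclude_smallest) {
    keep <- which(areas >= 0.1 * max(areas))
    if (length(keep) == 0L) keep <- which.max(areas)
  }
  sel <- matrix(lab %in% keep, nrow(z), ncol(z))
  idx <- which(sel, arr.ind = TRUE)
  # pixel-centre coordinates; project onto the pole-to-pole unit vector
  p1 <- image$poles[1, ]
  p2 <- image$poles[2, ]
  axis_vec <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  proj <- (idx[, "col"] - p1[1]) * axis_vec[1] +
          (idx[, "row"] - p1[2]) * axis_vec[2]
  (max(proj) - min(proj)) * image$pixel_size
}

#' Correlation between chromosome spread and log pole intensity
#'
#' Pearson correlation of chromosome spread (µm) against the natural
#' log of the background-subtracted pole intensity, with a two-sided p
#' value from the t distribution. The correlation is invariant to the
#' log base.
#'
#' @param records tibble with columns `spread_um` and `pole_intensity`
#'   (all positive), e.g. from [gen_congression_dataset()].
#' @return tibble with `r`, `p_value`, `n`.
#' @export
congression_correlation <- function(records) {
  if (!all(c("spread_um", "pole_intensity") %in% names(records)))
    stop("`records` must have columns `spread_um` and `pole_intensity`",
         call. = FALSE)
  if (nrow(records) < 3L) stop("need at least 3 records", call. = FALSE)
  if (any(records$pole_intensity <= 0))
    stop("pole intensities must be > 0 for the log transform",
         call. = FALSE)
  x <- log(records$pole_intensity)
  y <- records$spread_um
  if (stats::sd(x) < 1e-15 || stats::sd(y) < 1e-15)
    stop("zero variance in spread or intensity", call. = FALSE)
  ht <- stats::cor.test(y, x, method = "pearson")
  tibble::tibble(r = unname(ht$estimate), p_value = ht$p.value,
                 n = nrow(records))
}

#' Plot spread versus log pole intensity
#'
#' @param records tibble with `spread_um` and `pole_intensity`.
#' @return a ggplot scatter with the least-squares line.
#' @export
plot_congression <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = log(.data$pole_intensity),
                                        y = .data$spread_um)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "ln(pole intensity above background)",
                  y = "chromosome spread (µm)")
}
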