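#' Maximum-intensity projection of a z-stack
#'
#' @param stack a list of numeric matrices of identical dimension, or a
#'   3-D array with the slice index last.
#' @return matrix of the pixelwise maxima.
#' @export
max_project <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  if (!is.list(stack) || length(stack) == 0L)
    stop("`stack` must contain at least one slice", call. = FALSE)
  dims <- unique(lapply(stack, dim))
  if (length(dims) != 1L)
    stop("all slices must have the same dimensions", call. = FALSE)
  Reduce(pmax, stack)
}

#' Extract a pole-to-pole intensity line profile
#'
#' Samples pixel intensity along the segment joining the two annotated
#' poles, at points one pixel apart, by bilinear interpolation. With
#' `width > 1` the profile is averaged over that many parallel lines
#' offset perpendicular to the axis (one pixel apart, centred on the
#' axis).
#'
#' @param image a [spindle_image()].
#' @param channel channel name (default `"tubulin"`).
#' @param width odd number of parallel lines to average (default 1).
#' @return tibble with columns `position_um` (distance from the first
#'   pole) and `intensity`.
#' @export
extract_line_profile <- function(image, channel = "tubulin", width = 1L) {
  stopifnot(inherits(image, "spindle_image"))
  if (!channel %in% names(image$channels))
    stop(sprintf("no channel `%s` (have: %s)", channel,
                 paste(names(image$channels), collapse = ", ")),
         call. = FALSE)
  if (width < 1 || width %% 2 == 0)
    stop("`width` must be an odd number >= 1", call. = FALSE)
  z <- image$channels[[channel]]
  p1 <- image$poles[1, ]
  p2 <- image$poles[2, ]
  len_px <- sqrt(sum((p2 - p1)^2))
  if (len_px < 1e-9) stop("poles coincide", call. = FALSE)
  dir <- (p2 - p1) / len_px
  perp <- c(-dir[2], dir[1])
  s <- seq(0, len_px, by = 1)
  if (s[length(s)] < len_px) s <- c(s, len_px)
  offsets <- seq(-(width - 1) / 2, (width - 1) / 2)
  # pracma::interp2 uses x = columns, y = rows on a unit grid
  vals <- vapply(offsets, function(o) {
    xp <- p1[1] + s * dir[1] + o * perp[1]
    yp <- p1[2] + s * dir[2] + o * perp[2]
    xp <- pmin(pmax(xp, 1), ncol(z))
    yp <- pmin(pmax(yp, 1), nrow(z))
    pracma::interp2(x = seq_len(ncol(z)), y = seq_len(nrow(z)), Z = z,
                    xp = xp, yp = yp, method = "linear")
  }, numeric(length(s)))
  vals <- matrix(vals, nrow = length(s))
  tibble::tibble(position_um = s * image$pixel_size,
                 intensity = rowMeans(vals))
}

#' Normalize a line profile to spindle length and maximum intensity
#'
#' Positions are mapped affinely to `[0, 1]` (pole to pole) and
#' intensities divided by the profile maximum, so the output maximum is
#' exactly 1.
#'
#' @param profile tibble with `position_um` and `intensity` (>= 10
#'   samples).
#' @return tibble with columns `position` (in `[0, 1]`) and
#'   `intensity` (max 1).
#' @export
normalize_profile <- function(profile) {
  if (!all(c("position_um", "intensity") %in% names(profile)))
    stop("`profile` must have columns `position_um` and `intensity`",
         call. = FALSE)
  if (nrow(profile) < 10L)
    stop("need at least 10 samples along the profile", call. = FALSE)
  rng <- range(profile$position_um)
  if (diff(rng) < 1e-12) stop("profile has zero length", call. = FALSE)
  mx <- max(profile$intensity)
  if (mx <= 0) stop("profile maximum must be > 0", call. = FALSE)
  tibble::tibble(position = (profile$position_um - rng[1]) / diff(rng),
                 intensity = profile$intensity / mx)
}

#' Ten-bin medians of a normalized profile
#'
#' The spindle length is divided into 10 equal bins; bin `i` covers
#' positions `[(i-1)/10, i/10)` with the last bin closed at 1. Each
#' sample falls in exactly one bin; the per-bin medians are returned.
#'
#' @param profile normalized profile tibble (`position`, `intensity`).
#' @return tibble with columns `bin` (1–10) and `median`.
#' @export
bin_medians <- function(profile) {
  if (!all(c("position", "intensity") %in% names(profile)))
    stop("`profile` must be a normalized profile (columns `position`, ",
         "`intensity`)", call. = FALSE)
  bin <- pmin(floor(profile$position * 10) + 1L, 10L)
  counts <- tabulate(bin, nbins = 10L)
  if (any(counts == 0L))
    stop("empty profile bin(s): ", paste(which(counts == 0L), collapse = ", "),
         "; sample the profile more densely (>= 10 points per spindle ",
         "length)", call. = FALSE)
  out <- tibble::tibble(bin = bin, intensity = profile$intensity) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(median = stats::median(.data$intensity),
                     .groups = "drop")
  out
}

#' Sub-polar to equator intensity ratio
#'
#' The mean of the bin-3 and bin-8 medians (the sub-polar regions)
#' divided by the mean of the bin-5 and bin-6 medians (the equator).
#' The statistic is symmetric in profile orientation, since bins
#' {3, 8} and {5, 6} are mirror pairs.
#'
#' @param medians output of [bin_medians()], or a numeric vector of the
#'   10 bin medians in order.
#' @return single numeric ratio.
#' @export
region_ratio <- function(medians) {
  if (is.data.frame(medians)) {
    if (!all(c("bin", "median") %in% names(medians)))
      stop("`medians` must have columns `bin` and `median`", call. = FALSE)
    m <- medians$median[order(medians$bin)]
  } else m <- medians
  if (length(m) != 10L) stop("need exactly 10 bin medians", call. = FALSE)
  eq <- mean(m[c(5, 6)])
  if (abs(eq) < 1e-12) stop("zero equator intensity", call. = FALSE)
  mean(m[c(3, 8)]) / eq
}

#' Convenience: region ratio straight from an image
#'
#' Chains [extract_line_profile()], [normalize_profile()],
#' [bin_medians()] and [region_ratio()].
#'
#' @param image a [spindle_image()].
#' @param channel,width forwarded to [extract_line_profile()].
#' @return single numeric ratio.
#' @export
spindle_region_ratio <- function(image, channel = "tubulin", width = 1L) {
  extract_line_profile(image, channel = channel, width = width) |>
    normalize_profile() |>
    bin_medians() |>
    region_ratio()
}

#' Compare two groups of region ratios (Wilcoxon rank-sum)
#'
#' Two-sided Mann–Whitney/Wilcoxon rank-sum test: exact when the
#' combined sample size is at most 20 and there are no ties, normal
#' approximation with tie correction otherwise. Identical constant
#' groups return p = 1 with a warning.
#'
#' @param ratios_a,ratios_b numeric vectors, each of length >= 3.
#' @return tibble with `statistic`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
compare_groups <- function(ratios_a, ratios_b) {
  if (length(ratios_a) < 3L || length(ratios_b) < 3L)
    stop("each group needs at least 3 values", call. = FALSE)
  if (stats::sd(c(ratios_a, ratios_b)) < 1e-15) {
    warning("all values identical across both groups; p = 1",
            call. = FALSE)
    return(tibble::tibble(statistic = length(ratios_a) *
                            length(ratios_b) / 2,
                          p_value = 1, n_a = length(ratios_a),
                          n_b = length(ratios_b),
                          method = "degenerate (all values equal)"))
  }
  n_tot <- length(ratios_a) + length(ratios_b)
  has_ties <- anyDuplicated(c(ratios_a, ratios_b)) > 0
  exact <- n_tot <= 20 && !has_ties
  ht <- suppressWarnings(
    stats::wilcox.test(ratios_a, ratios_b, exact = exact, correct = TRUE)
  )
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n_a = length(ratios_a), n_b = length(ratios_b),
                 method = if (exact) "exact rank-sum"
                          else "normal approximation, tie-corrected")
}

#' Plot group region-ratio distributions
#'
#' @param ratios named list of numeric vectors (one per group).
#' @return a ggplot boxplot with jittered points.
#' @export
plot_region_ratios <- function(ratios) {
  d <- purrr::imap_dfr(ratios, function(v, nm)
    tibble::tibble(group = nm, ratio = v))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$ratio)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "sub-polar / equator intensity ratio")
}
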