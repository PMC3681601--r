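#' Read and write FRAP trace tables
#'
#' Traces are stored as plain CSV with columns `time_s`, `intensity`,
#' `is_prebleach`, `trace_id`, `role` (`"sample"` or `"control"`), the
#' same long format produced by [gen_trace_ensemble()]. Reading
#' validates the schema and reports offending row numbers.
#'
#' @param path CSV file path.
#' @return `read_traces()` returns the trace tibble; `write_traces()`
#'   returns `path` invisibly.
#' @export
read_traces <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_s", "intensity", "is_prebleach", "trace_id", "role")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("trace file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  raw$is_prebleach <- as.logical(raw$is_prebleach)
  bad_role <- which(!raw$role %in% c("sample", "control"))
  if (length(bad_role))
    stop("invalid `role` (not sample/control) at row(s): ",
         paste(utils::head(bad_role, 5), collapse = ", "), call. = FALSE)
  bad_t <- which(!is.finite(raw$time_s) | !is.finite(raw$intensity))
  if (length(bad_t))
    stop("non-finite time or intensity at row(s): ",
         paste(utils::head(bad_t, 5), collapse = ", "), call. = FALSE)
  tibble::as_tibble(raw)
}

#' @param traces trace tibble in the documented schema.
#' @rdname read_traces
#' @export
write_traces <- function(traces, path) {
  need <- c("time_s", "intensity", "is_prebleach", "trace_id", "role")
  miss <- setdiff(need, names(traces))
  if (length(miss))
    stop("traces are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  readr::write_csv(traces[need], path)
  invisible(path)
}

#' Read and write spindle images (multi-page TIFF + YAML sidecar)
#'
#' Channels are written channel-major as 16-bit pages of one TIFF;
#' pixel values must lie in `[0, 65535]` and are rounded to integers,
#' so round-trips are lossless for integer data. Metadata that TIFF
#' does not carry — pixel size, pole coordinates, channel names,
#' provenance — goes in a YAML sidecar next to the image
#' (`<image>.yaml`).
#'
#' @param path TIFF file path.
#' @param project if `TRUE` and the file holds a z-stack of one
#'   channel, return its maximum-intensity projection (sidecar
#'   `provenance: stack`).
#' @return `read_spindle_image()` returns a [spindle_image()];
#'   `write_spindle_image()` returns `path` invisibly.
#' @export
read_spindle_image <- function(path, project = FALSE) {
  sidecar <- sidecar_path(path)
  if (!file.exists(sidecar))
    stop("missing sidecar `", sidecar, "` (pixel size and poles are ",
         "required; micrometre results would be meaningless without ",
         "them)", call. = FALSE)
  meta <- yaml::read_yaml(sidecar)
  if (is.null(meta$pixel_size))
    stop("sidecar lacks `pixel_size`", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  mats <- lapply(pages, function(p) round(p * 65535))
  provenance <- meta$provenance %||% "projection"
  if (project && identical(provenance, "stack")) {
    mats <- list(max_project(mats))
    names(mats) <- meta$channels[1] %||% "channel_1"
    provenance <- "projection"
  } else {
    nms <- meta$channels %||% sprintf("channel_%d", seq_along(mats))
    names(mats) <- nms
  }
  poles <- matrix(unlist(meta$poles), nrow = 2, byrow = TRUE)
  spindle_image(mats, pixel_size = meta$pixel_size, poles = poles,
                provenance = provenance)
}

#' @param image a [spindle_image()] with integer-valued channels in
#'   `[0, 65535]`.
#' @rdname read_spindle_image
#' @export
write_spindle_image <- function(image, path) {
  stopifnot(inherits(image, "spindle_image"))
  rng <- range(unlist(lapply(image$channels, range)))
  if (rng[1] < 0 || rng[2] > 65535)
    stop("pixel values must lie in [0, 65535] for 16-bit TIFF output",
         call. = FALSE)
  pages <- lapply(image$channels, function(ch) round(ch) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16,
                  compression = "none")
  yaml::write_yaml(
    list(pixel_size = image$pixel_size,
         poles = list(as.numeric(image$poles[1, ]),
                      as.numeric(image$poles[2, ])),
         channels = names(image$channels),
         provenance = image$provenance),
    sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".yaml")

`%||%` <- function(a, b) if (is.null(a)) b else a
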