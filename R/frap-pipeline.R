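#' Correct a FRAP trace for acquisition-induced photobleaching
#'
#' Rescales a bleached-spindle trace by the fluorescence loss of a
#' non-bleached control imaged under the same conditions:
#' \deqn{F_{Corr}(t) = F(t) \cdot \bar C_{pre} / F_{Control}(t)}
#' where \eqn{\bar C_{pre}} is the mean pre-bleach control intensity.
#' Pre-bleach frames are corrected identically. If the control is on a
#' different time grid it is linearly interpolated onto the sample's
#' times (the sample's time range must be covered).
#'
#' @param sample tibble with columns `time_s`, `intensity`,
#'   `is_prebleach` — the bleached-spindle trace.
#' @param control tibble with the same columns — the non-bleached
#'   control (typically an average over several control spindles).
#' @return The sample tibble with `intensity` replaced by the corrected
#'   intensity.
#' @examples
#' p <- recovery_params("full_single", tf_half = 10)
#' tr <- gen_frap_trace(trace_sim_config(p, noise_sd = 0))
#' corr <- correct_photobleach(dplyr::filter(tr, role == "sample"),
#'                             dplyr::filter(tr, role == "control"))
#' @export
correct_photobleach <- function(sample, control) {
  check_trace_frame(sample, "sample")
  check_trace_frame(control, "control")
  if (any(control$intensity <= 0))
    stop("control intensities must be > 0 everywhere", call. = FALSE)
  if (min(sample$time_s) < min(control$time_s) - 1e-9 ||
      max(sample$time_s) > max(control$time_s) + 1e-9)
    stop("control does not cover the sample's time range", call. = FALSE)
  ctrl_at <- stats::approx(control$time_s, control$intensity,
                           xout = sample$time_s, rule = 1)$y
  c_pre <- mean(control$intensity[control$is_prebleach])
  if (!is.finite(c_pre))
    stop("control has no pre-bleach frames", call. = FALSE)
  dplyr::mutate(sample, intensity = .data$intensity * c_pre / ctrl_at)
}

#' Normalize a corrected FRAP trace
#'
#' Min–max normalization between the pre-bleach mean and the first
#' post-bleach intensity:
#' \deqn{F_{Norm}(t) = \frac{F_{Corr}(t) - F_{Corr}(0)}
#'                         {\bar F_{pre} - F_{Corr}(0)}}
#' so that the value at `t = 0` is exactly 0 and full recovery to the
#' pre-bleach level maps to 1. Only post-bleach times are kept.
#'
#' @param corrected a corrected trace tibble (`time_s`, `intensity`,
#'   `is_prebleach`), as returned by [correct_photobleach()].
#' @return A tibble with columns `time_s` (>= 0) and `value`.
#' @export
normalize_trace <- function(corrected) {
  check_trace_frame(corrected, "corrected")
  if (!any(corrected$is_prebleach))
    stop("trace has no pre-bleach frames", call. = FALSE)
  i0 <- which(!corrected$is_prebleach & abs(corrected$time_s) < 1e-9)
  if (length(i0) != 1L)
    stop("trace must contain exactly one post-bleach frame at t = 0",
         call. = FALSE)
  f0 <- corrected$intensity[i0]
  f_pre <- mean(corrected$intensity[corrected$is_prebleach])
  denom <- f_pre - f0
  if (abs(denom) < 1e-12 * max(abs(f_pre), 1))
    stop("no bleach detected: pre-bleach mean equals intensity at t = 0",
         call. = FALSE)
  post <- !corrected$is_prebleach
  tibble::tibble(time_s = corrected$time_s[post],
                 value = (corrected$intensity[post] - f0) / denom)
}

#' Pool normalized traces on a common time grid
#'
#' @param traces either a list of normalized-trace tibbles
#'   (`time_s`, `value`) or one long tibble with a `trace_id` column.
#' @return A tibble with columns `time_s`, `value` (pointwise mean),
#'   `sem` and `n`.
#' @export
pool_traces <- function(traces) {
  if (is.data.frame(traces)) {
    if (!"trace_id" %in% names(traces))
      stop("long-format input needs a `trace_id` column", call. = FALSE)
    traces <- split(traces[c("time_s", "value")], traces$trace_id)
  }
  if (length(traces) < 1L) stop("no traces to pool", call. = FALSE)
  grid <- traces[[1]]$time_s
  same <- purrr::map_lgl(traces, function(tr) {
    length(tr$time_s) == length(grid) && all(abs(tr$time_s - grid) < 1e-9)
  })
  if (!all(same))
    stop("traces are not on a common time grid", call. = FALSE)
  vals <- vapply(traces, function(tr) tr$value, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  n <- ncol(vals)
  m <- rowMeans(vals)
  sem <- if (n > 1) apply(vals, 1, stats::sd) / sqrt(n) else rep(0, length(grid))
  tibble::tibble(time_s = grid, value = m, sem = sem, n = n)
}

#' Correct, normalize and pool a simulated FRAP ensemble
#'
#' Applies the full trace pipeline to a long-format ensemble (as from
#' [gen_trace_ensemble()] or [read_traces()]): the control traces are
#' averaged pointwise into a single control (the mean of the
#' non-bleached spindles), each sample trace is corrected against it
#' with [correct_photobleach()], normalized with [normalize_trace()],
#' and the normalized traces pooled with [pool_traces()].
#'
#' @param traces long tibble with columns `time_s`, `intensity`,
#'   `is_prebleach`, `trace_id`, `role`.
#' @return A pooled normalized trace tibble (`time_s`, `value`, `sem`, `n`).
#' @export
process_frap_ensemble <- function(traces) {
  need <- c("time_s", "intensity", "is_prebleach", "trace_id", "role")
  miss <- setdiff(need, names(traces))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  controls <- dplyr::filter(traces, .data$role == "control")
  samples <- dplyr::filter(traces, .data$role == "sample")
  if (nrow(controls) == 0L || nrow(samples) == 0L)
    stop("ensemble needs both sample and control traces", call. = FALSE)
  ctrl_mean <- controls |>
    dplyr::group_by(.data$time_s, .data$is_prebleach) |>
    dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop") |>
    dplyr::arrange(.data$time_s)
  normalized <- samples |>
    dplyr::group_split(.data$trace_id) |>
    purrr::map(function(tr) {
      nt <- normalize_trace(correct_photobleach(tr, ctrl_mean))
      nt$trace_id <- tr$trace_id[1]
      nt
    }) |>
    dplyr::bind_rows()
  pool_traces(normalized)
}

#' Simulate and fit a FRAP recovery study
#'
#' One-call harness reproducing a pooled FRAP analysis end to end:
#' simulate `n_traces` sample/control pairs from ground-truth
#' [recovery_params()], correct for acquisition bleaching against the
#' averaged control, normalize, pool, and fit the requested model to
#' the pooled mean.
#'
#' @param params ground-truth [recovery_params()].
#' @param n_traces number of bleached spindles to simulate.
#' @param seed master seed for the simulation.
#' @param model_kind model to fit (defaults to the generating kind).
#' @param noise_sd,... forwarded to [trace_sim_config()].
#' @return A list with elements `fit` (a [fit_recovery()] result),
#'   `pooled` (the pooled normalized trace) and `traces` (the raw
#'   ensemble).
#' @examples
#' p <- recovery_params("two_population", f = 0.15, s = 0.85,
#'                      tf_half = 8, ts_half = 300)
#' study <- frap_recovery_study(p, n_traces = 15, seed = 1)
#' tidy(study$fit)
#' @export
frap_recovery_study <- function(params, n_traces = 15, seed = 1L,
                                model_kind = params$model_kind,
                                noise_sd = 0.03, ...) {
  cfg <- trace_sim_config(params, noise_sd = noise_sd, ...)
  traces <- gen_trace_ensemble(cfg, n = n_traces, seed = seed)
  pooled <- process_frap_ensemble(traces)
  fit <- fit_recovery(pooled, model_kind = model_kind, seed = seed)
  list(fit = fit, pooled = pooled, traces = traces)
}

# internal: minimal schema check for a single-trace tibble
check_trace_frame <- function(x, what) {
  if (!is.data.frame(x))
    stop(sprintf("`%s` must be a data frame", what), call. = FALSE)
  need <- c("time_s", "intensity", "is_prebleach")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(sprintf("`%s` is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (is.unsorted(x$time_s, strictly = TRUE))
    stop(sprintf("`%s` times must be strictly increasing", what),
         call. = FALSE)
  invisible(x)
}
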