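#' Fit a recovery model to a normalized FRAP trace
#'
#' Bounded nonlinear least squares with deterministic multistart. The
#' free parameters depend on the model kind:
#' `full_single` fits one half-time; `single_plus_immobile` fits a
#' recovering fraction and its half-time; `two_population` fits the
#' fast/slow split and two half-times (the two populations partition
#' the pool, `f + s = 1`). Half-times are optimized on the log scale
#' within `[dt/10, 100 * t_end]`; fractions within `[0, 1]`. Starts are
#' a log-spaced half-time grid crossed with fraction splits
#' {0.25, 0.5, 0.75}; the best residual sum of squares wins, with ties
#' broken by the smaller parameter count upstream in [select_model()].
#'
#' @param trace a normalized trace tibble with columns `time_s` and
#'   `value` (the pooled output of [pool_traces()] works directly).
#' @param model_kind `"full_single"`, `"single_plus_immobile"` or
#'   `"two_population"`.
#' @param n_starts number of multistart initializations (default 16).
#' @param seed seed for the (rarely needed) jittered extra starts.
#' @return An object of class `"frap_fit"`: a list with `params`
#'   ([recovery_params()]), `rss`, `n_obs`, `aicc`, `converged`,
#'   `n_starts_used`, the input `data` and a `fitted` tibble.
#' @examples
#' p <- recovery_params("two_population", f = 0.3, s = 0.7,
#'                      tf_half = 10, ts_half = 200)
#' tr <- tibble::tibble(time_s = seq(0, 165, 5),
#'                      value = model_recovery(seq(0, 165, 5), p))
#' fit <- fit_recovery(tr, "two_population")
#' glance(fit)
#' @export
fit_recovery <- function(trace,
                         model_kind = c("two_population", "full_single",
                                        "single_plus_immobile"),
                         n_starts = 16L, seed = 1L) {
  model_kind <- match.arg(model_kind)
  if (!is.data.frame(trace) || !all(c("time_s", "value") %in% names(trace)))
    stop("`trace` must have columns `time_s` and `value`", call. = FALSE)
  t <- trace$time_s
  y <- trace$value
  if (any(t < 0)) stop("normalized traces have post-bleach times only",
                       call. = FALSE)
  if (length(t) < 4L)
    stop("at least 4 post-bleach points are required for fitting",
         call. = FALSE)
  n_par <- switch(model_kind, full_single = 1L,
                  single_plus_immobile = 2L, two_population = 3L)
  if (length(t) <= n_par)
    stop("more observations than free parameters are required",
         call. = FALSE)

  # degenerate flat-zero trace: no recovery at all
  if (all(abs(y) < 1e-12)) {
    warning("flat zero trace: returning the zero-plateau solution",
            call. = FALSE)
    params <- structure(list(model_kind = model_kind, f = 0, s = 0,
                             tf_half = NA_real_, ts_half = NA_real_),
                        class = "recovery_params")
    return(new_frap_fit(params, rss = 0, n_obs = length(t), n_par = n_par,
                        converged = TRUE, n_starts_used = 0L,
                        data = trace, t = t))
  }

  dt <- min(diff(t))
  lo <- log(dt / 10)
  hi <- log(100 * max(t))
  starts <- fit_start_grid(model_kind, lo, hi, n_starts, seed)

  obj <- switch(
    model_kind,
    full_single = function(p) sum((y - recovery_value(t, 1, exp(p[1])))^2),
    single_plus_immobile =
      function(p) sum((y - recovery_value(t, p[1], exp(p[2])))^2),
    two_population = function(p) {
      sum((y - recovery_value(t, p[1], exp(p[2]), 1 - p[1], exp(p[3])))^2)
    }
  )
  lower <- switch(model_kind, full_single = lo,
                  single_plus_immobile = c(0, lo),
                  two_population = c(0, lo, lo))
  upper <- switch(model_kind, full_single = hi,
                  single_plus_immobile = c(1, hi),
                  two_population = c(1, hi, hi))

  best <- NULL
  any_ok <- FALSE
  for (st in starts) {
    res <- suppressWarnings(
      stats::nlminb(st, obj, lower = lower, upper = upper,
                    control = list(iter.max = 1000, rel.tol = 1e-14,
                                   x.tol = 1e-12))
    )
    # nlminb cannot meet rel.tol near machine precision and reports
    # "singular convergence"; the minimum is still resolved
    ok <- res$convergence == 0 || res$objective < 1e-20 ||
      (grepl("convergence", res$message %||% "") &&
         !grepl("false", res$message %||% ""))
    any_ok <- any_ok || ok
    if (is.null(best) || res$objective < best$objective) best <- res
  }

  p <- best$par
  params <- switch(
    model_kind,
    full_single = recovery_params("full_single", tf_half = exp(p[1])),
    single_plus_immobile =
      recovery_params("single_plus_immobile", f = p[1], tf_half = exp(p[2])),
    two_population =
      recovery_params("two_population", f = p[1], s = 1 - p[1],
                      tf_half = exp(p[2]), ts_half = exp(p[3]))
  )
  new_frap_fit(params, rss = best$objective, n_obs = length(t),
               n_par = n_par, converged = any_ok,
               n_starts_used = length(starts), data = trace, t = t)
}

# deterministic multistart grid; jittered extras only if n_starts exceeds it
fit_start_grid <- function(model_kind, lo, hi, n_starts, seed) {
  th <- seq(lo + log(2), hi - log(50), length.out = 4)
  splits <- c(0.25, 0.5, 0.75)
  starts <- switch(
    model_kind,
    full_single = as.list(seq(lo + log(2), hi - log(50), length.out =
                                max(4, min(n_starts, 16)))),
    single_plus_immobile =
      unlist(lapply(th, function(h) lapply(splits, function(f) c(f, h))),
             recursive = FALSE),
    two_population = {
      out <- list()
      for (a in 1:3) for (b in (a + 1):4) for (f in splits)
        out[[length(out) + 1L]] <- c(f, th[a], th[b])
      out
    }
  )
  if (length(starts) > n_starts) {
    keep <- unique(round(seq(1, length(starts), length.out = n_starts)))
    starts <- starts[keep]
  } else if (length(starts) < n_starts) {
    extra <- withr::with_seed(as.integer(seed), {
      lapply(seq_len(n_starts - length(starts)), function(i) {
        base <- starts[[1 + (i - 1) %% length(starts)]]
        base + stats::rnorm(length(base), 0, 0.2)
      })
    })
    starts <- c(starts, extra)
  }
  starts
}

new_frap_fit <- function(params, rss, n_obs, n_par, converged,
                         n_starts_used, data, t) {
  k <- n_par + 1  # + residual variance
  aicc <- if (n_obs - k - 1 > 0) {
    n_obs * log(max(rss, 1e-300) / n_obs) + 2 * k +
      2 * k * (k + 1) / (n_obs - k - 1)
  } else NA_real_
  fitted_vals <- if (is.na(params$tf_half)) rep(0, length(t))
                 else model_recovery(t, params)
  structure(
    list(params = params, rss = rss, n_obs = n_obs, n_par = n_par,
         aicc = aicc, converged = converged,
         n_starts_used = n_starts_used, data = data,
         fitted = tibble::tibble(time_s = t, value = fitted_vals)),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("<frap_fit>", x$params$model_kind,
      sprintf("| rss %.4g | AICc %.4g | n %d%s\n", x$rss, x$aicc, x$n_obs,
              if (x$converged) "" else " | NOT CONVERGED"))
  print(x$params)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a FRAP fit into one row per parameter
#'
#' @param x a `"frap_fit"` object.
#' @param ... unused.
#' @return tibble with columns `term` and `estimate`.
#' @export
tidy.frap_fit <- function(x, ...) {
  p <- x$params
  out <- switch(
    p$model_kind,
    full_single = tibble::tibble(term = "tf_half", estimate = p$tf_half),
    single_plus_immobile = tibble::tibble(
      term = c("f", "tf_half", "immobile"),
      estimate = c(p$f, p$tf_half, 1 - p$f)),
    two_population = tibble::tibble(
      term = c("f", "tf_half", "s", "ts_half"),
      estimate = c(p$f, p$tf_half, p$s, p$ts_half))
  )
  out
}

#' One-row summary of a FRAP fit
#'
#' @param x a `"frap_fit"` object.
#' @param ... unused.
#' @return tibble with `model_kind`, `rss`, `aicc`, `n_obs`, `n_par`,
#'   `converged`.
#' @export
glance.frap_fit <- function(x, ...) {
  tibble::tibble(model_kind = x$params$model_kind, rss = x$rss,
                 aicc = x$aicc, n_obs = x$n_obs, n_par = x$n_par,
                 converged = x$converged)
}

#' Compare recovery models on one trace by AICc
#'
#' Fits every candidate model with [fit_recovery()] and ranks them by
#' the corrected Akaike information criterion. Candidates whose AICc is
#' within 2 of the best are flagged: the data do not discriminate them,
#' and the selection is reported as indeterminate rather than silently
#' resolved.
#'
#' @param trace normalized trace tibble (`time_s`, `value`).
#' @param candidates character vector of model kinds (>= 2).
#' @param n_starts,seed forwarded to [fit_recovery()].
#' @return An object of class `"frap_model_selection"`: list with
#'   `best` (model kind), `indeterminate` (logical), `table`
#'   (per-model glance tibble with `delta_aicc`) and `fits`.
#' @export
select_model <- function(trace,
                         candidates = c("full_single",
                                        "single_plus_immobile",
                                        "two_population"),
                         n_starts = 16L, seed = 1L) {
  candidates <- unique(candidates)
  if (length(candidates) < 2L)
    stop("need at least 2 candidate models", call. = FALSE)
  fits <- purrr::map(candidates, function(k) {
    fit_recovery(trace, model_kind = k, n_starts = n_starts, seed = seed)
  })
  names(fits) <- candidates
  tab <- purrr::map_dfr(fits, glance) |>
    dplyr::mutate(delta_aicc = .data$aicc - min(.data$aicc)) |>
    dplyr::arrange(.data$aicc)
  best <- tab$model_kind[1]
  indeterminate <- sum(tab$delta_aicc < 2) > 1L
  if (indeterminate)
    warning("model selection indeterminate: ",
            paste(tab$model_kind[tab$delta_aicc < 2], collapse = ", "),
            " within 2 AICc units", call. = FALSE)
  structure(list(best = best, indeterminate = indeterminate,
                 table = tab, fits = fits),
            class = "frap_model_selection")
}

#' @export
print.frap_model_selection <- function(x, ...) {
  cat("<frap_model_selection> best:", x$best,
      if (x$indeterminate) "(indeterminate)" else "", "\n")
  print(x$table)
  invisible(x)
}

#' @export
tidy.frap_model_selection <- function(x, ...) x$table

#' Plot a FRAP fit over its data
#'
#' @param object a `"frap_fit"` object.
#' @param ... unused.
#' @return A ggplot: points (with SEM ribbon when available) and the
#'   fitted recovery curve.
#' @export
autoplot.frap_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$value))
  if ("sem" %in% names(d))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$value - .data$sem,
                   ymax = .data$value + .data$sem),
      fill = "grey80")
  curve_t <- seq(min(d$time_s), max(d$time_s), length.out = 200)
  curve <- tibble::tibble(
    time_s = curve_t,
    value = if (is.na(object$params$tf_half)) rep(0, 200)
            else model_recovery(curve_t, object$params))
  p +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(x = "time after bleach (s)",
                  y = "normalized fluorescence",
                  title = paste("FRAP recovery:", object$params$model_kind))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
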