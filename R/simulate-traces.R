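#' Configuration for the FRAP-trace simulator
#'
#' Bundles the acquisition settings used to forward-simulate a FRAP
#' experiment: a photobleach at `t = 0` preceded by `n_pre` pre-bleach
#' frames, frames every `dt` seconds out to `t_end`, multiplicative
#' acquisition-induced photobleaching shared by the bleached spindle and
#' its non-bleached control, and additive Gaussian measurement noise.
#'
#' Defaults mirror a typical oocyte acquisition: 3 pre-bleach frames,
#' 5 s sampling for 165 s, and an acquisition-bleaching rate under which
#' a control spindle has lost 25% of its fluorescence after 80 s of
#' imaging.
#'
#' @param params a [recovery_params()] object — the ground-truth kinetics.
#' @param n_pre number of pre-bleach frames (>= 3).
#' @param dt sampling interval, seconds.
#' @param t_end last post-bleach time, seconds.
#' @param pre_level mean pre-bleach intensity, arbitrary units.
#' @param bleach_depth fraction of pre-bleach intensity remaining at
#'   `t = 0`, in `[0, 1)`.
#' @param acq_bleach_rate per-second multiplicative acquisition-bleaching
#'   rate applied from `t = 0` onwards.
#' @param noise_sd Gaussian noise standard deviation, as a fraction of
#'   `pre_level`.
#' @param seed integer seed.
#' @return A list of class `"trace_sim_config"`.
#' @export
trace_sim_config <- function(params,
                             n_pre = 3L,
                             dt = 5,
                             t_end = 165,
                             pre_level = 100,
                             bleach_depth = 0.2,
                             acq_bleach_rate = log(4 / 3) / 80,
                             noise_sd = 0.03,
                             seed = 1L) {
  stopifnot(inherits(params, "recovery_params"))
  check_field <- function(ok, name, what) {
    if (!ok) stop(sprintf("invalid `%s`: %s", name, what), call. = FALSE)
  }
  check_field(is.numeric(dt) && dt > 0, "dt", "must be > 0")
  check_field(is.numeric(t_end) && t_end >= dt, "t_end", "must be >= dt")
  check_field(n_pre >= 3, "n_pre", "must be >= 3")
  check_field(is.numeric(bleach_depth) && bleach_depth >= 0 &&
                bleach_depth < 1, "bleach_depth", "must be in [0, 1)")
  check_field(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd",
              "must be >= 0")
  check_field(is.numeric(acq_bleach_rate) && acq_bleach_rate >= 0,
              "acq_bleach_rate", "must be >= 0")
  check_field(is.numeric(pre_level) && pre_level > 0, "pre_level",
              "must be > 0")
  structure(list(params = params, n_pre = as.integer(n_pre), dt = dt,
                 t_end = t_end, pre_level = pre_level,
                 bleach_depth = bleach_depth,
                 acq_bleach_rate = acq_bleach_rate,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "trace_sim_config")
}

# shared time grid: pre-bleach frames at negative times, t = 0 is the
# first post-bleach frame
sim_time_grid <- function(cfg) {
  c(-rev(seq_len(cfg$n_pre)) * cfg$dt, seq(0, cfg$t_end, by = cfg$dt))
}

#' Simulate one FRAP trace and its non-bleached control
#'
#' Forward model: the bleached spindle drops to
#' `pre_level * bleach_depth` at `t = 0` and recovers according to the
#' configured [recovery_params()]; the control stays at `pre_level`.
#' Both are attenuated by `exp(-acq_bleach_rate * t)` for `t >= 0`
#' (acquisition-induced photobleaching; pre-bleach frames are
#' unattenuated) and carry i.i.d. Gaussian noise.
#'
#' @param cfg a [trace_sim_config()].
#' @param trace_id identifier stamped on the output rows.
#' @return A tibble with columns `time_s`, `intensity`, `is_prebleach`,
#'   `trace_id` and `role` (`"sample"` or `"control"`).
#' @examples
#' p <- recovery_params("two_population", f = 0.15, s = 0.85,
#'                      tf_half = 8, ts_half = 300)
#' tr <- gen_frap_trace(trace_sim_config(p, seed = 7))
#' dplyr::count(tr, role, is_prebleach)
#' @export
gen_frap_trace <- function(cfg, trace_id = "trace_001") {
  stopifnot(inherits(cfg, "trace_sim_config"))
  withr::with_seed(cfg$seed, gen_frap_trace_impl(cfg, trace_id))
}

gen_frap_trace_impl <- function(cfg, trace_id) {
  tt <- sim_time_grid(cfg)
  post <- tt >= 0
  decay <- ifelse(post, exp(-cfg$acq_bleach_rate * tt), 1)
  f_model <- numeric(length(tt))
  f_model[post] <- model_recovery(tt[post], cfg$params)
  base_sample <- ifelse(
    post,
    cfg$pre_level * (cfg$bleach_depth + (1 - cfg$bleach_depth) * f_model),
    cfg$pre_level
  )
  sd_abs <- cfg$noise_sd * cfg$pre_level
  sample_int <- base_sample * decay + stats::rnorm(length(tt), 0, sd_abs)
  control_int <- cfg$pre_level * decay + stats::rnorm(length(tt), 0, sd_abs)
  dplyr::bind_rows(
    tibble::tibble(time_s = tt, intensity = sample_int,
                   is_prebleach = !post, trace_id = trace_id,
                   role = "sample"),
    tibble::tibble(time_s = tt, intensity = control_int,
                   is_prebleach = !post, trace_id = trace_id,
                   role = "control")
  )
}

#' Simulate an ensemble of FRAP traces
#'
#' Draws `n` independent sample/control trace pairs on a common time
#' grid. Per-trace seeds are derived deterministically from `seed`, so a
#' fixed seed reproduces the ensemble bitwise.
#'
#' @param cfg a [trace_sim_config()]; its own `seed` field is ignored in
#'   favour of `seed`.
#' @param n number of trace pairs (>= 1).
#' @param seed master seed for the ensemble.
#' @return A tibble in the same long format as [gen_frap_trace()], with
#'   `trace_id` values `"trace_001" ... "trace_<n>"`.
#' @export
gen_trace_ensemble <- function(cfg, n, seed = cfg$seed) {
  stopifnot(inherits(cfg, "trace_sim_config"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be >= 1", call. = FALSE)
  n <- as.integer(n)
  sub_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max, n))
  purrr::map_dfr(seq_len(n), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- sub_seeds[i]
    gen_frap_trace(cfg_i, trace_id = sprintf("trace_%03d", i))
  })
}
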