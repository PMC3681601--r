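test_that("noise-free fits recover the generating parameters to high precision", {
  t <- seq(0, 165, 5)
  cases <- list(
    recovery_params("two_population", f = 0.3, s = 0.7,
                    tf_half = 10, ts_half = 200),
    oocyte_params(),
    recovery_params("two_population", f = 0.4, s = 0.6,
                    tf_half = 5, ts_half = 60),
    embryo_params(),
    recovery_params("full_single", tf_half = 25)
  )
  for (p in cases) {
    tr <- tibble::tibble(time_s = t, value = model_recovery(t, p))
    fit <- fit_recovery(tr, model_kind = p$model_kind)
    expect_true(fit$converged)
    expect_lt(fit$rss, 1e-12)
    expect_equal(fit$params$f, p$f, tolerance = 1e-4)
    expect_equal(fit$params$tf_half, p$tf_half, tolerance = 1e-4)
    if (p$model_kind == "two_population") {
      expect_equal(fit$params$s, p$s, tolerance = 1e-4)
      expect_equal(fit$params$ts_half, p$ts_half, tolerance = 1e-4)
      expect_lt(fit$params$tf_half, fit$params$ts_half)
    }
  }
})

test_that("a flat zero trace yields the zero-plateau solution with a warning", {
  tr <- tibble::tibble(time_s = seq(0, 50, 5), value = rep(0, 11))
  expect_warning(fit <- fit_recovery(tr, "two_population"), "flat zero")
  expect_equal(fit$params$f + fit$params$s, 0)
  expect_equal(fit$rss, 0)
})

test_that("fitting rejects undersized or malformed inputs", {
  expect_error(fit_recovery(tibble::tibble(time_s = c(0, 5, 10),
                                           value = c(0, .1, .2))),
               "4 post-bleach")
  expect_error(fit_recovery(tibble::tibble(time_s = c(-5, 0, 5, 10, 15),
                                           value = rep(0.1, 5))),
               "post-bleach")
  expect_error(fit_recovery(data.frame(t = 1, y = 2)), "time_s")
})

test_that("parameter recovery under noise is nearly unbiased at the study settings", {
  # pooled fits over 12 Monte-Carlo replicates, oocyte-like truth
  p <- oocyte_params()
  ests <- t(vapply(1:12, function(i) {
    fit <- frap_recovery_study(p, n_traces = 15, seed = 2000 + i)$fit
    c(fit$params$f, fit$params$tf_half, fit$params$s, fit$params$ts_half)
  }, numeric(4)))
  bias <- colMeans(ests) - c(p$f, p$tf_half, p$s, p$ts_half)
  expect_lt(abs(bias[1]), 0.05)            # fast fraction
  expect_lt(abs(bias[3]), 0.05)            # slow fraction
  expect_lt(abs(bias[2]) / p$tf_half, 0.15)  # fast half-time
  expect_lt(abs(bias[4]) / p$ts_half, 0.15)  # slow half-time
})

test_that("AICc selection reproduces the qualitative model choices", {
  # oocyte-like: two well-separated turnover rates -> two_population
  oo <- frap_recovery_study(oocyte_params(), n_traces = 15, seed = 1)
  sel_oo <- suppressWarnings(select_model(oo$pooled, seed = 1))
  expect_equal(sel_oo$best, "two_population")

  # embryo-like: one turnover population plus an immobile remainder
  em <- frap_recovery_study(embryo_params(), n_traces = 11, seed = 2,
                            model_kind = "single_plus_immobile")
  sel_em <- suppressWarnings(select_model(em$pooled, seed = 2))
  expect_equal(sel_em$best, "single_plus_immobile")

  # low-noise full single-rate recovery -> the one-parameter model
  t <- seq(0, 165, 5)
  pf <- recovery_params("full_single", tf_half = 30)
  set.seed(1)
  fs <- tibble::tibble(time_s = t,
                       value = model_recovery(t, pf) + rnorm(34, 0, 0.01))
  sel_fs <- suppressWarnings(select_model(fs))
  expect_equal(sel_fs$best, "full_single")

  # the table is complete and ranked
  expect_equal(nrow(sel_oo$table), 3L)
  expect_equal(sel_oo$table$delta_aicc[1], 0)
  expect_true(all(diff(sel_oo$table$aicc) >= 0))
})

test_that("near-ties are flagged as indeterminate rather than silently resolved", {
  # data truly from single_plus_immobile: the richer two_population fit
  # can chase enough noise that AICc cannot separate the pair; this
  # noise realization produces such a tie
  t <- seq(0, 165, 5)
  p <- embryo_params()
  set.seed(3)
  tr <- tibble::tibble(time_s = t,
                       value = model_recovery(t, p) + rnorm(34, 0, 0.02))
  expect_warning(
    sel <- select_model(tr, candidates = c("single_plus_immobile",
                                           "two_population")),
    "indeterminate")
  expect_true(sel$indeterminate)
})

test_that("tidy, glance and autoplot expose the fit", {
  fit <- frap_recovery_study(oocyte_params(), n_traces = 5, seed = 9)$fit
  td <- tidy(fit)
  expect_setequal(td$term, c("f", "tf_half", "s", "ts_half"))
  gl <- glance(fit)
  expect_equal(gl$model_kind, "two_population")
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
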