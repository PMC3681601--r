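# spindleq

Quantitative analysis of acentrosomal (meiotic) spindle fluorescence
microscopy. Oocyte spindles assemble without centrosomes, and the
proteins that organize their poles — notably the Augmin complex, which
recruits γ-tubulin to nucleate new microtubules from existing ones —
behave very differently there than on mitotic spindles. spindleq
implements the three measurement chains such studies rely on, for
anyone who needs them as tested, reusable code rather than one-off
scripts:

1. **FRAP recovery kinetics.** Traces from fluorescence recovery after
   photobleaching are corrected for acquisition-induced bleaching
   against non-bleached control spindles
   (`F_corr(t) = F(t)·C̄_pre/F_control(t)`), min–max normalized between
   the pre-bleach mean and the post-bleach intensity at `t = 0`, pooled,
   and fit to a family of recovery models on the half-time scale,

   `F(t) = f·(1 − 2^(−t/tf½)) + s·(1 − 2^(−t/ts½))`,

   covering one fully recovering population, one recovering population
   plus an immobile remainder, and two recovering populations that
   partition the pool (`f + s = 1`, fast and slow). Fitting is bounded
   multistart least squares; competing models are ranked by AICc with
   near-ties flagged as indeterminate.
2. **Pole-to-pole intensity profiles.** Line scans between annotated
   poles, normalized to spindle length and per-line maximum, summarized
   as ten per-bin medians, and reduced to a sub-polar/equator ratio
   (bins 3 and 8 over bins 5 and 6) compared between groups with the
   Wilcoxon rank-sum test.
3. **Pole accumulation vs chromosome congression.** Background-
   subtracted per-pixel pole intensity from two ROIs
   (`I2/N2 − (I1−I2)/(N1−N2)`), chromosome-mass axial spread from a
   thresholded chromosome channel, and the Pearson correlation of
   spread against log pole intensity.

Every stage has a synthetic-data generator (`gen_frap_trace()`,
`gen_spindle_image()`, `gen_congression_dataset()`) producing inputs
with known ground truth, so the estimators are validated by parameter
recovery without any microscopy download.

## Worked example

Simulate a pooled oocyte-style FRAP study — 15 bleached spindles, 3
pre-bleach frames, one frame every 5 s for 165 s, noise sd 0.03 —
from a ground truth of 15% fast (8 s half-time) and 85% slow (300 s
half-time), then run the full correction → normalization → pooling →
fitting chain:

```r
library(spindleq)

truth <- recovery_params("two_population", f = 0.15, s = 0.85,
                         tf_half = 8, ts_half = 300)
study <- frap_recovery_study(truth, n_traces = 15, seed = 1)
tidy(study$fit)
#> # A tibble: 4 × 2
#>   term    estimate
#>   <chr>      <dbl>
#> 1 f          0.141
#> 2 tf_half    7.26
#> 3 s          0.859
#> 4 ts_half  293.
```

The fit recovers the generating parameters: a slow pool of 86% (truth
85%) with a half-recovery time of 293 s (truth 300 s), and a fast pool
of 14% at 7.3 s (truth 8 s; half-times near the 5 s frame interval
carry the widest uncertainty). Model selection shows why the
two-population description is the right one for this regime:

```r
sel <- select_model(study$pooled, seed = 1)
sel$table[c("model_kind", "rss", "aicc", "delta_aicc")]
#> # A tibble: 3 × 4
#>   model_kind               rss  aicc delta_aicc
#>   <chr>                  <dbl> <dbl>      <dbl>
#> 1 two_population       0.00816 -274.        0
#> 2 single_plus_immobile 0.0237  -240.       33.7
#> 3 full_single          0.0869  -199.       75.5
```

A ΔAICc of 34 against the nearest alternative is a decisive margin —
single-population models, with or without an immobile remainder, do
not describe a pool with two well-separated exchange rates.
`autoplot(study$fit)` overlays the fitted curve on the pooled data.

The congression analysis works the same way from its generator:

```r
records <- gen_congression_dataset(n = 26, seed = 1)
congression_correlation(records)
#> # A tibble: 1 × 3
#>        r       p_value     n
#>    <dbl>         <dbl> <int>
#> 1 -0.879 0.00000000344    26
```

a strongly negative spread-versus-log-intensity correlation, as
expected from the generator's calibrated population correlation of
−0.772 (individual samples of n = 26 scatter around it).

`run_pipeline(pipeline_config(seed = 1))` chains all three analyses
from one master seed and returns (optionally writes as JSON) a single
deterministic report with the AICc table, the group comparison, and
the correlation.

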