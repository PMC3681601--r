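---
title: "Models and methods behind spindleq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spindleq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindleq)
```

spindleq quantifies fluorescence microscopy of acentrosomal (meiotic)
spindles along three axes: the turnover kinetics of spindle-associated
proteins measured by fluorescence recovery after photobleaching (FRAP),
the axial distribution of fluorescence between spindle poles and
equator, and the relationship between spindle-pole protein accumulation
and chromosome congression. Because raw oocyte microscopy is rarely
redistributable, every analysis is paired with a synthetic-data
generator that produces inputs with the statistical structure the
analysis assumes, so the whole pipeline is testable offline and its
estimators can be validated by parameter recovery.

## The FRAP recovery model family

A photobleached region recovers as bleached molecules exchange with
unbleached ones. After correction and normalization (below), recovery
is modelled on the half-time scale, where each recovering population
contributes

$$F_p(t) = a_p\left(1 - 2^{-t/t_{1/2,p}}\right),$$

with $a_p$ the population's fraction of the pool and $t_{1/2,p}$ its
half-recovery time (decay rate $k = \ln 2 / t_{1/2}$, so reported
half-times are literal). Three nested model kinds cover the regimes
seen on spindles:

* **`full_single`** — one population, full recovery:
  $F(t) = 1 - 2^{-t/t_{1/2}}$ (1 parameter).
* **`single_plus_immobile`** — one recovering population of size $f$
  plus an immobile ("non-turnover") remainder $1-f$:
  $F(t) = f(1 - 2^{-t/t_{1/2}})$ (2 parameters). This is the regime of
  mitotic spindles in syncytial embryos, where most of the protein
  turns over in seconds and a minority does not exchange at all.
* **`two_population`** — a fast fraction $f$ and a slow fraction
  $s = 1-f$ that *partition the whole pool*:
  $F(t) = f(1-2^{-t/t_{f,1/2}}) + s(1-2^{-t/t_{s,1/2}})$
  (3 parameters, labels canonicalized so $t_{f,1/2} < t_{s,1/2}$).
  This is the oocyte regime: a small fast pool plus a large, slowly
  exchanging pool.

### Why the two-population model is constrained to $f + s = 1$

The constraint is a deliberate design choice with an identifiability
rationale. With a 165 s observation window and a slow half-time of
several minutes, the slow component is sampled only on its initial,
nearly linear stretch, where $s(1 - 2^{-t/t_s}) \approx
s\,t\ln 2/t_s$. If the total mobile fraction $f+s$ is left free, $s$
and $t_s$ trade off along a flat residual valley (halving both changes
the curve by less than realistic noise), and least-squares estimates
wander over a wide range of $(s, t_s)$ pairs with equally good fits.
Fixing $f+s=1$ removes the valley: the late-time level pins $s$, and
the late slope then pins $t_s$. Monte-Carlo recovery runs in the test
suite confirm that under the constraint all parameter sets of interest
are recovered with small bias from 15 pooled traces, while without it
they are not. The case of a genuinely immobile remainder is not lost —
it is exactly the `single_plus_immobile` model, and AICc-based
selection (below) distinguishes the two regimes reliably.

## Correction and normalization

Imaging itself bleaches fluorophores, so the raw recovery of a
bleached spindle is confounded with acquisition bleaching. A
non-bleached control spindle imaged identically measures that loss,
and the sample is rescaled by the control's relative decline:

$$F_{\mathrm{Corr}}(t) = F(t)\,\frac{\bar C_{\mathrm{pre}}}{F_{\mathrm{Control}}(t)},$$

with $\bar C_{\mathrm{pre}}$ the control's pre-bleach mean
(`correct_photobleach()`). In practice the control is the average of
several non-bleached spindles; `process_frap_ensemble()` uses the
pointwise mean of all control traces. The corrected trace is then
min–max normalized between the pre-bleach mean and the first
post-bleach frame,

$$F_{\mathrm{Norm}}(t) = \frac{F_{\mathrm{Corr}}(t) - F_{\mathrm{Corr}}(0)}
{\bar F_{\mathrm{pre}} - F_{\mathrm{Corr}}(0)},$$

so $F_{\mathrm{Norm}}(0) = 0$ and full recovery maps to 1
(`normalize_trace()`). A zero denominator means no bleach was applied
and is rejected rather than propagated. Normalization is per trace and
pooling (`pool_traces()`) is pointwise afterwards, mirroring the
per-oocyte measurement order; a comparison against pooling corrected
traces before a single normalization showed indistinguishable
estimator distributions, so the order is not load-bearing.

## Fitting and model selection

`fit_recovery()` minimizes the residual sum of squares with
`stats::nlminb` under box constraints: fractions in $[0,1]$ and
half-times, optimized on the log scale, in
$[\mathrm{d}t/10,\;100\,t_{\max}]$. The objective is multimodal enough
to warrant multistart: 16 deterministic starts built from a log-spaced
half-time grid crossed with fraction splits $\{0.25, 0.5, 0.75\}$,
keeping the best final RSS. At `rel.tol = 1e-12` the optimizer often
terminates with a "singular convergence" code once the surface is flat
to machine precision; this is treated as convergence (noise-free
recovery in the test suite is exact to ~1e-14), while "false
convergence" of every start is reported as failure. A trace that is
identically zero (no recovery) returns the zero-plateau solution with
a warning instead of a spurious optimum.

Models are compared with the corrected Akaike information criterion,
$\mathrm{AICc} = n\ln(\mathrm{RSS}/n) + 2k + 2k(k+1)/(n-k-1)$ with $k$
counting the kinetic parameters plus the residual variance.
`select_model()` fits all candidates and returns the full ranked table
so that "model A fits, model B does not" is an inspectable margin;
candidates within 2 AICc units of the best are flagged as
indeterminate rather than silently resolved, since differences that
small are within noise.

## The synthetic FRAP generator

`gen_frap_trace()` forward-simulates the acquisition: `n_pre`
pre-bleach frames at `pre_level` placed at negative times, a bleach to
`pre_level * bleach_depth` at $t = 0$, recovery following the
configured model, multiplicative acquisition bleaching
$e^{-rt}$ applied to sample and control alike from $t=0$, and i.i.d.
Gaussian noise. Defaults are the oocyte acquisition settings: 3
pre-bleach frames, 5 s sampling to 165 s, and an acquisition-bleaching
rate $r = \ln(4/3)/80$ under which a control loses 25% of its signal
by 80 s. The bleach depth (0.2) and noise level (0.03 of the
pre-bleach intensity) are not published quantities; they are
plausible-scale defaults exposed as configuration, not claims about
any instrument. Because noise is i.i.d. Gaussian and bleaching is
exactly multiplicative and shared with the control, passing recovery
tests demonstrates estimator correctness under the model's own
assumptions — not robustness to detector nonlinearity, focus drift, or
spindle movement, which real acquisitions add.

## Spindle intensity profiles

`extract_line_profile()` samples a channel by bilinear interpolation
at one-pixel spacing along the segment joining the two annotated
poles, optionally averaged over a configurable odd number of parallel
lines (default width 1: a single line). Pole positions are user input;
automatic detection is out of scope beyond the generator's ground
truth. `normalize_profile()` maps positions affinely to $[0,1]$ and
divides intensities by the profile maximum — the per-line maximum, not
the image maximum, so the statistic is invariant to global intensity
scale. The profile is then split into ten equal bins (bin $i$ covers
$[(i-1)/10, i/10)$, last bin closed) and summarized by per-bin medians
(`bin_medians()`); a bin left empty by sparse sampling is an error,
not a silent NA. The headline statistic is the sub-polar/equator
ratio, $\mathrm{mean}(m_3, m_8)/\mathrm{mean}(m_5, m_6)$
(`region_ratio()`), which is symmetric under profile reversal — so no
orientation convention is needed — and groups are compared with the
two-sided Wilcoxon rank-sum test (`compare_groups()`), exact when the
combined sample size is at most 20 with no ties, normal approximation
with tie correction otherwise.

The image generator renders the spindle as a plateau with Gaussian
pole peaks (height set by `pole_enrichment`, per-pole attenuation by
`pole_asymmetry` for weak/missing poles) times a radial Gaussian
envelope, plus cytosol background and pixel noise. A multiplicative
window centred on 25% and 75% of the axis (`subpolar_scale`) thins the
sub-polar regions specifically, which is the knob used to emulate a
mutant with reduced pole-proximal microtubule density. The measured
region ratio is monotone in that knob (property-tested). The
generator's simplifications — no point-spread function, no spindle
curvature, no chromatic offset — mean profile tests validate the
measurement chain, not optical realism.

## Pole intensity and chromosome congression

Pole accumulation is measured from two user-drawn ROIs on the
projection: a large one ($I_1$ summed over $N_1$ pixels) spanning
spindle plus cytosol and a small one ($I_2$, $N_2$) tightly covering
the two poles. The background per pixel is
$b = (I_1-I_2)/(N_1-N_2)$ and the reported value is the per-pixel
pole intensity above background, $I_2/N_2 - b$. The widely quoted
one-line form "$I_2-(I_1-I_2)/(N_1-N_2)$" subtracts one pixel's
background from a summed intensity and is dimensionally inconsistent
with a per-pixel quantity; `pole_intensity(per_pixel = FALSE)` computes
that literal form for comparison, but the per-pixel reading is the
default and the one used throughout. The statistic cancels any
constant offset added to the image exactly (tested).

Chromosome spread is the axial extent of the chromosome mass:
threshold the chromosome channel (Otsu on the normalized channel by
default; a half-maximum threshold is available and is what the
generator's blob geometry is calibrated against), label connected
blobs, optionally drop blobs under 10% of the largest blob's area (a
proxy for excluding the small 4th chromosome), project the remaining
mask pixels onto the pole-to-pole axis, and report
$(\max - \min) \times$ pixel size. Projection onto the axis makes the
measure rotation-equivariant to within a pixel of discretization.

`congression_correlation()` is the Pearson correlation of spread
against $\ln$(pole intensity) with a t-distribution p value; the base
of the logarithm is immaterial to $r$ (tested to machine precision).
The congression generator draws lognormal intensities and sets
`spread = intercept + slope * ln(intensity) + noise`. Rather than grid
search, the noise is calibrated in closed form: for the target
population correlation $\rho$,
$\sigma_\varepsilon = |b|\,\sigma_{\ln A}\sqrt{1/\rho^2 - 1}$
(`calibrate_congression_noise()`), with defaults (slope $-1$ µm per
log-unit, $\sigma_{\ln A} = 1$, intercept 9 µm) chosen to give spreads
in the observed 2–10 µm range around $\rho = -0.772$. The sample
correlation at $n = 26$ is mildly attenuated toward zero
($\mathbb{E}[r] \approx \rho(1 - (1-\rho^2)/2n)$), which the
acceptance suite accounts for when averaging replicates.

## Numerical choices and problem sizes

Reproducibility is a contract: every generator takes a seed, derives
per-item sub-seeds deterministically, and leaves the global RNG state
untouched; fixed seeds give bitwise-identical outputs, and
`run_pipeline()` threads one master seed through all stages and embeds
the resolved configuration in its report. The test and demonstration
problem sizes — 15 traces per FRAP study (11 for the embryo regime),
48 images per profile group, $n=26$ congression records with 1000
replicates for calibration checks, 50 random draws for the noise-free
fitting oracle — are the study sizes the analyses are designed around,
and they keep the full suite comfortably fast on a laptop.

## Limitations

* FRAP is modelled as well-mixed exponential exchange; no
  diffusion-reaction kinetics, bleach-spot geometry, or spatial
  recovery modelling.
* Normalized recovery is fit by unweighted least squares on the pooled
  mean; per-point SEMs are computed but not used as weights (they are
  nearly homoscedastic in the regimes covered).
* A fast half-time near the sampling interval (8 s vs 5 s frames) is
  recovered with wide relative spread — of order ±25% from 15 noisy
  traces — because only the first few frames constrain it. Slow
  fractions and slow half-times are much tighter.
* Pole coordinates and ROI masks are inputs, as in manual analysis;
  the package does not segment spindles.
* The image generator is a measurement-chain fixture, not an optics
  simulator.
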