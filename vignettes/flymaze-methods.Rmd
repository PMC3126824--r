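---
title: "Models and methods behind flymaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flymaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flymaze)
```

`flymaze` models a population visual-psychophysics assay: flies walk through
an 8-junction binary-choice maze over a screen displaying wide-field motion,
and their distribution over the nine exit tubes measures how strongly they
follow the motion. This vignette explains the models, the parameters that
matter, and the design choices made where the paradigm leaves the details
open.

## Stimulus rendering

All stimulus parameters are physical (visual degrees, seconds); a single
`screen_geometry()` object converts to pixels and frames. The default —
640 × 480 px at 2 px/degree and 60 Hz — makes the screen 320° × 240° of
visual field, appropriate for a wide-field stimulus viewed from very close.
Velocities quoted in pixels/s elsewhere convert through `pixels_per_degree`.

**Gratings** are square waves: every pixel is exactly the foreground or
background colour, matching a two-colour bar stimulus rather than a
sinusoid. The phase advances by `velocity * spatial_frequency / frame_rate`
cycles per frame; temporal frequency is always *derived* as
`sf * |v|` (`derive_temporal_frequency()`), never taken as an independent
input, because only two of the three drift parameters are free. A grating
whose period falls below 2 px is rejected as unrepresentable rather than
aliased silently.

**Random-dot kinematograms.** A fraction `coherence` of dots (the signal
dots) translate along the signal direction; every other dot moves at the
same speed along its own uniform-random direction, redrawn when the dot
respawns. This "random-direction" noise rule is the simplest kinematics
consistent with describing coherence as the fraction of dots moving
coherently; a per-frame random-walk rule would destroy noise-dot motion
energy at the dot scale and is not used. Dot ages are initialized uniformly
over the lifespan so respawning is desynchronized (no population-wide
flicker); expired dots reappear at uniform-random positions with age 0,
keeping the rendered dot count constant. Positions wrap toroidally, keeping
density constant at the edges. Square dots are rasterized to *exactly* the
pixel count of the circle of the same nominal diameter (smallest covering
square, trimmed corner-first), so shape manipulations never change the
stimulus area.

**Combined competition stimuli** draw the dots opaquely over the grating;
the dot direction is the grating direction rotated by one of the eight
45°-spaced relative directions. The grating direction is horizontal by
construction (the maze's choice axis), so `relative_direction_deg` is the
single degree of freedom.

**Synthetic textures** stand in for natural scenes, whose defining spectral
feature is high energy at low spatial frequencies. White noise is shaped in
the frequency domain and min–max rescaled to [0, 255], then translated
rigidly with toroidal wrap. The shaping filter acts on *horizontal*
frequencies only (`|f_x|^(-exponent/2)` on the amplitude): because the
regularity metric below analyses pixel rows, a horizontal-only filter makes
the measured log-power fall with slope exactly `-exponent`, including the
white-noise limit at exponent 0. A radially isotropic filter would not: a
row of a 2-D isotropic field integrates power over vertical frequencies,
which shifts the measured slope by one. This is a deliberate choice to make
the generator's single parameter mean exactly what the analysis measures.

## Image regularity

Movies are scored frame by frame: each frame is converted to luminance (the
unweighted channel mean — the stimuli are synthetic, so perceptual channel
weighting would add a constant with no discriminative value), each pixel row
is Fourier transformed, and the power of bin *k* is `|F_k|^2 / width` in
cycles per image width. Averaging over *all* rows (rather than one scan
line) reduces variance without changing the expectation for these
horizontally structured stimuli; a `rows` argument restores the single-line
variant. The movie's score is the **non-DC peak** of the frame-averaged
spectrum: the DC bin is mean luminance, and excluding it is what makes the
metric measure *structure* — it is invariant to global luminance offsets and
to horizontal translation (motion changes phase, not power), and scales
quadratically with pattern contrast. The normalization constant is
arbitrary but fixed; all downstream use (the salience map and the
meta-analysis) needs only a consistent scale.

## The maze model

Each counted fly makes 8 independent Bernoulli(*p*) choices toward the
stimulus; the exit tube is (#toward − #away)/2, so tubes follow a
Binomial(8, *p*) shifted to −4..+4 and

> E[VR] = 4(2p − 1).

Independence per junction is the null behavioural model: the assay reports
population outcomes only, and single-fly runs are described as behaving like
group runs, so no within-maze correlation is introduced. Fly loss is a
pre-choice Bernoulli exclusion (lost flies are loaded but never counted),
independent of choice behaviour, defaulting to 5%. Defaults of 25
flies/maze and 8 mazes per experiment reproduce the paradigm's ~200 flies
per data point.

The psychometric link is a saturating exponential,
`p = 0.5 + (p_max − 0.5)(1 − exp(−gain · salience)) + asymmetry`, clamped to
[0, 1]: zero salience gives chance performance, and the per-junction bias
saturates at the strain's ceiling `p_max`. The baseline asymmetry is a
stimulus-*independent* bias toward one absolute side; experiments are always
direction-balanced (half the mazes with mirrored stimulus motion,
sign-corrected before pooling), which cancels such asymmetries in
expectation — a property the tests verify directly. `paradigm_strains()`
provides two reference parameter sets calibrated so the standard grating
yields expected VRs near 0.5 (wild type) and 1.5 (the hyper-responsive
mutant-like set), the baseline magnitudes of the paradigm.

In `run_pipeline()`, salience is the movie's peak power times
`salience_scale`, which defaults to `4 / (width · 127.5²)` — i.e. peak power
normalized by that of a full-contrast sinusoid — giving a dimensionless,
order-1 salience. `estimate_p()` inverts the binomial model
(`p̂ = (m/4 + 1)/2` from the direction-corrected mean tube index *m*) with a
Wald interval over the `8 × flies` junction choices.

## Statistics

The maze — not the fly — is the statistical unit throughout: per-maze VRs
are averaged and the s.e.m. is taken across mazes, matching how maze counts
are reported (N = mazes). Mazes with zero counted flies are excluded with a
message, never scored as 0, which would bias toward the null.

**Normality gate.** VR samples are screened with the Lilliefors test: a KS
statistic against a normal with estimated mean and s.d., whose null
distribution is *simulated* (10⁴ replicates by default) rather than read
from approximation tables — reproducible, table-free, and exact up to Monte
Carlo error. The null depends only on the sample size, so it is generated
once per size under an internal fixed seed and cached; the caller's RNG
state is never touched. The gate is applied at α = 0.05. Samples passing it
get t-tests (one-sample vs 0, or Welch two-sample between strains);
failures get the Wilcoxon signed-rank or Mann–Whitney U test. Samples too
small to screen (n < 5) default to the t-test; constant samples are handled
as degenerate cases (a constant 0 is trivially null, a constant non-zero
trivially non-null).

**ANOVA letters.** Parameter sweeps are compared by one-way ANOVA; when the
omnibus test is significant, all-pairs Tukey HSD comparisons at the same
level feed a compact letter display (insert-and-absorb), so groups sharing
a letter are not significantly different. Tukey HSD is the standard
procedure for all-pairs letter displays; the multiple-comparisons method in
the original workflow is unspecified.

**Meta-analysis fits.** `meta_fit()` fits VR against peak spectral power by
OLS, quadratic or linear. Its reported "correlation" is defined — and this
is a documented choice, since such legends are often ambiguous — as the
Pearson r between observed and fitted values, which for the linear model
equals |r(x, y)|, with a two-sided p-value.

## Numerical and testing choices

Tolerances: noiseless polynomial recovery is checked to 6+ significant
digits; Parseval's identity to 1e−9 relative error; stochastic checks use
3-standard-error bands at fixed seeds. Problem sizes in the test suite are
chosen for precision at interactive speed: 2⁸-path exhaustive enumeration as
the VR oracle, 1000 mazes × 25 flies for Monte-Carlo agreement, 100
replications for CI coverage (nominal 95%, required ≥ 93), 1000 replications
for type-I calibration of the VR-vs-zero test at α = 0.01 and of the
Lilliefors test at α = 0.05, and 100 seeds for recovering texture spectral
slopes within ±0.2.

Degenerate inputs are rejected loudly rather than patched: zero-width
gratings below pixel resolution, sub-pixel dots, empty mazes, rank-deficient
meta-fit designs, and zero-variance correlation inputs all raise or flag.

## What the simulator does and does not show

The generator emulates the *statistical skeleton* of the assay: multinomial
tube counts from sequential binary choices, direction balancing, fly loss,
and strain-dependent stimulus coupling. Passing tests therefore validate the
scoring, inference and calibration machinery, and the internal consistency
of the stimulus–salience–behaviour chain. They do not validate the
biological link between any real stimulus and real flies: the psychometric
link is a modelling convenience (real dose–response curves need not be
saturating-exponential in peak power), junction choices in real mazes may be
serially correlated, and the synthetic texture reproduces a natural scene's
spectral envelope, not its edges, objects or higher-order statistics.
Absolute spectral power values depend on the documented normalization and
geometry and are comparable only within a fixed configuration.
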