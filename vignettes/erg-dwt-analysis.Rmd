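---
title: "Haar wavelet descriptors of the flash ERG: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haar wavelet descriptors of the flash ERG: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergdwt)
```

## The problem

The light-adapted flash electroretinogram (ERG) is the retina's mass
electrical response to a brief flash: a small negative a-wave
(photoreceptor-dominated), a larger positive b-wave (bipolar-cell
dominated), and a burst of high-frequency oscillatory potentials (OPs,
roughly 80–160 Hz, attributed mainly to amacrine cells) riding on the
b-wave's rising limb. Group differences in neurodevelopmental
conditions have been reported in time-domain ERG measures; a
time-frequency decomposition can separate the ON/OFF-pathway
contributions (slow bands) from the OP generators (fast bands) and so
localize *which* retinal circuit differs.

`ergdwt` implements that analysis as a reusable, tested pipeline:

1. simulate (or read) cohorts of flash-ERG epochs,
2. preprocess (sweep averaging with centile rejection, QC, resampling),
3. decompose each epoch with the orthonormal Haar discrete wavelet
   transform (DWT) and extract band/window energy descriptors,
4. compare groups with nonparametric Tukey-type multiple contrast
   tests on relative effects.

## The descriptors

For an epoch $x(t)$ sampled at 2048 Hz on $[-20, 105)$ ms (256
samples, flash onset at 0 ms), the full dyadic Haar decomposition
yields detail coefficients $d(j,k)$, the inner products of the signal
with dilated/translated Haar functions. Level $j$ spans the octave
$f_s/2^{j+1}$–$f_s/2^j$ Hz; at 2048 Hz, levels 6, 5, 4, 3 are the
octaves 16–32, 32–64, 64–128 and 128–256 Hz, which bracket the nominal
band centers 20, 40, 80 and 160 Hz. Each coefficient owns a dyadic
time segment of $2^j$ samples; the segments of one level tile the
epoch.

Six descriptors summarize the scalogram in physiologically motivated
(band, time-window) cells, with a coefficient assigned to a window iff
its segment midpoint lies inside the closed interval:

| descriptor | band (Hz) | window (ms) | reading |
|---|---|---|---|
| a20 | 20 | $[-20, 17.5]$ | generalized ON-response around the a-wave |
| a40 | 40 | $[0, 17.5]$ | OFF-pathway contribution to the a-wave |
| b20 | 20 | $[17.5, 55]$ | ON-pathway contribution to the b-wave |
| b40 | 40 | $[17.5, 55]$ | OFF-pathway contribution to the b-wave |
| op80 | 80 | $[8.125, 55]$ | slow oscillatory potentials |
| op160 | 160 | $[8.125, 55]$ | fast oscillatory potentials |

The a20 window deliberately begins 20 ms before flash onset; we adopt
that convention literally. The OP percentage is
$\%\mathrm{OPs} = 100\,(op80 + op160)/(b20 + b40 + op80 + op160)$,
undefined when the denominator is zero. Time-domain features are
measured conventionally: baseline = mean of pre-stimulus samples,
a-amplitude baseline-to-trough (trough searched in 5–25 ms),
b-amplitude trough-to-peak (peak searched up to 60 ms); both are
DC-invariant.

**Aggregation mode.** A window holds several coefficients, and
"energy" admits more than one reading. The package offers three:
root-sum-of-squares (`rss`, the default), maximum absolute coefficient
(`max_abs`), and sum of absolute values (`sum_abs`). We default to
`rss` for a reason worth stating: the dyadic DWT is *shift-variant* —
translating a signal by a fraction of a segment redistributes energy
between neighboring coefficients and even between adjacent levels. A
single-coefficient maximum inherits that instability, and with
physiological latency jitter of only ±1 ms the maximum-based OP
descriptors fluctuate by 20–35% between otherwise identical
recordings. Summing squared coefficients over the window pools the
redistributed energy back together and is far more stable, while
agreeing with the maximum up to a monotone rescaling for
single-component windows. All three modes satisfy positive
homogeneity (doubling the waveform doubles every descriptor), so the
rank-based group tests are unaffected by the choice whenever the
waveform shape is common across groups.

## The synthetic cohort generator

The generator exists so every downstream stage is testable without any
data download; its defaults are the study conditions the tests run
under.

A noiseless epoch is
$$x(t) = -A_a\,g(t; t_a, w_a) + A_b\,g(t; t_b, w_b) + A_{op}\,e^{-\tau/\lambda}\,
\frac{\sin(2\pi f \tau) + 0.6 \sin(2\pi \cdot 1.5 f \tau)}{1.6}\,\mathbb{1}[\tau \ge 0],$$
with $g$ a unit-peak Gaussian kernel and $\tau = t - t_{op}$. Defaults:
$A_a = 12$, $t_a = 15$ ms, $w_a = 3.5$ ms; $A_b = 28$, $t_b = 32$ ms,
$w_b = 9$ ms; $A_{op} = 26$, $f = 120$ Hz, $t_{op} = 15$ ms,
$\lambda = 40$ ms; white noise SD 1 µV (a 60-sweep average of ~8 µV
single-sweep noise). These were chosen once so that (i) the photopic
a-trough is clearly measurable (~7–8 µV, comfortably above the 1 µV
inclusion rule), (ii) the b-wave's rising slope — which the broadband
Haar filters see strongly in the 64–256 Hz levels — does not drown
the OP contribution in the OP bands, and (iii) descriptor magnitudes
land in the tens-of-µV·s range reported for real cohorts.

The OP burst is a *slow + fast pair* (120 and 180 Hz under a shared
envelope) rather than a single carrier. A single 120 Hz tone leaves
the 128–256 Hz band populated by spectral leakage alone, and because
of shift-variance that leakage is extremely sensitive to burst
latency: in simulation the op160 descriptor of a single-tone burst had
a between-participant CV of 25–35% under 1 ms latency jitter, which
swamps any plausible group effect. The two-component burst mirrors
the slow/fast OP distinction seen in photopic recordings and places
genuine mid-band energy in both OP bands.

Cohorts add, per participant, independent Gaussian jitter (SD 1 ms) to
the three component times and independent log-normal jitter (SD ~10%)
to the three amplitudes, fixed across that participant's flashes and
eyes; the two eyes are independent noise replicates. Flash strength
acts as a multiplicative luminance gain (default 0.6, 0.85, 1.0, 1.05,
1.0 across the five flashes — a shallow photopic-hill profile; flashes
are analyzed as separate strata, so no Naka–Rushton fit is attempted).
Group effects are multiplicative presets on $(A_a, A_b, A_{op})$:
controls $(1,1,1)$; ADHD $(1.2, 1.5, 1.4)$ — broadband elevation; ASD
$(1.0, 1.0, 0.8)$ — reduced OPs with a near-control b-wave.

What the generator does *not* emulate: line interference and
non-Gaussian artifacts, baseline drift, inter-eye correlation,
iris-color and electrode-height effects on amplitude (these are
carried as metadata and an exclusion rule only, as in the source
protocol), age effects, and any biophysical nonlinearity. Passing
tests therefore demonstrate that the pipeline recovers effects of the
assumed multiplicative form under realistic jitter and noise — not
that real cohorts satisfy those assumptions.

## Preprocessing rules

* **Sweep rejection**: a sweep is kept iff its peak-to-peak amplitude
  lies in the inclusive [25th, 75th] percentile band of the sweep set,
  computed with inverse-ECDF (type 1) quantiles so the band is
  delimited by observed sweeps. The underlying acquisition rule is
  stated ambiguously in the field ("above or below the 25th centile");
  the interquartile reading is the only one that rejects both high and
  low outliers while using the 25th centile, and we apply it per sweep
  (not per time point). At least 4 sweeps are required.
* **QC**: a recording is excluded iff its measured a-wave amplitude is
  ≤ 1 µV, or its electrode sits more than 2 mm below the reference
  position (−2 mm is still included; missing metadata never excludes).
  QC is a pure per-recording predicate.
* **Resampling**: linear interpolation onto the dyadic analysis grid
  (256 samples at 2048 Hz from −20 ms), with no extrapolation. The
  grid is a package convention: a power-of-two epoch that covers every
  descriptor window with margin; the acquisition rate of the source
  instrument is not published, and 2048 Hz keeps all bands of interest
  far below Nyquist. Band-limited peaks survive within 1%.

## Group comparison

For each flash × parameter we report per-group medians with
distribution-free 95% confidence intervals from binomial order
statistics (conservative coverage; endpoints are observed values), and
an all-pairs (Tukey-type) nonparametric multiple contrast test:

* per contrast $(i,j)$, the pairwise relative effect
  $\hat p_{ij} = \hat P(X_i < X_j) + \tfrac12 \hat P(X_i = X_j)$,
  estimated by midranks (exactly the enumeration estimate);
* rank-based plug-in variances (Brunner–Munzel type) and a
  DeLong-style placement covariance between contrasts sharing a group;
* simultaneous inference from the equicoordinate quantile of a
  multivariate $t$ over the estimated contrast correlation matrix,
  with Satterthwaite-type degrees of freedom (the smallest per-contrast
  value); the multivariate probabilities use quasi-Monte-Carlo
  integration at tolerance $10^{-4}$ under an internal fixed seed, so
  runs are reproducible and the caller's RNG is untouched;
* test statistics on the probability scale; confidence limits built on
  the half-logit (Fisher) scale and back-transformed, after half-count
  shrinkage of boundary estimates (the transformation is undefined at
  0 and 1). If every observation in the study is identical the result
  is flagged degenerate with $\hat p = 0.5$, $p = 1$.

Two significance readings are reported side by side, as in the source
analysis: the multiplicity-adjusted p-value against `alpha` (default
0.05) and a stringent fixed cut-off (default $p < 0.005$).

Classical tests are delegated to base R (`kruskal.test`,
`wilcox.test` with tie-corrected normal fallback, `chisq.test` without
continuity correction); the robust percentage-bend correlation
(bending constant $\beta = 0.2$) is implemented directly following
Wilcox's estimator, since no installed package provides it.

Eyes are aggregated per participant before testing; the default is the
mean of the two eyes' feature values. The source protocol records
both eyes but states no pooling rule, so the rule is configurable
(`right_only`, `left_only`, or `both_as_units`, the last inflating n
and flagged non-default).

## Numerical and degenerate-input choices

* Haar filters are orthonormal; Parseval and perfect reconstruction
  are maintained to ≤ 1e−9 relative and checked in the tests.
* Coefficient-to-window assignment uses segment midpoints against
  closed windows; on the dyadic grid midpoints can never hit a window
  edge, so ties are impossible.
* Empty descriptor windows yield 0 with a warning rather than an
  error.
* `%OPs` with a zero denominator is `NA`, not an exception.
* Degenerate contrasts (zero plug-in variance under complete
  separation) receive a variance floor from the shrunk estimate so the
  statistic stays finite and decisive.
* Order-statistic median CIs below n = 6 cannot reach 95% coverage;
  the full range is returned with a warning.

## Problem sizes used by the tests

The test suite runs entirely on synthetic data: DWT oracle checks on
exhaustive short signals (lengths 8–32) plus 1000 random length-256
epochs; familywise-error calibration on 2000 null replicates of three
groups of 20; effect recovery on 100 seeded cohorts of 50 per group at
the strongest flash. These sizes give Monte-Carlo standard errors
well inside the asserted bands (e.g. ±0.005 on a FWER of 0.05 over
2000 replicates) and are the package's reference scales for the
claims above.

## Known limitations

* Printed %OPs values in the literature that motivated the descriptor
  set are not reproducible from the published descriptor medians via
  the stated formula; the formula is implemented as stated, and the
  alternative aggregation modes allow exploring the discrepancy.
* Descriptor units are labeled µV·s for parity with the field's
  reporting; no dimensional calibration of the discrete transform is
  attempted, so absolute magnitudes are comparable only within a
  fixed grid and mode.
* The Haar wavelet is the only wavelet implemented; the shift-variance
  discussed above is intrinsic to it and is the main reason the `rss`
  aggregation is the default.
* No covariate modeling (iris color, electrode height, age, sex) —
  these remain metadata with one exclusion rule, as in the source
  protocol.

## A worked example

```{r example, eval = FALSE}
spec <- cohort_spec(group_sizes = c(ASD = 20, ADHD = 20, control = 20),
                    flash_strengths = 1.204, luminance_gain = 1, seed = 1)
res <- run_study(study_config(cohort = spec, seed = 1))
res$results[res$results$parameter %in% c("b20", "op80", "op160"),
            c("parameter", "ASD_median", "control_median", "ADHD_median",
              "p_control_v_ASD", "p_control_v_ADHD")]
```

See the README for the printed output of this example and for how to
regenerate the headline numbers with `scripts/acceptance.R`.
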