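# ergdwt

Time-frequency analysis of the light-adapted flash electroretinogram
(ERG) with the Haar discrete wavelet transform, for researchers
studying retinal signaling differences between clinical groups (e.g.
neurodevelopmental conditions) and for anyone who needs a tested,
reproducible implementation of DWT-based ERG descriptors and the
accompanying nonparametric group statistics.

## What it computes

A flash-ERG epoch `x(t)` (µV vs ms, flash onset at 0 ms) is decomposed
with the orthonormal Haar DWT,

```
DWT(j, k) = < x , 2^(-j/2) ψ(2^(-j) t - k) > ,
```

where level `j` covers the octave `fs/2^(j+1)`–`fs/2^j` Hz and
coefficient `k` owns a dyadic time segment. On the 2048 Hz analysis
grid (256 samples from −20 ms) the levels bracket the nominal band
centers 20, 40, 80, 160 Hz. Six descriptors summarize the scalogram
energy in band × time-window cells —

* `a20` (20 Hz, −20…17.5 ms) and `a40` (40 Hz, 0…17.5 ms): ON- and
  OFF-pathway contributions around the a-wave,
* `b20`, `b40` (20/40 Hz, 17.5…55 ms): ON/OFF contributions to the
  b-wave,
* `op80`, `op160` (80/160 Hz, 8.125…55 ms): slow and fast oscillatory
  potentials,

plus `%OPs = 100·(op80+op160)/(b20+b40+op80+op160)` and the
time-domain a-wave (baseline-to-trough) and b-wave (trough-to-peak)
amplitudes. Groups are compared per flash strength and parameter with
an all-pairs (Tukey-type) nonparametric multiple contrast test on
relative effects `P(X_i < X_j) + ½P(X_i = X_j)` — pseudo-rank
estimates, simultaneous multivariate-t confidence intervals on the
Fisher (half-logit) scale, multiplicity-adjusted p-values, and a
stringent fixed cut-off (p < 0.005) reported alongside. A synthetic
cohort generator with per-group effect multipliers makes the whole
pipeline testable end to end without any data download.

See `vignette("erg-dwt-analysis")` for the model, the design
decisions and their rationale.

## A worked example

```r
library(ergdwt)

spec <- cohort_spec(group_sizes = c(ASD = 20, ADHD = 20, control = 20),
                    flash_strengths = 1.204, luminance_gain = 1, seed = 1)
res <- run_study(study_config(cohort = spec, seed = 1))
res$results[res$results$parameter %in% c("b20", "op80", "op160"),
            c("parameter", "ASD_median", "control_median", "ADHD_median",
              "p_control_v_ASD", "p_control_v_ADHD")]
#>   parameter ASD_median control_median ADHD_median p_control_v_ASD p_control_v_ADHD
#> 1       b20       70.9           65.2        85.5        4.92e-01         1.44e-07
#> 2      op80       55.7           67.4        89.2        8.55e-07         0.00e+00
#> 3     op160       45.2           53.8        71.4        2.19e-09         0.00e+00
```

The medians are descriptor energies (µV·s-labeled units) per group at
the 1.204 log photopic cd·s·m⁻² flash; the trailing columns are
multiplicity-adjusted p-values for the control-vs-ASD and
control-vs-ADHD contrasts. The simulated ASD group (OP amplitude
preset 0.8×) shows the characteristic pattern: clearly reduced OP-band
energies (tiny p-values) with a statistically indistinguishable b20,
while the simulated ADHD group (b-wave 1.5×, OPs 1.4×) is elevated
everywhere. `render_report(res, "markdown", "table1.md")` lays the
full table out with group column blocks and trailing contrasts.

A thin command-line wrapper ships in `inst/scripts/erg-dwt`
(`simulate`, `extract`, `compare`, `report` subcommands).

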