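---
title: "Cycle-wise DFA of gait signals: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cycle-wise DFA of gait signals: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdfa)
```

## The measurement problem

A gait laboratory record couples two views of the same motor act:
surface EMG of the shank muscles (tibialis anterior driving dorsiflexion
and foot clearance; lateral gastrocnemius driving push-off) and
foot-pressure (FSR) traces that mark when each foot is loaded. Classical
spatiotemporal gait parameters average over strides; detrended
fluctuation analysis (DFA) instead asks how fluctuations scale with time
within the signal, summarizing long-range temporal correlation in a
single exponent α per series. Applying DFA *per gait cycle* and *per
channel* yields a distribution of exponents per participant that can be
compared across groups.

## The DFA estimator

For a series $x_1,\dots,x_N$ the profile is the centered cumulative sum
$Y(k)=\sum_{i\le k}(x_i-\bar x)$. For a window size $n$ the profile is
cut into $\lfloor N/n\rfloor$ non-overlapping windows anchored at the
first sample; within each window an ordinary-least-squares line is
subtracted; and

$$F(n)=\sqrt{\tfrac{1}{N'}\textstyle\sum_k (Y(k)-Y_{trend}(k))^2},\qquad
N'=\lfloor N/n\rfloor\, n ,$$

where the trailing remainder enters neither the sum nor the count — the
minimal consistent reading of a single global RMS over equal-length
windows (a both-ends variant exists in the literature and is
deliberately not implemented). α is the unweighted OLS slope of
$\log_{10}F(n)$ on $\log_{10}n$. Benchmarks: α ≈ 0.5 for uncorrelated
noise, α > 0.5 persistent, α < 0.5 anti-persistent, and integration
raises α by 1, so Brownian-like signals sit near 1.5.

### Numerical choices

* **Window grid.** ~20 log-spaced integer sizes in $[16, N/4]$. The
  lower bound limits the small-window bias of linear detrending; the
  upper bound keeps at least four windows in every $F(n)$. The grid is a
  free parameter of any DFA implementation; exponents shift by a few
  hundredths under alternative grids, which is why per-subject published
  values can only be matched approximately.
* **Detrending.** Linear (order 1) only; the polynomial order exists as
  an argument for forward compatibility but higher orders are rejected.
* **Residuals are computed explicitly** (window-centered values minus
  the fitted line) rather than via the algebraic shortcut
  $S_{yy}-S_{ty}^2/S_{tt}$, which loses ~8 significant digits to
  cancellation on large-mean profiles and turns the exact-zero case
  (profile linear in every window) into $10^{-7}$-level noise.
* **Degenerate sizes.** $n < 4$ is rejected ($n\le 2$ has identically
  zero residuals under a line); sizes with $F(n)=0$ are dropped from the
  log–log fit with a warning; fewer than four usable sizes is an error.
* **Cycle length.** At 1500 Hz a stride spans ~1500–2000 samples, so
  per-cycle grids reach $n\approx 400$. Cycles shorter than 256 samples
  are flagged `excluded_short` and kept in the output table rather than
  silently dropped.
* α is exactly affine-invariant ($F$ scales by $|a|$; the log–log slope
  is unchanged), which the suite asserts at $10^{-9}$.

## Signal conditioning

EMG: 4th-order Butterworth bandpass, 20–450 Hz, applied
forward–backward. "4th order" names the per-pass design, so the
zero-phase cascade has an effective 8th-order magnitude response; the
alternative reading (2nd order per pass) is available through
`filter_spec(order = 2)`. The design goes analog prototype →
lowpass-to-bandpass transform → bilinear transform with prewarping; no
DSP dependency is available in the target environment, so the
coefficients are computed in-package (they agree with standard
references to ~1e-15). Edge transients are suppressed by odd
(point-reflected) padding of at least three low-cutoff periods with zero
initial filter state. Rectification is $|\cdot|$; normalization divides
by the maximum of the rectified *trial*, never per cycle, so relative
burst amplitude across cycles is preserved.

FSR: min–max scaling to $[0,1]$, applied per 15 s analysis window so
the detection threshold adapts to slow drift. The dynamic threshold is
$(\min+\max)/2$ — exactly 0.5 after scaling, but stated on the range so
detection commutes with affine rescaling.

## Segmentation

Heel strikes are rising edges through the threshold
(`x[i] >= thr & x[i-1] < thr`; a plateau yields one strike at its first
sample), filtered by a greedy keep-first refractory rule with a 0.5 s
minimum inter-strike interval. Cycles are half-open `[strike_i,
strike_{i+1})`, 0-based, and all channels are sliced with identical
indices. By default each leg is segmented from its own foot
(`per_leg_fsr`); a `right_fsr_for_all` switch reproduces the variant in
which right-foot events segment every channel, since both conventions
appear in practice.

The 15 s windowing interacts with segmentation at window boundaries:
cycles spanning a boundary are not formed (each window is segmented
independently), which discards at most one cycle per window boundary.
This is logged via the per-window cycle counts rather than patched
across windows, keeping windows independent units of work.

## The synthetic stated world

The generators define the conditions under which the pipeline is tested:

* **fGn/fBm** via exact circulant (Davies–Harte) embedding of the target
  autocovariance $\gamma(k)=\tfrac{\sigma^2}{2}(|k{+}1|^{2H}-2|k|^{2H}+|k{-}1|^{2H})$.
  Exactness makes Hurst-recovery tests sharp: mean $|\hat\alpha-H|$ at
  $N=8192$ is ≤ 0.03 across $H\in[0.3,0.9]$, within the 0.05 band the
  tests assert. Negative FFT eigenvalues cannot occur for fGn in theory;
  tiny numerically negative values are clamped with a warning (an
  `"error"` mode exists).
* **Synthetic gait**: stance is a raised-cosine pulse occupying 60% of a
  1.1 s mean stride (preferred-pace walking), stride durations jittered
  by a truncated Gaussian (sd 0.02 s, cut at ±3 sd so the 0.5 s
  refractory bound stays satisfiable by construction); the left foot is
  offset half a stride. EMG channels are 20–450 Hz bandlimited noise
  amplitude-modulated by phase-locked envelopes (tibialis peaking
  mid-swing, gastrocnemius in late stance). Defaults: `noise_sigma =
  0.02` against a unit plateau; robustness tests run at 0.05.
* **Edge geometry matters.** Loading and unloading edges are ~2 ms
  raised cosines and the additive sensor noise is band-limited (white
  noise smoothed by a ~5 ms moving average, rescaled to marginal sd
  `noise_sigma`). Both choices are physically motivated — foot-switch
  FSRs switch in milliseconds and front-end electronics are low-pass —
  and both are load-bearing: with ramps proportional to stance duration
  the mid-ramp threshold crossing lags the true onset by tens of
  milliseconds, and with sample-wise white noise the slow unloading edge
  re-crosses the threshold outside the refractory window, producing
  spurious strikes no parameterization of the stated detector can
  reject. A green segmentation suite therefore establishes correctness
  of the detector *for switch-like pressure signals*, not robustness to
  arbitrarily slow-loading insoles.
* **No group effect is simulated.** There is no credible generative
  model of how training reshapes α, so cohort simulations are
  exchangeable across group labels; group-statistics tests instead
  inject known mean shifts directly into α samples. A green ANOVA suite
  establishes calibration and power of the test, not any physiological
  claim.

## Group statistics

Per-cycle exponents are pooled per (group × channel) cell and compared
by one-way ANOVA computed from the explicit sum-of-squares
decomposition, with Tukey HSD (Tukey–Kramer under unequal n) post hoc
comparisons gated at the omnibus p < 0.05 (Bonferroni available; the
gate can be forced open). Two units of analysis are provided: `cycle`
(each cycle one observation — matches per-cycle box-plot practice but
inflates n because cycles within a record are dependent) and `record`
(per-record mean α, one observation per record). The default is `cycle`;
the choice is surfaced in the config precisely because the literature is
usually silent about it. No outlier filtering is applied by default:
degenerate cycles can produce extreme α (even negative), and they are
retained and traceable via `r_squared` and `status` in the output table.

## I/O and reproducibility

WFDB support covers single-file format-16 records (16-bit little-endian
interleaved ADC counts with gain/baseline scaling) — sufficient for
round-tripping the synthetic writer and for typical physiological
archives in that format; other formats are rejected with a clear error
rather than mis-read. The CSV fallback is a header row of channel names
plus an optional `# fs=<Hz>` line. Channel names resolve to roles via a
case-insensitive substring table (`default_role_map`) that the caller
can replace; unresolvable or duplicated names are errors listing the
offending channels. Analysis is deterministic; all simulation randomness
descends from explicit seeds, and every generator saves and restores the
global RNG state. Runs write a JSON manifest (package version, seed,
config echo) sufficient to reproduce the output byte for byte.

## Known limitations

* Per-subject published exponents cannot be matched exactly without the
  original window grid and cycle identity; only distribution-level
  behaviour is reproducible.
* Multi-segment or multi-.dat WFDB records, toe/heel split FSR
  channels, and WFDB annotation files are unsupported.
* DFA assumes the within-cycle series is long enough for ~20 scales;
  very short cycles are excluded rather than estimated badly, which can
  bias cycle counts for fast cadences at low sampling rates.
* The cycle-level ANOVA ignores within-record dependence; use
  `anova_unit = "record"` when records, not cycles, are the exchangeable
  unit.
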