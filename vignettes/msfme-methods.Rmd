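---
title: "Multiscale fuzzy measure entropy for EEG/ECG recovery analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale fuzzy measure entropy for EEG/ECG recovery analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msfme)
```

## The problem

After an acute bout of coordinatively demanding exercise, the irregularity
of resting-state brain (EEG) and heart (ECG) signals changes over the
recovery minutes, and the two may change together. This package quantifies
that irregularity with **multiscale fuzzy measure entropy (MSFME)**, tracks
it per post-exercise minute relative to a pre-exercise baseline, compares
recovery trajectories across training conditions, and measures brain–heart
coupling as the rank correlation between the two entropy trajectories.

The design it targets: 19-electrode EEG (international 10–20 montage) plus
one ECG lead, synchronized, with a resting block before exercise (baseline)
and a resting block after it; several training conditions (DL0, DL005,
DL01, DL1 — differing in how often a new movement-variation instruction was
issued) with small per-condition groups.

## Fuzzy measure entropy

For a z-transformed series $x_1,\dots,x_N$ and embedding dimension $m$,
form the template vectors $X_i = (x_i,\dots,x_{i+m-1})$. Two families of
centered vectors are compared:

* **local**: $X_i - \bar X_i$ (each vector minus its own mean), sensitive
  to local waveform shape;
* **global**: $X_i - \bar x$ (each vector minus the whole-series mean),
  sensitive to excursions around the global level.

For every ordered pair $i \ne j$ the Chebyshev distance $d_{ij}$ of the
centered vectors is scored by an exponential fuzzy membership
$\mu(d) = \exp(-d^n/r)$, and the mean similarity $\phi^{(m)}$ is taken over
all pairs (self-matches excluded). With both window lengths $m$ and $m+1$,

$$\mathrm{FuzzyMEn} =
  \ln\frac{\phi_L^{(m)}}{\phi_L^{(m+1)}} +
  \ln\frac{\phi_G^{(m)}}{\phi_G^{(m+1)}}.$$

The multiscale curve evaluates this on coarse-grained series: at scale
$\tau$, each block of $\tau$ consecutive samples is replaced by its mean,
leaving $\lfloor N/\tau\rfloor$ points. A 10-s analysis interval at 256 Hz
has 2,560 samples at scale 1 and 128 at scale 20.

### Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `m` | 2 | embedding dimension; adequate down to 128 points |
| `r_local`, `r_global` | 0.15 | similarity threshold, in SD units of the z-transformed interval |
| `n_local`, `n_global` | 2 | fuzzy weight (sharpness of the membership) |
| `membership_form` | `exp_pow_over_r` | $\exp(-d^n/r)$; alternative $\exp(-(d/r)^n)$ |
| `scale_min:scale_max` | 1:20 | coarse-graining range |

Two conventions deserve explanation because the underlying literature
leaves them open:

* **Membership form.** The sources describe only an "exponential function"
  with weight $n$ and threshold $r$. The default $\exp(-d^n/r)$ follows the
  fuzzy-measure-entropy convention; the ratio form $\exp(-(d/r)^n)$ is a
  config switch, and both are exercised by the oracle tests. The two give
  different absolute values but the same qualitative orderings.
* **One threshold for both branches.** A single $r = 0.15$ and
  $n = 2$ are applied to both the local and global branches — the simplest
  faithful reading; both are independently settable.

Other numerical choices: the z-transform uses the population SD (divisor
$N$) — entropy is invariant to this choice by affine invariance, it is
fixed only for bit-reproducibility; thresholds are *not* re-scaled per
coarse-graining scale (the standard multiscale-entropy convention, since
the coarse-grained series is not re-normalized); summation order in the
kernel is deterministic, so results are bit-stable; a constant interval
returns entropy 0 with a degeneracy flag instead of NaN; an underflowing
mean similarity raises an error rather than returning ±Inf.

## The session pipeline

1. **Filtering** (only when the recording is above the analysis rate):
   zero-phase FIR bandpass, EEG 4–70 Hz and ECG 0.02–40 Hz, then integer
   decimation to the analysis rate (canonically 1,024 → 256 Hz). The
   0.02 Hz ECG edge is realized as mean removal plus the 40 Hz low-pass
   half: an actual 0.02 Hz FIR transition would need a kernel longer than
   the recording, while mean removal has the identical effect on any
   10-s analysis interval. When decimating, the upper band edge is
   additionally capped below the target Nyquist (anti-aliasing).
2. **Segmentation**: non-overlapping contiguous 10-s intervals from the
   recording start, trailing remainder discarded, each interval
   z-transformed independently.
3. **Entropy**: the MSFME curve per interval and channel.
4. **Minute averaging**: the six 10-s values per minute are averaged;
   minutes with fewer intervals are flagged and excluded by default
   (artifact-rejected spans in real data shorten recordings; exclusion is
   the conservative option, and re-segmentation of concatenated clean data
   can be emulated by passing an already-concatenated recording).
5. **Baseline normalization**: the last complete pre-rest minute is the
   baseline (100%); post-rest values become `pct_baseline = 100·post/baseline`
   and `delta_pct = pct_baseline − 100`, per (subject, electrode, scale).
6. **Lobe aggregation**: electrode values are averaged into FP, F, C, T,
   P, O; TC (total cortex) averages all 19 electrodes directly — *not* the
   six lobe means, which would over-weight the small lobes. The ECG channel
   passes through as its own region.
7. **Condition medians**: element-wise medians over subjects, robust to
   outliers at group sizes of 7–8.

The reporting grid is Post1–Post5 plus the final recovery minute
(Post25 in a full 25-minute recording); the pipeline analyzes whatever
complete post-rest minutes exist and `minutes =` selects the grid.

## Scale selection

Testing all 20 scales would multiply the test count; instead a
condition-independent **heterogeneity measure** picks one analysis scale
per (post-minute, region), separately for EEG and ECG. At each scale, over
the $\binom{K}{2}$ pairs of condition medians of Δ% MSFME,
$H(\tau) = \sum_{a<b} |\mathrm{med}_a(\tau) - \mathrm{med}_b(\tau)|$, and
the selected scale is $\arg\max_\tau H(\tau)$. Properties: invariant to
condition order and to adding constants; scales linearly; ties are broken
toward the smallest scale (the option retaining the most coarse-grained
samples — the sources never address ties). Heterogeneity operates on
baseline-normalized Δ% medians, not raw entropies, so between-subject level
differences cannot drive the selection. With a single condition no pairs
exist; the pipeline then falls back to `scale_min` and records that.

## Statistics

* **Time effects**: Wilcoxon signed-rank test of each post-rest minute's
  Δ% against baseline (zero), per condition × region, at the selected
  scale. The implementation uses the normal approximation **without
  continuity correction** and excludes zero differences — the unique
  convention under which the closed-form values hold: all-same-sign $n=7$
  gives $z = 14/\sqrt{35} = 2.366$, one-opposed $n=8$ gives
  $z = 17/\sqrt{51} = 2.380$. The z carries the direction of change.
* **Effect size**: the rank-biserial chain $r = z/\sqrt{n}$ (n = pairs),
  $d = 2r/\sqrt{1-r^2}$, reported as a magnitude. This chain reproduces
  every reference (z, n, d) triple to ±0.001 — e.g. $(2.366, 7) \to 3.996$
  and $(2.1, 8) \to 2.217$ — and only under $n$ = number of pairs, which
  fixes that convention.
* **Condition effects**: Kruskal-Wallis H (tie-corrected) per region ×
  minute across conditions; if the omnibus $p \le 0.05$, pairwise rank
  comparisons with Bonferroni adjustment (×·number of pairs, capped at 1).
* **Interaction**: Spearman correlation between the 10-s `pct_baseline`
  values of an EEG region (at its selected scale) and the ECG (at its own
  selected scale), pooled over a condition's subjects within one post
  minute — 8 subjects × 6 intervals give n = 48 per cell, the only pooling
  that yields usable n at these group sizes. Per-subject correlation with a
  median summary is available as `correlation_pooling = "subject"` and is
  clearly non-default. Classification: $|r_s| \ge 0.5$ strong,
  $0.3 \le |r_s| < 0.5$ moderate, below that negligible; the magnitude rule
  is sign-blind.

Significance level is $p \le 0.05$ throughout.

## The synthetic-study generator

Subject-level recordings for this kind of study are typically not publicly
deposited, so the generator is a first-class module that produces studies
with the statistical structure the analysis assumes:

* **EEG**: per 10-s interval, a variance-normalized convex mixture
  $w\cdot\text{white} + (1-w)\cdot 1/f$ noise. The white fraction $w$ is
  the irregularity knob: FME at scale 1 rises monotonically with $w$
  (measured response ≈ 1.9 nats per unit $w$ around $w = 0.5$, where FME ≈
  2.5 nats), while the variance re-normalization keeps amplitude fixed.
  Lobes get slightly different baseline $w$ (0.45–0.55), so irregularity
  differs by lobe. A programmed Δ% entropy shift for (condition, lobe,
  post-minute) moves $w$ by `1.3 · Δ%/100` — the gain calibrated once from
  the measured response curve; a programmed −10% realizes a median Δ% of
  about −9.5%.
* **ECG**: Gaussian-bump QRS templates (σ = 15 ms) repeated at jittered RR
  intervals (default 0.5 s → 120 bpm, the skipping-cadence regime) plus
  additive white noise; entropy rises monotonically with the noise SD.
* **Coupling**: a per-interval AR(1) latent series (lag-0.5 smoothness) is
  split into a shared and a private component with weights
  $\sqrt{|\rho|}$ and $\sqrt{1-|\rho|}$, so the EEG-side and ECG-side
  modulations correlate at exactly $|\rho|$. The EEG side adds the
  modulation to $w$; the ECG side scales the log noise SD, with the sign of
  $\rho$ deciding co- or counter-movement. Because each side's entropy
  tracks its modulation nearly deterministically at these amplitudes, the
  pooled Spearman between the two entropy series lands near the programmed
  $\rho$ (slightly attenuated by entropy estimation noise; programmed 0.8
  realizes $\hat\rho \approx 0.74$ on average).
* Everything is seeded: one study seed deterministically derives every
  subject/phase/channel/interval stream, so identical seeds give
  byte-identical studies, and generation never disturbs the caller's RNG.

What the generator does **not** emulate: biophysical EEG forward modeling,
realistic P/T-wave morphology, artifacts (blinks, sweat, cable movement),
line noise, or non-stationarities other than the programmed ones. Passing
tests therefore demonstrate that the pipeline recovers the statistical
structure it assumes — not that real recordings satisfy those assumptions.
The generator is calibration-free with respect to any real dataset's
spectra by design.

## Problem sizes used in tests

The kernel is $O(N^2 m)$ per interval; a full 10-s/256 Hz scales-1–20
curve costs ~0.2 s. The package's simulation-heavy checks therefore run at
deliberately reduced sizes, chosen once: recovery and calibration suites
generate at 64 Hz with one pre-rest and one post-rest minute and an
occipital montage subset (the `channels` and `lobe_map` arguments exist
exactly for such focused runs); `demo_synthetic_study()` runs the full
31-subject, 20-channel, scales-1–20 design at 64 Hz (~10 min on one CPU).
The full-rate (256/1,024 Hz) and full-montage paths are exercised by the
pipeline and orchestrator tests on small blocks.

## Known limitations

* The Wilcoxon p uses the normal approximation even at n = 7–8, because
  that approximation is what makes the reported z and d chain well defined at all sample sizes; exact permutation p-values
  are deliberately out of scope.
* EDF support is minimal (16-bit continuous, equal per-channel rates,
  1-s records): enough to round-trip the package's own studies, not a
  general EDF+ reader.
* The heterogeneity selector picks a single scale per cell; top-k retention
  or significance filtering of H is out of scope.
* Entropy is interpreted as signal irregularity only, not as complexity.
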