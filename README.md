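# msfme

Nonlinear recovery analysis of synchronized EEG and ECG recordings via
**multiscale fuzzy measure entropy (MSFME)**.

After an acute exercise bout, the irregularity of resting-state brain and
heart signals drifts back toward baseline over minutes, and the two can
move together. This package is for researchers who want to quantify that
process: it computes fuzzy measure entropy over coarse-graining scales
1–20 on 10-s signal intervals, tracks per-minute trajectories relative to
the last pre-exercise minute (baseline = 100%), aggregates 19-channel EEG
into cerebral lobes (FP, F, C, T, P, O, and total cortex TC), selects one
analysis scale per (minute, region) by a heterogeneity measure over
condition medians, tests time and condition effects nonparametrically, and
measures brain–heart interaction as the Spearman correlation between the
EEG-entropy and ECG-entropy interval series.

Because subject-level recordings for such studies are rarely deposited,
the package ships a seeded synthetic-study generator (white/1-f noise
mixtures for EEG, a jittered QRS-template ECG, programmable per-lobe
entropy shifts and latent EEG–ECG coupling) plus EDF/CSV writers, so the
entire pipeline is testable end to end.

## The core quantities

Fuzzy measure entropy of a z-transformed series, embedding dimension
*m* = 2, threshold *r* = 0.15, fuzzy weight *n* = 2:

    FuzzyMEn = ln(φ_L^m / φ_L^{m+1}) + ln(φ_G^m / φ_G^{m+1})

where φ_L and φ_G are mean exponential fuzzy similarities
exp(−d^n / r) of Chebyshev distances between locally-centered
(own-mean-removed) and globally-centered embedding vectors. The multiscale
curve evaluates this on coarse-grained series (block means of length τ,
τ = 1…20; a 10-s/256 Hz interval has 2,560 points at scale 1, 128 at
scale 20).

Time effects use the Wilcoxon signed-rank normal approximation without
continuity correction, z = (W − n(n+1)/4) / √(n(n+1)(2n+1)/24), and the
rank-biserial effect-size chain r = z/√n, d = 2r/√(1−r²). Scale selection
maximizes H(τ) = Σ_{pairs} |median_a − median_b| of Δ% MSFME over
condition pairs. Correlations classify as moderate at |r_s| ≥ 0.3 and
strong at |r_s| ≥ 0.5.

## Worked example

```r
library(msfme)

# entropy of one 10-s white-noise interval across scales
x <- zscore_series(colored_noise(2560, beta = 0, seed = 7))
msfme(x, entropy_params(scale_max = 5))
#> # A tibble: 5 × 3
#>   scale n_samples entropy
#>   <int>     <int>   <dbl>
#> 1     1      2560    2.75
#> 2     2      1280    2.10
#> 3     3       853    1.79
#> 4     4       640    1.58
#> 5     5       512    1.47
```

Entropy falls with scale — the classic multiscale signature of white
noise, whose block means become ever smoother.

```r
# a synthetic two-condition study with a programmed occipital entropy
# drop of -10% in the first post-exercise minute of condition DL1
eff <- study_effect_spec(
  conditions = c("DL0", "DL1"), n_subjects_per_condition = 5,
  lobe_entropy_deltas = data.frame(condition = "DL1", lobe = "O",
                                   minute = 1, delta_pct = -10),
  fs = 64)
st <- simulate_study(eff, pre_minutes = 1, post_minutes = 1, seed = 42)
an <- run_study_analysis(st, params = entropy_params(scale_max = 2),
                         target_fs = 64)
report_time_effects(an, significant_only = TRUE)
#> # A tibble: 5 × 9
#>   condition region minute scale     z      p     d     n significant
#>   <chr>     <chr>   <int> <int> <dbl>  <dbl> <dbl> <int> <lgl>
#> 1 DL0       C           1     2  2.02 0.0431  4.24     5 TRUE
#> 2 DL1       F           1     2  2.02 0.0431  4.24     5 TRUE
#> 3 DL1       FP          1     2 -2.02 0.0431  4.24     5 TRUE
#> 4 DL1       O           1     1 -2.02 0.0431  4.24     5 TRUE
#> 5 DL1       TC          1     1 -2.02 0.0431  4.24     5 TRUE
```

The programmed occipital decrease surfaces as a significant negative z for
DL1 in O (and drags TC along, since TC averages all electrodes); at n = 5
subjects a unanimous direction is exactly the 0.043 boundary case, and
occasional spurious cells (here DL0/C) are expected at this size — the
null calibration of the full chain is checked quantitatively in the test
suite. `tidy(an, "interaction")` gives the Spearman brain–heart table,
`autoplot()` and `plot_trajectories()` the standard figures, and
`demo_synthetic_study()` runs a full 7/8/8/8-subject four-condition design.

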