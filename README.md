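# mammowtmm

Sliding-window 2D wavelet transform modulus maxima (WTMM) analysis of
mammographic tissue, for researchers studying tumor-associated tissue
disruption and bilateral breast asymmetry from standard MLO-view
mammograms — plus a synthetic-data module (fractional Brownian surfaces,
breast phantoms, whole two-breast cohorts) so the entire pipeline can be
validated without patient data.

## The method

Local mammographic intensity fluctuations are modeled as monofractal rough
surfaces: `f(r + eps) − f(r) ~ eps^H` with a Hurst exponent `H` per small
region. The 2D WTMM formalism estimates `H` from the gradient-of-Gaussian
wavelet transform `T_psi[f](b, a) = grad T_theta[f](b, a)`: modulus maxima
chain into curves at each scale `a`, link across scales into the space-scale
skeleton `L(a)`, and the partition functions

    Z(q, a) = sum over lines l in L(a) of ( sup over l, a' <= a of M_psi )^q
    Z(q, a) ~ a^tau(q),     D(h) = min_q ( q h − tau(q) )

give the scaling exponents and singularity spectrum; monofractal regions
(linear `tau(q)`) get a single `H`, all others are discarded.

A mammogram is scanned with 360-px windows (256-px analysis cores, 32-px
stride). Windows classify as **fatty** (`H <= 0.45`, blue), **disrupted**
(`0.45 < H < 0.55`, yellow — uncorrelated fluctuations, the proposed
signature of lost tissue homeostasis) or **dense** (`H >= 0.55`, red).
Per mammogram: %B, %Y, %R and %Y/%B over accepted windows. Per patient, the
bilateral asymmetry score

    YB Factor = (%Y_tumor / %B_tumor) / (%Y_opposite / %B_opposite)

is ~1 for symmetric breasts. Cohorts are compared with two-sided Wilcoxon
rank-sum tests (unadjusted p-values).

## Worked example

```r
library(mammowtmm)

## a 256x256 fractional Brownian surface with known roughness
img <- generate_fbm_surface(256, hurst = 0.5, seed = 1)
estimate_hurst(img)
#> <hurst_estimate H = 0.550 (se 0.002), curvature +0.018, monofractal>

## classify a window cut from a dense-like texture (H = 0.65)
analyze_window(generate_fbm_surface(360, 0.65, seed = 1)$values)$class
#> [1] "dense"

## a synthetic study-sized cohort and its headline contrast
cohort <- generate_cohort(cohort_spec(seed = 20240901))
cmp <- compare_groups(cohort)
subset(cmp, metric == "yb_factor" & contrast == "cancer vs benign")
#>       metric   level         contrast n_a n_b statistic p_unadjusted     p_bh
#> 13 yb_factor patient cancer vs benign  81  23      5063 2.236330e-10 1.192709e-09
```

The estimate `0.550` recovers the generator's `H = 0.5` within the
estimator's per-patch scatter (sd ~0.065; unbiased on average). In the
simulated cohort, cancer patients' tumor breasts carry a +0.15 disrupted
fraction shift, and the YB Factor separates cancer from benign patients at
p ~ 2e-10 with the study's group sizes (81 vs 23).

The `analysis/` scripts run the full narrative: `01_simulate_cohort.R`
(study-structured cohort), `02_analyze_phantom.R` (windowed WTMM map of a
two-texture breast phantom; pure fatty-band windows classify 100% fatty,
pure dense-band windows 92% dense), `03_hurst_recovery.R` (estimator
validation sweep), `04_group_comparisons.R` (rank-sum contrasts and box-plot
summaries). Outputs land in `results/`.

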