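# mueller3

Linear (3×3) Mueller matrix polarimetry for backscattering tissue imaging,
built around the two-region problem of separating glioblastoma (GBM) from
adjacent non-tumor white matter by their polarization properties. The
package is for researchers working with rotating-polarizer polarimetric
imagers — or evaluating whether such an instrument could separate two
tissue classes — who need the full chain from raw intensity frames to
region-level statistics, plus a synthetic phantom generator to exercise it
when no instrument data are available.

## What it computes

With only linear polarizers in the illumination (PSG) and detection (PSA)
arms, the sample is described by the 3×3 sub-block of its Mueller matrix
acting on the linear Stokes vector (s0, s1, s2). The detected intensity at
polarizer angles (α, β) is

    I(α, β) = (g/2) · a(β)ᵀ M s(α),   s(θ) = (1, cos 2θ, sin 2θ)ᵀ,

which is linear in the nine elements of M, so nine or more well-chosen
frames determine M per pixel by least squares (`reconstruct_mueller()`).
From the normalized M the package derives:

* **Polar decomposition (MMPD)** — `mmpd()` factors M = M_Δ·M_R·M_D and
  returns the diattenuation D, the depolarization coefficient Δ (from the
  eigenvalues of M′M′ᵀ with M′ = M·M_D⁻¹), the depolarization power 1−Δ,
  and the linear retardance δ.
* **MMT anisotropy** — `mmt_t()`:
  t = √((m22−m33)² + (m23−m32)²) / 2 (a rotation-invariant `"plus"`
  variant using m23+m32 is also provided).
* **FDH / CMC statistics** — `fdh()` density-normalized histograms with
  exact unit area, and `cmc()` central moment coefficients P1 (mean),
  P2 (variance), P3 (skewness), P4 (raw kurtosis).
* **Region comparisons** — `summarize_roi()` per-sample ROI means,
  `diagonal_symmetry()` for the |m22| = |m33| structure of backscattering
  averages, and `compare_groups()` Welch t-tests across a cohort.
* **Synthetic phantoms** — `make_phantom()` / `make_cohort()` generate
  two-region Mueller images from published average tissue matrices
  (`tissue_preset()`) or composed optical elements, simulate the intensity
  frames with detector noise and inter-sample jitter, and
  `analyze_cohort()` / `run_pipeline()` run the whole analysis.

## Worked example

```r
library(mueller3)

# published average GBM matrix: t and the polar-decomposition parameters
G <- tissue_preset("gbm")
mmt_t(G)$t                     # 0.325   (printed in the literature as 0.33)
mmpd(G)$one_minus_delta        # 0.6699  (vs 0.65 from per-pixel averaging)
mmpd(G)$D                      # 0.02236
diagonal_symmetry(G)           # diff = 0.01, pass (|m22| ~ |m33|)

# full simulated study: 20 samples, 1% detector noise, 0.02 diagonal jitter
res <- run_pipeline(pipeline_config(n_samples = 20, size = c(64, 64),
                                    jitter_sd = 0.02, noise_sd = 0.01,
                                    seed = 42))
res
#> <pipeline_result> cohort of 20 samples, seed 42
#>
#> Group means (per-sample ROI means):
#>    region    m22    m33 one_minus_delta      t
#> 1     GBM 0.3239 -0.329           0.658 0.3266
#> 2 non-GBM 0.0983 -0.084           0.889 0.0916
#>
#> Group comparison:
#>         parameter  mean1   mean2  p_value significant
#> 1             m22  0.324  0.0983 1.68e-30        TRUE
#> 2             m33 -0.329 -0.0840 7.88e-28        TRUE
#> 3 one_minus_delta  0.658  0.8894 7.64e-34        TRUE
#> 4               t  0.327  0.0916 4.90e-34        TRUE
```

The GBM region reconstructs to the stronger-polarization-maintaining
tissue (larger |m22|, |m33|, larger t, smaller 1−Δ) and white matter to the
stronger depolarizer; all four group comparisons are significant at
α = 0.05, with p-values this small because the simulated cohort encodes the
published group separation with modest jitter.

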