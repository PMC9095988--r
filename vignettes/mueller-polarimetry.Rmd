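---
title: "Linear Mueller matrix polarimetry of two-region tissue: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear Mueller matrix polarimetry of two-region tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mueller3)
```

## The measurement model

A backscattering polarimetric imager illuminates thick tissue through a
rotating linear polarizer (the polarization state generator, PSG) and images
the backscattered light through a second rotating polarizer (the analyzer,
PSA). With only linear polarizers in the beam, the circular Stokes component
is neither generated nor analyzed, so the sample is described by the 3×3
sub-block of its Mueller matrix acting on the linear Stokes vector
$(s_0, s_1, s_2)$:

$$ S_\mathrm{out} = M\,S_\mathrm{in}, \qquad
   M = \begin{pmatrix} m_{11} & m_{12} & m_{13}\\
                       m_{21} & m_{22} & m_{23}\\
                       m_{31} & m_{32} & m_{33} \end{pmatrix}. $$

The detected intensity for PSG angle $\alpha$ and PSA angle $\beta$ is
$I(\alpha,\beta) = \tfrac{g}{2}\, a(\beta)^\top M\, s(\alpha)$ with
$s(\theta) = (1, \cos 2\theta, \sin 2\theta)^\top$ and gain $g$. This is
linear in the nine elements of $M$, so any set of angle pairs whose
instrument matrix has rank 9 determines $M$ per pixel; `reconstruct_mueller()`
solves the system by least squares and normalizes each pixel by its $m_{11}$,
which also cancels the unknown gain. The default design is the minimal
exactly determined grid $\alpha,\beta \in \{0°, 45°, 90°\}$ (9 frames) —
instruments of this type do not agree on a canonical sequence, and this grid
is the smallest standard choice for linear-only polarimetry; arbitrary
designs with more frames are supported and solved by ordinary least squares.

Angle conventions: polarizer and fast-axis angles are measured
counter-clockwise from horizontal and enter through the usual $2\theta$
doubling on the Poincaré equator. Published tissue matrices of this kind do
not state their handedness convention; the sign structure of the
backscattering matrices (negative $m_{33}$) is reproduced phenomenologically
through the backscatter depolarizer below rather than derived from
instrument geometry.

## Polar decomposition (MMPD) and the MMT parameter

`mmpd()` factors a normalized matrix as
$M = M_\Delta M_R M_D$ — depolarizer, retarder, diattenuator. The
diattenuation vector $(m_{12}, m_{13})$ is read off the first row,
$D = \sqrt{m_{12}^2 + m_{13}^2}$; stripping it leaves
$M' = M M_D^{-1} = M_\Delta M_R$, and the symmetric product
$M_{DR} = M' M'^\top$ has eigenvalues
$\{1,\ \Delta^2,\ \Delta^2\cos^2\delta\}$. The unit eigenvalue belongs to the
intensity channel and is identified by its eigenvector (largest $s_0$
component) rather than by magnitude, which keeps the assignment stable under
noise. Since $\cos^2\delta \le 1$, the larger of the two remaining
eigenvalues is $\Delta^2$; this resolves an assignment that the compact
eigenvalue notation leaves ambiguous. $\Delta \in [0,1]$ is the
depolarization-maintaining coefficient and $1-\Delta$ the depolarization
power; $\delta = \arccos\sqrt{\lambda_\mathrm{small}/\lambda_\mathrm{large}}
\in [0, \pi/2]$ is the linear retardance. The retarder orientation is not
recovered (none of the downstream summaries use it). Eigenvalues in
$[-\epsilon, 0)$ are numerical noise and are clamped to zero
($\epsilon = 10^{-6}$ by default); pixels with more negative eigenvalues, or
with $D$ at 1 (singular diattenuator), are masked rather than propagated.

The MMT anisotropy parameter is

$$ t = \tfrac{1}{2}\sqrt{(m_{22}-m_{33})^2 + (m_{23}-m_{32})^2}. $$

The package implements this `"minus"` form as the default and also the
`"plus"` variant using $(m_{23}+m_{32})$, which is exactly invariant under
sample rotation (for a rotated pure retarder the minus form oscillates as
$|\cos 4\varphi|(1-\cos\delta)/2$ — a property the test suite asserts). The
two coincide for the essentially diagonal matrices typical of backscattering
tissue averages, where $m_{23} = m_{32} = 0$. For a backscatter depolarizer
$\mathrm{diag}(1, \Delta, -\Delta)$ the two views are internally consistent:
$t = \Delta$ and $1-\Delta = 1-t$.

Worked numbers the package reproduces from the published average matrices of
glioblastoma (GBM) and adjacent white matter (`tissue_preset()`): $t = 0.325$
(GBM, printed as 0.33) and $t = 0.09$ (non-GBM); $1-\Delta = 0.91$
(non-GBM). Decomposing the *average* GBM matrix yields $1-\Delta \approx
0.67$ against the published per-pixel average of 0.65; the decomposition is
nonlinear, so the map of the mean need not equal the mean of the map, and
the package asserts this case only to a ±0.03 tolerance.

## FDH and central moment coefficients

`fdh()` computes a density-normalized histogram of an element or parameter
over a region of interest. Two contracts matter: the area under the
histogram is exactly 1 (values outside the requested range are clipped into
the edge bins, so no mass is dropped), and the binning settings are recorded
in every report so the histogram is reproducible. Bin count and range are
not standardized for this kind of imagery; the defaults are 256 bins over
the data range, both configurable.

`cmc()` returns the central moment coefficients of a sample: $P_1$ the mean,
$P_2$ the population variance, $P_3$ the skewness and $P_4$ the raw
(non-excess) kurtosis, so a Gaussian gives $P_4 = 3$. Population
normalization (divide by $n$) matches the expectation-based definitions
rather than sample-corrected estimators. A constant sample has $P_2 = 0$ and
$P_3$, $P_4$ undefined (0/0); these are reported as `NA` with an explicit
`defined = FALSE` flag instead of silently propagating `NaN`. Moments are
computed on raw pixel values by default; a binned approximation
(`weighted_by_fdh = TRUE`) from bin centers and heights is available and
converges to the raw moments as bins grow. A `scale` multiplier is exposed
because published moment tables for normalized elements sometimes imply an
undocumented rescaling of the FDH domain (e.g. variances in the hundreds for
elements bounded by 1); the package does not guess that transformation, it
only records whatever scale the user sets. For the same reason the
published per-study moment tables are not reproduction targets: the raw
images behind them are not deposited.

## Region comparisons

`summarize_roi()` reduces each sample to arithmetic means of the nine
elements and the derived parameters over a region of interest.
`compare_groups()` then tests group differences across a cohort with
two-sided t-tests. Two deliberate choices:

* **Unit of analysis.** Tests run on per-sample ROI means (one value per
  specimen), not on pixels. Pixels within a specimen are strongly
  correlated, and treating them as independent replicates would
  pseudo-replicate the data; the per-sample reading is the conservative one
  for a 20-specimen cohort.
* **Welch by default.** The unequal-variance (Welch) test is the robust
  default when group variances differ, as they do between tumor and white
  matter; the pooled Student variant is available by flag. P-values are
  reported raw, one test per parameter, matching per-parameter reporting
  conventions; a Bonferroni flag exists for users who want it.

Degenerate cohorts are handled explicitly: both groups constant with equal
means give $p = 1$; fewer than two samples per group is an error.
`diagonal_symmetry()` quantifies the $|m_{22}| = |m_{33}|$ structure of
backscattering tissue averages as an absolute magnitude difference with a
default pass threshold of 0.02.

## What the synthetic phantoms emulate

No image data of this kind are publicly deposited, so the package carries a
first-class generator. A phantom is a two-region image (left/right split by
default, mirroring the layout of published two-region fields of view;
arbitrary masks are supported) whose region matrices are either the
published GBM / white-matter averages or composed optical elements
$M_\Delta M_R M_D$ in the backscatter convention. From the ground-truth
image the generator simulates the nine intensity frames the instrument
would record and adds detector noise.

Study-condition defaults, chosen once:

* **Cohort size 20** — the specimen count of the emulated study.
* **Intensity noise**: additive zero-mean Gaussian on the frames, sd 1% of
  the maximum intensity. No noise model is published for this instrument
  class; 1% additive noise propagates to element errors of roughly the
  quoted 0.04 element-wise calibration accuracy, which is the only stated
  error figure. Noise scales linearly into element error (a tested
  property).
* **Inter-sample variability**: Gaussian jitter of sd 0.02 on the diagonal
  elements $m_{22}$, $m_{33}$ of each specimen's region matrices, truncated
  to the physical range — about half the calibration error, and small
  against the 0.32 vs 0.09 group separation, so a 20-specimen cohort
  separates the groups with overwhelming power, as the emulated study's
  uniformly significant t-tests imply.
* **Determinism**: per-sample child seeds are a fixed integer function of
  the master seed and the sample index, so cohorts are reproducible sample
  by sample and any seed reproduces the full output byte for byte.

What the phantoms deliberately do **not** emulate: spatial texture within a
region (each region is homogeneous up to detector noise), polarized photon
transport, wavelength dependence, or histology-derived microstructure.
Passing tests on phantoms therefore validate the algebra, the estimators
and the statistical calibration of the pipeline — not the biological claim
that these parameters separate real tumor from real white matter.

## Numerical choices and problem sizes

* Pixels with reconstructed $m_{11} \le 10^{-6}\times$ the image maximum are
  masked, not normalized.
* The per-pixel decomposition runs in compiled code (identical, to
  $10^{-10}$, to the single-matrix R path — a tested equivalence); this
  keeps a 20-sample 64×64 cohort analysis under a second and makes
  calibration studies cheap.
* Test problem sizes are chosen as the smallest that pin each property:
  64×64 phantoms for round-trip and cohort checks, 8×8 phantoms for the
  type-I-error study (1000 null cohorts of 20 samples, expecting a ~5%
  rejection rate at $\alpha = 0.05$), $10^5$–$10^6$ draws for Gaussian
  moment checks.
* Physicality checks on normalized elements use a configurable tolerance
  (default 0.05) slightly above the quoted 0.04 calibration accuracy.

## A complete run

```{r pipeline}
res <- run_pipeline(pipeline_config(n_samples = 20, size = c(64, 64),
                                    jitter_sd = 0.02, noise_sd = 0.01,
                                    seed = 42))
res
```

The group means land on the published scale (GBM $m_{22} \approx 0.32$,
$1-\Delta \approx 0.66$, $t \approx 0.33$; white matter $m_{22} \approx
0.09$, $1-\Delta \approx 0.89$, $t \approx 0.09$) and all four comparisons
are significant, because that is what the generator's study conditions
encode — the run demonstrates the pipeline, it is not independent evidence
about tissue.

## Known limitations

* 3×3 only: circular retardance/diattenuation and full 4×4 decompositions
  (Lu–Chipman, differential) are out of scope, as is physical-realizability
  (Cloude) filtering.
* The backscattering sign convention is adopted phenomenologically.
* Published per-study FDH peak and moment tables are not reproducible
  without the raw images and are not targets; the package instead
  guarantees reproducibility of its own reports.
* The retarder orientation and any spatial statistics of the maps are not
  estimated.
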