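---
title: "Grading steatosis from autofluorescence spectra: models and methods"
author: "steatoFluor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading steatosis from autofluorescence spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steatoFluor)
```

# The problem

Liver autofluorescence under UV–violet excitation mixes the emissions of a
handful of intrinsic fluorophores, and the mixture shifts as steatosis
progresses: NAD(P)H and vitamin A fluorescence declines while flavins,
lipopigments, lipofuscin and porphyrins grow, producing brighter, redder
spectra. `steatoFluor` reproduces the full analysis chain used to exploit
this in the MCD (methionine–choline-deficient diet) mouse model — three
groups MCC / MCD2w / MCD8w, five excitation wavelengths (330, 365, 385,
405, 415 nm) — together with a generative simulator that supplies data
with the study's statistical structure, since the original animal spectra
were never deposited.

Every excitation wavelength is analyzed independently; the study never
pools excitations into one classifier, and neither does the package.

# The generative model

A clean spectrum of subject $s$ in group $g$ at excitation
$\lambda_{exc}$ is

$$ I(\lambda) \;=\; \sum_f A_{f,g}\, M_{f,s}\,
   \eta_f(\lambda_{exc})\, b_f(\lambda), $$

where $A_{f,g}$ is the group's mean amplitude for fluorophore $f$
(arbitrary intensity units), $\eta_f$ its unitless excitation efficiency,
and $b_f$ a Gaussian emission band (porphyrins carry a secondary Gaussian
lobe at 680 nm with mixing fraction 0.35). The measured spectrum is
`I * response + dark + noise`, with Gaussian noise of sd
`noiseSD * (1 + signal/100)` — a floor of `noiseSD` counts plus a
component proportional to the local signal, which makes the error bars
grow where the signal does.

Band positions follow the fluorophore literature as summarized in the
grading context: NAD(P)H near 470 nm, vitamin A near 490 nm, flavins at
520 nm, lipopigments near 540 nm, lipofuscin broad around 620 nm, and
porphyrins at 620 nm with the 680 nm secondary peak. Excitation
efficiencies encode the qualitative pattern that NAD(P)H and vitamin A
are not excited at 405/415 nm while porphyrin excitation grows
monotonically with excitation wavelength. Band widths and the amplitude
tables are the package's own calibration choices: no absolute fluorophore
concentrations are published, so the defaults were set once so that the
simulated study displays the documented phenomenology — intensity above
550 nm strictly ordered MCC < MCD2w < MCD8w, growing between-spectrum
spread with stage, group-separable spectral shapes at every excitation,
and AUC statistics that order the groups and separate them by Tukey HSD at
$\alpha = 0.05$.

## Subject effect and lipid coupling

The per-subject multiplier factorizes as
$M_{f,s} = G_s\, D_{f,s}$:

* $G_s$ is a lognormal **common intensity factor** (CV = `subjectCV`,
  defaults 0.15 / 0.30 / 0.45 by stage). It scales the whole spectrum, so
  it dominates the between-subject spread of the area-under-curve
  statistic but cancels exactly under single-wavelength normalization.
* $D_{f,s}$ is a small lognormal **band-shape jitter** (CV = `shapeCV`,
  default 0.10, one draw per fluorophore and subject). It perturbs band
  ratios — the feature the classifier sees — and therefore sets the
  within-group shape variability.

This decomposition mirrors the study's own data: per-subject lipid content
overlaps heavily between the two diet groups while the spectral *shapes*
classify nearly perfectly, so overall brightness and shape must carry
largely independent information.

Lipid content (% area, morphometry scale) is drawn per subject from a
normal with the stage's published moments — (0.16, 0.35), (6.73, 5.78),
(10.99, 6.83) — truncated at zero via the inverse-CDF, which keeps the
random-number stream deterministic. The standardized truncated draw is the
subject's latent severity and is mixed into $\log G_s$ with weight
`coupling` (default 0.5; 0 disables it for null experiments), so a
positive rank correlation between spectral AUC and lipid content exists by
construction. Note the realized mean of a zero-truncated normal exceeds
the underlying mean — `truncatedNormalMoments(10.99, 6.83)` gives 11.79 —
and the tests check the Monte-Carlo draws against that closed form, since
the published moments describe observed (non-negative) data rather than a
stated distribution. For the control group (0.16 ± 0.35) no zero-truncated
normal can even match both moments (its CV cannot exceed 1), which is why
the package parameterizes the *underlying* normal with the published
values rather than moment-matching the truncated law.

# Preprocessing

Order: dark subtraction → sensitivity correction → boxcar smoothing →
range restriction → normalization; each step appends to the
`processingLog` of the `SpectraSet`.

* **Dark subtraction** clips negative results to zero — counts are
  physical.
* **Sensitivity correction** divides by the relative spectral response
  (estimated from a calibration lamp as measured/reference), which must be
  strictly positive on the grid.
* **Boxcar width** is unspecified by the acquisition software convention
  it imitates; the default is 5 grid points (≈ 3.9 nm at the 0.77 nm
  step), configurable, with truncated windows at the edges so the grid
  never shrinks.
* **Range restriction** keeps the closed window assigned to the
  excitation (e.g. 490.9–795.8 nm at 405 nm), with a 1e-9 nm tolerance on
  the comparisons so grid points landing on a boundary by floating-point
  accident are kept. Printed point counts are treated as descriptive;
  the package derives counts from its own grid.
* **Normalization** divides each spectrum by its value at the grid point
  *nearest* the reference wavelength (600 nm by default; an exact 600.00
  point generally does not exist on a 0.77 nm grid). It errors on a
  non-positive reference intensity and is idempotent.

Two products feed the statistics: the **corrected** spectra (all steps
except normalization) carry the intensity scale and feed the AUC
statistics, whose point is exactly that intensity growth; the
**normalized** spectra feed PCA/QDA, removing irradiation-geometry and
source-power differences so the classifier sees shape only. Running the
AUC on normalized spectra would invert the group ordering (the 600 nm
anchor pins the growing red band to 1), which is why `runAll()` keeps the
two branches distinct.

# Statistics

* **Spectral AUC**: trapezoidal integral over the excitation-specific
  window (425–800, 425–800, 440–800, 490–800, 500–800 nm). The windows
  deliberately exceed some measured ranges; the package integrates over
  the intersection and emits a message. Comparisons are always within one
  excitation, so the truncation cancels.
* **ANOVA + Tukey HSD** via `stats::aov`/`TukeyHSD`, i.e. Tukey–Kramer
  for the unequal group sizes. With two groups the adjusted p equals the
  pooled-variance t-test p (up to `ptukey`'s numerical accuracy, ~1e-5).
* **Spearman vs lipid** on per-subject mean AUC (n = 22), average ranks
  for ties, t-approximation on n − 2 df (`cor.test(..., exact = FALSE)`).
  Constant input is an error, not NA.

# Classification chain

* **PCA** (`stats::prcomp`, covariance of mean-centered spectra) keeps 6
  components by default — the study's fixed choice — and warns below a
  90% explained-variance floor. Automatic scree-elbow detection is
  deliberately not implemented; the component count is documented as a
  manual choice. PCA is fit once on the full data set of an excitation
  and reused inside cross-validation folds; only the discriminant model is
  refit per fold.
* **Box's M** gates LDA vs QDA: $M = (N-k)\ln|S_p| - \sum_k (n_k-1)
  \ln|S_k|$ with the standard $\chi^2$ correction; QDA is recommended iff
  $p < \alpha$. Its type-I error calibrates to ~5% at the study's scale
  (3 groups × 100 observations, 3 dimensions), which the acceptance suite
  verifies over 500 replicates.
* **QDA**: class covariances with the $n_k - 1$ denominator, empirical
  priors by default (group sizes are unequal), log-discriminants
  evaluated via Cholesky factors, posteriors by max-subtracted softmax.
  Exact singularity triggers a logged ridge of `1e-10 × trace`; argmax
  ties break to the lexicographically first label, with a message.
* **LOOCV** refits QDA for every held-out spectrum; it is deterministic
  and reported side by side with the resubstitution scheme as paired
  "classification, cross-validation" cells. Total error is reported under
  *both* circulating definitions — pooled misclassification share and
  unweighted mean of group error rates — because published reports mix
  them.
* **Canonical plane**: the two leading eigenvectors of $W^{-1}B$, scaled
  to unit pooled within-class variance; the decision-boundary raster
  classifies a 400 × 400 grid spanning the observed scores ± 10% margin
  with a QDA refit on the 2-D canonical scores. With three groups there
  are exactly two canonical axes; degenerate label sets pad a null second
  axis.
* **ROC / Youden**: one-vs-rest curves from the classifier posteriors,
  thresholds at every distinct score plus ±Inf sentinels, tied scores
  collapsed into single steps, trapezoidal AUC (provably equal to the
  Mann–Whitney U fraction, which the tests assert). Youden ties resolve
  to the lowest threshold, i.e. the most sensitive operating point —
  sensitivity and specificity are weighted equally, so the tie direction
  is a free choice made once. By default the ROC scores are the
  resubstitution posteriors, matching how the reference report pairs its
  tables; `rocScores = "loocv"` switches to held-out posteriors for an
  honest generalization estimate.

# What the simulator does and does not show

Passing tests demonstrate that the *pipeline* recovers the structure the
generator put in: ordered AUC, positive lipid correlation, covariance
heterogeneity (hence a QDA recommendation), >90% cross-validated success
with stage-separated profiles and chance-level (≈ 33%) success when the
profiles are identical and subject structure is disabled. They do not
validate the biology: real spectra contain re-absorption and scattering
effects, non-Gaussian band shapes, wavelength-dependent redshifts within a
band, and operator/pressure variability that the Gaussian-mixture model
omits. One caveat worth knowing: with subject-level random effects left
on, spectrum-level LOOCV is optimistic even under identical profiles,
because a held-out spectrum's subject mates remain in the training set —
the chance-level check therefore uses the fully exchangeable null
(`subjectCV = 0`, `shapeCV = 0`, `coupling = 0`).

# Problem sizes and reproducibility

The test suite simulates reduced designs (tiny 3-subject studies for
pipeline mechanics; one full-size 401-spectrum single-excitation study for
the statistical properties; 3000 subjects per group on a 3-point grid for
the lipid Monte-Carlo) and completes in well under a minute; the
acceptance script simulates the full 1870-spectrum, five-excitation study
and finishes in a few seconds more. All randomness flows from a single
integer seed through R's default generator; `runAll()` writes an
MD5-checksummed manifest (excluding the timing log) that is identical for
identical configurations and seeds.

# Known limitations

* Only three-class problems are supported by the canonical-plane renderer;
  there is no LDA production path beyond the gate's recommendation, and no
  regularized or shrinkage discriminant variants.
* No confidence intervals on ROC AUC; no multi-class AUC beyond
  one-vs-rest.
* The simulator does not model photon transport, re-absorption, or the
  diffuse-reflectance channel of the instrument; fluorophore amplitudes
  are calibration choices, not measured concentrations.
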