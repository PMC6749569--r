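# steatoFluor

Grading early hepatic steatosis from liver autofluorescence spectra.

Non-alcoholic fatty liver disease is usually graded by biopsy, where
mild-to-moderate steatosis is exactly the range with the worst
inter-observer agreement. Endogenous fluorescence (autofluorescence)
spectroscopy offers an optical alternative: under UV–violet excitation
(330–415 nm) liver tissue emits light from intrinsic fluorophores —
NAD(P)H, vitamin A, flavins, lipopigments, lipofuscin, porphyrins — and the
balance of those emissions shifts as fat accumulates. In the
methionine–choline-deficient (MCD) mouse model, spectra from control
animals (MCC) and animals fed the deficient diet for two (MCD2w) or eight
(MCD8w) weeks grow progressively brighter above ~550 nm and redshift as
the lipid-associated fluorophores take over.

`steatoFluor` implements that analysis end to end, for R, with a tested
synthetic-data generator standing in for the (undeposited) animal spectra:

* **Simulator** — Gaussian fluorophore emission bands with
  excitation-dependent efficiencies, per-group amplitude profiles, a
  lognormal per-subject intensity factor coupled to a zero-truncated-normal
  lipid content, instrument response/dark counts, and signal-dependent
  noise. Defaults reproduce the reference study design: 22 subjects
  (9/6/7; only 3 MCD2w animals at 415 nm) and 1870 spectra across five
  excitation wavelengths.
* **Preprocessing** — dark subtraction, spectral-sensitivity correction
  from a calibration lamp, boxcar smoothing, excitation-dependent range
  restriction, and normalization to 1 at 600 nm, each logged on the
  `SpectraSet` object (an extension of `SummarizedExperiment`).
* **Spectral statistics** — trapezoidal area under the curve (AUC) over
  excitation-specific integration windows, one-way ANOVA with Tukey HSD
  across dietary groups, and Spearman correlation of per-subject mean AUC
  against lipid content.
* **Classification** — PCA to six components, Box's M covariance-equality
  gate (which recommends the quadratic model), quadratic discriminant
  analysis (QDA) with empirical priors, resubstitution and leave-one-out
  cross-validated confusion matrices, canonical score planes with gridded
  decision boundaries, and one-vs-rest ROC curves from the posterior
  probabilities with Youden-index optimal cut-offs.

The QDA discriminant is the Gaussian
`d_k(x) = ln π_k − ½ ln|Σ_k| − ½ (x − μ_k)ᵀ Σ_k⁻¹ (x − μ_k)`,
posteriors are the softmax of the `d_k`, and the Youden optimum maximizes
`J = sensitivity + specificity − 1` over posterior thresholds.

## Worked example

One excitation wavelength (405 nm), full study size:

```r
library(steatoFluor)

sim <- simulateStudy(subsetDesign(defaultStudyDesign(), 405), seed = 7)
inst <- defaultInstrument()
corrected <- restrictRange(boxcarSmooth(correctSensitivity(
  subtractDark(sim$spectra[["405"]], inst), inst), 5))
normalized <- normalizeAt(corrected, 600)
normalized
#> SpectraSet: 401 spectra at 405 nm excitation
#>   grid: 491.22..795.37 nm, 396 points
#>   groups: MCC (145), MCD2w (131), MCD8w (125)
#>   processing: dark -> sensitivity -> boxcar(5) -> restrict[490.9,795.8] -> normalize(600)
```

The AUC statistic (computed on the corrected, un-normalized spectra) grows
with diet duration and separates all three groups:

```r
aucTab <- spectralAUC(corrected)
round(tapply(aucTab$auc, aucTab$group, mean))
#>   MCC MCD2w MCD8w
#>  3233  7950 15858
anovaTukey(aucTab$auc, aucTab$group)$tukey
#>          pair      diff p_adj reject
#> 1   MCD2w-MCC  4717.243     0   TRUE
#> 2   MCD8w-MCC 12624.696     0   TRUE
#> 3 MCD8w-MCD2w  7907.453     0   TRUE
```

Per-subject mean AUC tracks the morphometric lipid content
(rho = 0.82, p = 3.5e-06, n = 22 subjects). The classification chain on the
normalized spectra then reaches study-typical performance:

```r
X <- t(intensities(normalized))
pca <- pcaFit(X, 6)                     # six PCs: 98.8% of variance
scores <- pcaProject(pca, X)
covarianceEqualityTest(scores, spectrumGroups(normalized))$recommend
#> [1] "QDA"
qdaLoocv(scores, spectrumGroups(normalized))
#> ConfusionMatrix (cross-validation), actual x predicted:
#>       MCC MCD2w MCD8w
#> MCC   145     0     0
#> MCD2w   0   131     0
#> MCD8w   0     0   125
```

Here every spectrum is cross-validated into its true group; the
one-vs-rest ROC curves from the QDA posteriors all reach AUC 1.000 with
Youden-optimal sensitivity and specificity of 1.000. `runAll(runConfig())`
executes the same chain for all five excitations and writes every artifact
(spectra and AUC tables, paired confusion matrices, error rates under both
total-error definitions, ROC report, canonical-plane raster) plus an
MD5-checksummed manifest.

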