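#' @rdname SpectraSet-class
#' @param x a SpectraSet.
#' @export
wavelengths <- function(x) rowData(x)$wavelength_nm

#' @rdname SpectraSet-class
#' @export
intensities <- function(x) assay(x, "intensity")

#' @rdname SpectraSet-class
#' @export
excitation <- function(x) unique(colData(x)$excitation_nm)

#' @rdname SpectraSet-class
#' @export
spectrumGroups <- function(x) colData(x)$group

#' @rdname SpectraSet-class
#' @export
spectrumSubjects <- function(x) colData(x)$subject_id

#' @rdname SpectraSet-class
#' @export
spectrumIds <- function(x) colData(x)$spectrum_id

#' Ordered log of preprocessing steps applied to a SpectraSet
#' @param x a SpectraSet.
#' @return character vector, one entry per applied step, in order.
#' @export
processingLog <- function(x) {
  log <- metadata(x)$processing
  if (is.null(log)) character() else log
}

.logStep <- function(x, step) {
  metadata(x)$processing <- c(processingLog(x), step)
  x
}

setMethod("show", "SpectraSet", function(object) {
  wl <- wavelengths(object)
  cat(sprintf("SpectraSet: %d spectra at %g nm excitation\n",
              ncol(object), excitation(object)))
  cat(sprintf("  grid: %.2f..%.2f nm, %d points\n",
              min(wl), max(wl), length(wl)))
  cat(sprintf("  groups: %s\n",
      paste(sprintf("%s (%d)", names(table(spectrumGroups(object))),
                    table(spectrumGroups(object))), collapse = ", ")))
  log <- processingLog(object)
  cat(sprintf("  processing: %s\n",
              if (length(log)) paste(log, collapse = " -> ") else "<raw>"))
})

setMethod("show", "InstrumentModel", function(object) {
  cat(sprintf("InstrumentModel: grid %.1f..%.1f nm (%d points)\n",
              min(object@wavelength), max(object@wavelength),
              length(object@wavelength)))
  cat(sprintf("  dark counts: %.1f..%.1f; response: %.3f..%.3f\n",
              min(object@dark), max(object@dark),
              min(object@response), max(object@response)))
})

setMethod("show", "FluorophorePanel", function(object) {
  cat(sprintf("FluorophorePanel with %d bands:\n", length(object@bands)))
  for (b in object@bands) {
    sec <- if (b@secondaryFraction > 0)
      sprintf(" (+ secondary %g nm, fraction %.2f)", b@secondaryCenter,
              b@secondaryFraction) else ""
    cat(sprintf("  %-12s emission %g nm (sigma %g)%s\n", b@name,
                b@emissionCenter, b@emissionSigma, sec))
  }
})

setMethod("show", "StageProfile", function(object) {
  cat(sprintf("StageProfile '%s': lipid %.2f +/- %.2f %%, subject CV %.2f, noise sd %.2f\n",
              object@group, object@lipidMean, object@lipidSD,
              object@subjectCV, object@noiseSD))
  print(round(object@amplitude, 2))
})

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign\n  spectra counts (groups x excitations):\n")
  print(object@counts)
  cat(sprintf("  total spectra: %d\n", sum(object@counts)))
})

setMethod("show", "QDAModel", function(object) {
  cat(sprintf("QDAModel: %d classes in %d dimensions\n",
              length(object@labels), length(object@means[[1]])))
  cat(sprintf("  priors: %s\n",
      paste(sprintf("%s=%.3f", object@labels, object@priors), collapse = ", ")))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix (%s), actual x predicted:\n", object@scheme))
  print(object@counts)
})

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROCCurve '%s' vs rest: AUC %.3f, J %.3f at cut-off %.3f (sens %.3f, spec %.3f)\n",
              object@positiveClass, object@auc, object@youdenJ,
              object@optimalCutoff, object@optimalSensitivity,
              object@optimalSpecificity))
})

setMethod("show", "CanonicalPlane", function(object) {
  cat(sprintf("CanonicalPlane: %d observations, eigenvalues %.3f / %.3f, %d grid nodes\n",
              nrow(object@scores), object@eigenvalues[1], object@eigenvalues[2],
              nrow(object@grid)))
})
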