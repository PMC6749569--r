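#' Reference report tables from the ex-vivo mouse study
#'
#' Plain-text fixtures reproducing the printed report tables of the
#' reference ex-vivo MCD-diet mouse study whose design this package
#' emulates: the paired classification / cross-validation confusion counts
#' per excitation wavelength, the one-vs-rest ROC performance summary, and
#' the published per-group error rates.  The raw animal spectra were never
#' deposited, so these tables are the only numeric anchor available for the
#' report arithmetic (\code{\link{confusionRates}}, ROC averaging); the
#' simulator, not these tables, feeds the statistical pipeline.
#'
#' @return \code{referenceConfusionCounts}: data.frame(excitation_nm,
#'   actual, predicted, classification, cross_validation).
#' @name reference-tables
NULL

.refFile <- function(name)
  system.file("extdata", name, package = "steatoFluor", mustWork = TRUE)

#' @rdname reference-tables
#' @export
referenceConfusionCounts <- function()
  utils::read.csv(.refFile("reference_confusion_counts.csv"))

#' @rdname reference-tables
#' @param excitation_nm excitation wavelength to extract.
#' @param scheme "classification" or "cross-validation".
#' @return \code{referenceConfusionMatrix}: a \linkS4class{ConfusionMatrix}
#'   for one excitation and scheme.
#' @export
referenceConfusionMatrix <- function(excitation_nm,
                                     scheme = c("classification",
                                                "cross-validation")) {
  scheme <- match.arg(scheme)
  tab <- referenceConfusionCounts()
  tab <- tab[tab$excitation_nm == excitation_nm, ]
  if (nrow(tab) == 0)
    stop(sprintf("no reference counts for excitation %g nm", excitation_nm))
  col <- if (scheme == "classification") "classification" else "cross_validation"
  classes <- sort(unique(tab$actual))
  m <- matrix(0L, length(classes), length(classes),
              dimnames = list(classes, classes))
  m[cbind(tab$actual, tab$predicted)] <- as.integer(tab[[col]])
  ConfusionMatrix(m, scheme)
}

#' @rdname reference-tables
#' @return \code{referenceROCSummary}: data.frame(excitation_nm, class, auc,
#'   optimal_sensitivity, one_minus_optimal_specificity, optimal_cutoff).
#' @export
referenceROCSummary <- function()
  utils::read.csv(.refFile("reference_roc_summary.csv"))

#' @rdname reference-tables
#' @return \code{referenceErrorRates}: data.frame(excitation_nm, scheme,
#'   MCC, MCD2w, MCD8w, total) of published error percentages.
#' @export
referenceErrorRates <- function() {
  d <- utils::read.csv(.refFile("reference_error_rates.csv"),
                       check.names = FALSE)
  d
}
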