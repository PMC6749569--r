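#' @import methods
#' @importFrom S4Vectors SimpleList DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom SummarizedExperiment assay<-
NULL

#' Container for fluorescence spectra sharing one wavelength grid
#'
#' A \code{SpectraSet} holds all spectra recorded at a single excitation
#' wavelength: an intensity matrix (wavelength points in rows, spectra in
#' columns) together with per-spectrum metadata (spectrum id, subject id,
#' dietary group) and the ordered log of preprocessing steps already applied.
#' It extends \linkS4class{SummarizedExperiment}; the wavelength grid lives
#' in \code{rowData(x)$wavelength_nm} and must be strictly increasing.
#'
#' @slot .Data see \linkS4class{SummarizedExperiment}
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

.validSpectraSet <- function(object) {
  msg <- NULL
  wl <- rowData(object)$wavelength_nm
  if (is.null(wl))
    msg <- c(msg, "rowData must contain 'wavelength_nm'")
  else if (any(diff(wl) <= 0))
    msg <- c(msg, "wavelength grid must be strictly increasing")
  cd <- colData(object)
  for (f in c("spectrum_id", "subject_id", "group", "excitation_nm"))
    if (!f %in% colnames(cd)) msg <- c(msg, sprintf("colData lacks '%s'", f))
  if ("excitation_nm" %in% colnames(cd) && ncol(object) > 0 &&
      length(unique(cd$excitation_nm)) != 1L)
    msg <- c(msg, "a SpectraSet holds spectra of a single excitation wavelength")
  if (is.null(msg)) TRUE else msg
}
setValidity("SpectraSet", .validSpectraSet)

#' Construct a SpectraSet
#'
#' @param wavelength numeric vector of wavelengths (nm), strictly increasing.
#' @param intensity numeric matrix, \code{length(wavelength)} rows, one column
#'   per spectrum.
#' @param excitation_nm excitation wavelength (nm), one value for the set.
#' @param group character/factor of dietary group labels, one per spectrum.
#' @param subject_id character vector of subject identifiers, one per spectrum.
#' @param spectrum_id optional character vector of unique spectrum ids.
#' @param processing character vector of preprocessing steps already applied.
#' @return A \linkS4class{SpectraSet}.
#' @export
SpectraSet <- function(wavelength, intensity, excitation_nm, group, subject_id,
                       spectrum_id = NULL, processing = character()) {
  intensity <- as.matrix(intensity)
  stopifnot(length(wavelength) == nrow(intensity))
  n <- ncol(intensity)
  if (is.null(spectrum_id))
    spectrum_id <- sprintf("s%04d", seq_len(n))
  cd <- DataFrame(spectrum_id = as.character(spectrum_id),
                  subject_id = as.character(subject_id),
                  group = as.character(group),
                  excitation_nm = rep(as.numeric(excitation_nm), length.out = n))
  colnames(intensity) <- spectrum_id
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = DataFrame(wavelength_nm = as.numeric(wavelength)),
    colData = cd)
  out <- new("SpectraSet", se)
  metadata(out)$processing <- processing
  out
}

#' Spectrometer model: dark counts, relative response and lamp reference
#'
#' Holds the instrument quantities needed for preprocessing: the dark
#' spectrum (counts accumulated with the light path blocked), the relative
#' spectral response (unitless detector sensitivity, strictly positive) and
#' the known emission shape of the calibration lamp from which the response
#' is estimated.  All three are tabulated on the instrument's own wavelength
#' grid and interpolated onto spectrum grids on demand.
#'
#' @slot wavelength numeric, nm, increasing.
#' @slot dark numeric, counts, \eqn{\ge 0}.
#' @slot response numeric, unitless, \eqn{> 0}.
#' @slot lampReference numeric, relative lamp emission, \eqn{> 0}.
#' @export
setClass("InstrumentModel",
  representation(wavelength = "numeric", dark = "numeric",
                 response = "numeric", lampReference = "numeric"))

setValidity("InstrumentModel", function(object) {
  msg <- NULL
  n <- length(object@wavelength)
  if (any(diff(object@wavelength) <= 0))
    msg <- c(msg, "wavelength grid must be strictly increasing")
  if (length(object@dark) != n || length(object@response) != n ||
      length(object@lampReference) != n)
    msg <- c(msg, "dark, response and lampReference must match the grid length")
  if (any(object@dark < 0)) msg <- c(msg, "dark counts must be >= 0")
  if (any(object@response <= 0)) msg <- c(msg, "response must be > 0 everywhere")
  if (is.null(msg)) TRUE else msg
})

#' @rdname InstrumentModel-class
#' @param wavelength,dark,response,lampReference see slot descriptions.
#' @export
InstrumentModel <- function(wavelength, dark, response,
                            lampReference = rep(1, length(wavelength))) {
  new("InstrumentModel", wavelength = as.numeric(wavelength),
      dark = as.numeric(dark), response = as.numeric(response),
      lampReference = as.numeric(lampReference))
}

#' A single fluorophore emission band
#'
#' Emission is modelled as a Gaussian band, optionally with a secondary
#' Gaussian lobe (porphyrins emit a secondary peak near 680 nm).  The
#' excitation efficiency maps each excitation wavelength to a unitless
#' non-negative weight describing how strongly that source excites the
#' fluorophore.
#'
#' @slot name character label, e.g. "NAD(P)H".
#' @slot emissionCenter nm.
#' @slot emissionSigma nm, > 0.
#' @slot excitationEfficiency named numeric (names = excitation nm), >= 0.
#' @slot secondaryCenter,secondarySigma nm; \code{NA} when absent.
#' @slot secondaryFraction fraction of total emission in the secondary lobe,
#'   in [0, 1]; 0 when absent.
#' @export
setClass("FluorophoreBand",
  representation(name = "character", emissionCenter = "numeric",
                 emissionSigma = "numeric", excitationEfficiency = "numeric",
                 secondaryCenter = "numeric", secondarySigma = "numeric",
                 secondaryFraction = "numeric"))

setValidity("FluorophoreBand", function(object) {
  msg <- NULL
  if (object@emissionSigma <= 0) msg <- c(msg, "emissionSigma must be > 0")
  if (any(object@excitationEfficiency < 0))
    msg <- c(msg, "excitation efficiencies must be >= 0")
  if (is.null(names(object@excitationEfficiency)))
    msg <- c(msg, "excitationEfficiency must be named by excitation wavelength")
  if (object@secondaryFraction < 0 || object@secondaryFraction > 1)
    msg <- c(msg, "secondaryFraction must lie in [0, 1]")
  if (object@secondaryFraction > 0 &&
      (is.na(object@secondaryCenter) || is.na(object@secondarySigma) ||
       object@secondarySigma <= 0))
    msg <- c(msg, "secondary lobe requires valid center and sigma")
  if (is.null(msg)) TRUE else msg
})

#' @rdname FluorophoreBand-class
#' @param name,emissionCenter,emissionSigma,excitationEfficiency,secondaryCenter,secondarySigma,secondaryFraction see slots.
#' @export
FluorophoreBand <- function(name, emissionCenter, emissionSigma,
                            excitationEfficiency,
                            secondaryCenter = NA_real_,
                            secondarySigma = NA_real_,
                            secondaryFraction = 0) {
  new("FluorophoreBand", name = name,
      emissionCenter = as.numeric(emissionCenter),
      emissionSigma = as.numeric(emissionSigma),
      excitationEfficiency = excitationEfficiency,
      secondaryCenter = as.numeric(secondaryCenter),
      secondarySigma = as.numeric(secondarySigma),
      secondaryFraction = as.numeric(secondaryFraction))
}

#' Panel of fluorophore bands
#'
#' Named collection of \linkS4class{FluorophoreBand} objects; subset with
#' \code{[[} by fluorophore name.
#'
#' @slot bands named list of \linkS4class{FluorophoreBand}.
#' @export
setClass("FluorophorePanel", representation(bands = "list"))

setValidity("FluorophorePanel", function(object) {
  ok <- vapply(object@bands, is, logical(1), class2 = "FluorophoreBand")
  if (!all(ok)) return("all panel entries must be FluorophoreBand objects")
  nm <- vapply(object@bands, function(b) b@name, character(1))
  if (!identical(unname(nm), names(object@bands)))
    return("panel list names must equal the band names")
  TRUE
})

#' @rdname FluorophorePanel-class
#' @param ... \linkS4class{FluorophoreBand} objects.
#' @export
FluorophorePanel <- function(...) {
  bands <- list(...)
  names(bands) <- vapply(bands, function(b) b@name, character(1))
  new("FluorophorePanel", bands = bands)
}

#' @rdname FluorophorePanel-class
#' @param x a FluorophorePanel.
#' @param i band name or index.
#' @export
setMethod("[[", "FluorophorePanel", function(x, i) x@bands[[i]])

#' @rdname FluorophorePanel-class
#' @export
setMethod("names", "FluorophorePanel", function(x) names(x@bands))

#' Generative parameters of one dietary group
#'
#' Mean fluorophore amplitudes, the between-subject variability, the
#' measurement-noise scale and the lipid-content distribution for one study
#' group (control MCC, or MCD diet for 2 / 8 weeks).
#'
#' @slot group group label.
#' @slot amplitude named numeric of mean band amplitudes (arbitrary units).
#' @slot subjectCV coefficient of variation of the per-subject lognormal
#'   amplitude multiplier.
#' @slot noiseSD additive Gaussian noise scale (counts); the realised
#'   per-point sd is \code{noiseSD * (1 + signal/100)} so noise grows with
#'   local signal above a floor of \code{noiseSD}.
#' @slot lipidMean,lipidSD mean / sd (% area) of the underlying normal from
#'   which lipid content is drawn, truncated at 0.
#' @export
setClass("StageProfile",
  representation(group = "character", amplitude = "numeric",
                 subjectCV = "numeric", noiseSD = "numeric",
                 lipidMean = "numeric", lipidSD = "numeric"))

setValidity("StageProfile", function(object) {
  msg <- NULL
  if (any(object@amplitude < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (is.null(names(object@amplitude)))
    msg <- c(msg, "amplitudes must be named by fluorophore")
  if (object@subjectCV < 0) msg <- c(msg, "subjectCV must be >= 0")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (object@lipidSD <= 0) msg <- c(msg, "lipidSD must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' @rdname StageProfile-class
#' @param group,amplitude,subjectCV,noiseSD,lipidMean,lipidSD see slots.
#' @export
StageProfile <- function(group, amplitude, subjectCV, noiseSD,
                         lipidMean, lipidSD) {
  new("StageProfile", group = group, amplitude = amplitude,
      subjectCV = as.numeric(subjectCV), noiseSD = as.numeric(noiseSD),
      lipidMean = as.numeric(lipidMean), lipidSD = as.numeric(lipidSD))
}

#' Study design: subjects, spectra counts and wavelength grids
#'
#' @slot excitations excitation wavelengths (nm).
#' @slot counts integer matrix of spectra counts, groups x excitations.
#' @slot subjects integer matrix of subjects measured, groups x excitations
#'   (the same animals recur across excitations; an entry smaller than the
#'   group size means only the first so-many subjects were measured there).
#' @slot grid named list (by excitation) of c(start, stop, step) in nm.
#' @export
setClass("StudyDesign",
  representation(excitations = "numeric", counts = "matrix",
                 subjects = "matrix", grid = "list"))

setValidity("StudyDesign", function(object) {
  msg <- NULL
  ex <- as.character(object@excitations)
  if (!identical(colnames(object@counts), ex) ||
      !identical(colnames(object@subjects), ex))
    msg <- c(msg, "counts/subjects columns must be named by the excitations")
  if (!identical(rownames(object@counts), rownames(object@subjects)))
    msg <- c(msg, "counts and subjects must share group rownames")
  if (any(object@counts < 1)) msg <- c(msg, "every spectra count must be >= 1")
  if (any(object@subjects < 1)) msg <- c(msg, "every subject count must be >= 1")
  if (!all(ex %in% names(object@grid)))
    msg <- c(msg, "grid must define (start, stop, step) for every excitation")
  if (is.null(msg)) TRUE else msg
})

#' @rdname StudyDesign-class
#' @param excitations,counts,subjects,grid see slots.
#' @export
StudyDesign <- function(excitations, counts, subjects, grid) {
  new("StudyDesign", excitations = as.numeric(excitations),
      counts = counts, subjects = subjects, grid = grid)
}

#' Principal component model of a spectra matrix
#'
#' @slot center per-wavelength mean removed before projection.
#' @slot loadings matrix, wavelengths x retained components (orthonormal).
#' @slot varianceExplained fractions of total variance, all components,
#'   non-increasing.
#' @slot nComponents number of retained components.
#' @export
setClass("PCAModel",
  representation(center = "numeric", loadings = "matrix",
                 varianceExplained = "numeric", nComponents = "integer"))

setValidity("PCAModel", function(object) {
  msg <- NULL
  if (ncol(object@loadings) != object@nComponents)
    msg <- c(msg, "loadings must have nComponents columns")
  if (any(diff(object@varianceExplained) > 1e-8))
    msg <- c(msg, "explained-variance fractions must be non-increasing")
  if (sum(object@varianceExplained) > 1 + 1e-8)
    msg <- c(msg, "explained-variance fractions must sum to <= 1")
  if (is.null(msg)) TRUE else msg
})

#' Quadratic discriminant model
#'
#' Gaussian classifier with class-specific covariance matrices, fit on
#' principal-component scores.
#'
#' @slot labels class labels (sorted).
#' @slot priors named prior probabilities, summing to 1.
#' @slot means named list of class mean vectors.
#' @slot covariances named list of class covariance matrices (denominator
#'   \eqn{n_k - 1}), symmetric positive definite.
#' @slot logDets cached log-determinants of the covariances.
#' @export
setClass("QDAModel",
  representation(labels = "character", priors = "numeric",
                 means = "list", covariances = "list", logDets = "numeric"))

setValidity("QDAModel", function(object) {
  msg <- NULL
  if (abs(sum(object@priors) - 1) > 1e-8) msg <- c(msg, "priors must sum to 1")
  for (k in object@labels) {
    S <- object@covariances[[k]]
    if (max(abs(S - t(S))) > 1e-8)
      msg <- c(msg, sprintf("covariance of '%s' is not symmetric", k))
  }
  if (is.null(msg)) TRUE else msg
})

#' Confusion matrix with scheme tag
#'
#' @slot counts integer matrix, actual groups in rows, predicted in columns.
#' @slot scheme "classification" (resubstitution) or "cross-validation".
#' @export
setClass("ConfusionMatrix",
  representation(counts = "matrix", scheme = "character"))

setValidity("ConfusionMatrix", function(object) {
  msg <- NULL
  if (!identical(rownames(object@counts), colnames(object@counts)))
    msg <- c(msg, "rows and columns must carry the same group labels")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (!object@scheme %in% c("classification", "cross-validation"))
    msg <- c(msg, "scheme must be 'classification' or 'cross-validation'")
  if (is.null(msg)) TRUE else msg
})

#' @rdname ConfusionMatrix-class
#' @param counts,scheme see slots.
#' @export
ConfusionMatrix <- function(counts, scheme = "classification") {
  new("ConfusionMatrix", counts = as.matrix(counts), scheme = scheme)
}

#' Canonical discriminant plane with gridded decision boundaries
#'
#' @slot axes matrix, feature dimension x 2: the canonical axes (scaled to
#'   unit pooled within-class variance).
#' @slot eigenvalues the two leading eigenvalues of \eqn{W^{-1}B}.
#' @slot center grand mean removed before projection.
#' @slot scores n x 2 canonical scores of the observations.
#' @slot labels observation labels.
#' @slot centroids group centroids in the plane.
#' @slot grid data.frame (can1, can2, predicted): the boundary raster.
#' @export
setClass("CanonicalPlane",
  representation(axes = "matrix", eigenvalues = "numeric", center = "numeric",
                 scores = "matrix", labels = "character",
                 centroids = "matrix", grid = "data.frame"))

setValidity("CanonicalPlane", function(object) {
  if (ncol(object@axes) != 2L || ncol(object@scores) != 2L)
    return("a canonical plane has exactly two axes")
  TRUE
})

#' One-vs-rest ROC curve with Youden optimum
#'
#' @slot positiveClass label treated as positive.
#' @slot thresholds score thresholds, descending (with +/- Inf sentinels).
#' @slot sensitivity,oneMinusSpecificity operating points along the curve,
#'   from (0,0) to (1,1).
#' @slot auc trapezoidal area under the curve.
#' @slot youdenJ maximum of sensitivity + specificity - 1.
#' @slot optimalCutoff score threshold attaining the Youden maximum (ties
#'   resolved toward the lowest threshold, i.e. highest sensitivity).
#' @slot optimalSensitivity,optimalSpecificity operating point at the optimum.
#' @export
setClass("ROCCurve",
  representation(positiveClass = "character", thresholds = "numeric",
                 sensitivity = "numeric", oneMinusSpecificity = "numeric",
                 auc = "numeric", youdenJ = "numeric",
                 optimalCutoff = "numeric", optimalSensitivity = "numeric",
                 optimalSpecificity = "numeric"))

setValidity("ROCCurve", function(object) {
  msg <- NULL
  n <- length(object@thresholds)
  if (length(object@sensitivity) != n ||
      length(object@oneMinusSpecificity) != n)
    msg <- c(msg, "curve arrays must have equal length")
  if (n > 0) {
    if (object@sensitivity[1] != 0 || object@sensitivity[n] != 1)
      msg <- c(msg, "curve must run from sensitivity 0 to 1")
    if (any(diff(object@sensitivity) < 0) ||
        any(diff(object@oneMinusSpecificity) < 0))
      msg <- c(msg, "curve coordinates must be non-decreasing")
  }
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})
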