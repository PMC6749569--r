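# Small in-code fixtures shared across test files.

# A SpectraSet built directly from a matrix (wavelengths x spectra).
toySpectra <- function(wavelength, intensity, excitation_nm = 405,
                       group = NULL, subject_id = NULL) {
  intensity <- as.matrix(intensity)
  n <- ncol(intensity)
  if (is.null(group)) group <- rep("MCC", n)
  if (is.null(subject_id)) subject_id <- sprintf("s%d", seq_len(n))
  SpectraSet(wavelength, intensity, excitation_nm, group, subject_id)
}

# A flat instrument: zero dark, unit response, so preprocessing arithmetic
# can be checked in isolation.
flatInstrument <- function(wl = seq(200, 1100, by = 1))
  InstrumentModel(wl, dark = rep(0, length(wl)),
                  response = rep(1, length(wl)))

# Reduced study designs for fast simulations.
tinyDesign <- function(excitations = c(330, 405), nPerGroup = 10,
                       nSubjects = 3) {
  groups <- c("MCC", "MCD2w", "MCD8w")
  keys <- as.character(excitations)
  counts <- matrix(as.integer(nPerGroup), 3, length(excitations),
                   dimnames = list(groups, keys))
  subjects <- matrix(as.integer(nSubjects), 3, length(excitations),
                     dimnames = list(groups, keys))
  grid <- lapply(keys, function(k) c(start = 425, stop = 820, step = 0.77))
  names(grid) <- keys
  StudyDesign(excitations, counts, subjects, grid)
}

# Stage profiles identical across groups (the generator's null), with or
# without subject-level variability.
identicalProfiles <- function(subjectCV = 0, noiseSD = 1) {
  base <- defaultStageProfiles()$MCC
  lapply(stats::setNames(c("MCC", "MCD2w", "MCD8w"),
                         c("MCC", "MCD2w", "MCD8w")), function(g) {
    p <- base
    p@group <- g
    p@subjectCV <- subjectCV
    p@noiseSD <- noiseSD
    p
  })
}

# Corrected (dark -> sensitivity -> boxcar -> restrict) but NOT normalized
# spectra: the product the spectral-AUC statistics are computed on.
correctedSpectra <- function(sset, instrument = defaultInstrument(),
                             width = 5)
  restrictRange(boxcarSmooth(correctSensitivity(
    subtractDark(sset, instrument), instrument), width))

# Simulated three-class Gaussian scores for discriminant tests.
gaussianClasses <- function(n = 20, dim = 3, shift = c(0, 1.5, -1.5),
                            scale = c(1, 1, 2), seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(1:3, function(k)
    matrix(stats::rnorm(n * dim, shift[k], scale[k]), ncol = dim)))
  list(x = x, labels = rep(c("A", "B", "C"), each = n))
}
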