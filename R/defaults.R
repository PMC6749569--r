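#' Built-in fluorophore panel of liver tissue
#'
#' The main endogenous fluorophores of liver tissue under UV-violet
#' excitation, with Gaussian emission bands and excitation-efficiency
#' patterns reflecting their photophysics: pyridine nucleotides (NAD(P)H)
#' and vitamin A fluoresce strongly under 330-365 nm excitation and not at
#' all at 405/415 nm; flavins (FAD, emission maximum near 520 nm),
#' lipopigments (near 540 nm) and lipofuscin (broad, near 620 nm) are
#' excited across the range; porphyrins (620 nm, with a secondary emission
#' lobe at 680 nm) are excited increasingly strongly as the excitation
#' wavelength grows.
#'
#' @return A \linkS4class{FluorophorePanel}.
#' @export
defaultPanel <- function() {
  eff <- function(...) {
    e <- c(...)
    names(e) <- c("330", "365", "385", "405", "415")
    e
  }
  FluorophorePanel(
    FluorophoreBand("NAD(P)H", 470, 40, eff(1.00, 0.70, 0.15, 0, 0)),
    FluorophoreBand("vitamin A", 490, 45, eff(0.80, 0.40, 0.10, 0, 0)),
    FluorophoreBand("flavins", 520, 35, eff(0.40, 1.00, 0.90, 0.70, 0.60)),
    FluorophoreBand("lipopigments", 540, 45, eff(0.30, 0.50, 0.80, 0.80, 0.80)),
    FluorophoreBand("lipofuscin", 620, 50, eff(0.20, 0.30, 0.60, 0.80, 0.90)),
    FluorophoreBand("porphyrins", 620, 25, eff(0.10, 0.20, 0.40, 0.80, 1.00),
                    secondaryCenter = 680, secondarySigma = 20,
                    secondaryFraction = 0.35))
}

#' Default generative profiles of the three dietary groups
#'
#' Mean band amplitudes grow with diet duration for the lipid-associated
#' fluorophores (lipopigments, lipofuscin, porphyrins) and fall for NAD(P)H
#' and vitamin A, mirroring the progressive intensity growth above 550 nm
#' and the band redshift seen with steatosis progression.  Between-subject
#' variability (subjectCV) and measurement noise grow with stage, producing
#' the growing between-spectrum spread of diseased livers.  Lipid content
#' (% area by morphometry) is drawn from a normal truncated at zero with
#' the stated group means and standard deviations.
#'
#' @return Named list of \linkS4class{StageProfile} objects
#'   (MCC, MCD2w, MCD8w).
#' @export
defaultStageProfiles <- function() {
  amp <- function(nadph, vita, flav, lipo, fusc, porph)
    c("NAD(P)H" = nadph, "vitamin A" = vita, "flavins" = flav,
      "lipopigments" = lipo, "lipofuscin" = fusc, "porphyrins" = porph)
  list(
    MCC = StageProfile("MCC", amp(100, 40, 30, 10, 8, 5),
                       subjectCV = 0.15, noiseSD = 1.0,
                       lipidMean = 0.16, lipidSD = 0.35),
    MCD2w = StageProfile("MCD2w", amp(80, 30, 45, 30, 25, 15),
                         subjectCV = 0.30, noiseSD = 1.5,
                         lipidMean = 6.73, lipidSD = 5.78),
    MCD8w = StageProfile("MCD8w", amp(60, 20, 55, 55, 65, 50),
                         subjectCV = 0.45, noiseSD = 2.0,
                         lipidMean = 10.99, lipidSD = 6.83))
}

#' Default study design
#'
#' 22 subjects (9 control, 6 MCD2w, 7 MCD8w; only 3 MCD2w animals measured
#' at 415 nm) and the per-group, per-excitation spectra counts of the
#' reference study design, totalling 1870 spectra.  Wavelength grids run
#' 425-820 nm in 0.77 nm steps for every excitation.
#'
#' @param countScale optional multiplier on all spectra counts (rounded up),
#'   for reduced-size runs; default 1.
#' @return A \linkS4class{StudyDesign}.
#' @export
defaultStudyDesign <- function(countScale = 1) {
  ex <- c(330, 365, 385, 405, 415)
  groups <- c("MCC", "MCD2w", "MCD8w")
  counts <- matrix(c(132, 133, 136, 145, 137,
                     130, 125, 129, 131, 68,
                     111, 116, 128, 125, 124),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(groups, as.character(ex)))
  if (countScale != 1)
    counts[] <- pmax(1L, ceiling(counts * countScale))
  storage.mode(counts) <- "integer"
  subjects <- matrix(c(9, 9, 9, 9, 9,
                       6, 6, 6, 6, 3,
                       7, 7, 7, 7, 7),
                     nrow = 3, byrow = TRUE,
                     dimnames = list(groups, as.character(ex)))
  storage.mode(subjects) <- "integer"
  grid <- lapply(ex, function(e) c(start = 425, stop = 820, step = 0.77))
  names(grid) <- as.character(ex)
  StudyDesign(ex, counts, subjects, grid)
}

#' Restrict a study design to a subset of excitation wavelengths
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param excitations excitation wavelengths to keep.
#' @return the reduced \linkS4class{StudyDesign}.
#' @export
subsetDesign <- function(design, excitations) {
  keys <- as.character(excitations)
  if (!all(keys %in% colnames(design@counts)))
    stop("unknown excitation wavelength(s) in subset")
  StudyDesign(excitations,
              design@counts[, keys, drop = FALSE],
              design@subjects[, keys, drop = FALSE],
              design@grid[keys])
}

#' Default spectrometer model
#'
#' A smooth synthetic instrument: dark counts slowly rising with wavelength,
#' a bell-shaped relative spectral response peaking near 600 nm, and a
#' blackbody-like calibration-lamp reference shape.  Tabulated on a 1 nm
#' grid over 400-850 nm.
#'
#' @return An \linkS4class{InstrumentModel}.
#' @export
defaultInstrument <- function() {
  wl <- seq(400, 850, by = 1)
  dark <- 90 + 0.01 * wl + 2 * sin(wl / 40)
  response <- 0.55 + 0.45 * exp(-((wl - 600) / 170)^2)
  lamp <- exp(-((wl - 700) / 260)^2)  # smooth incandescent-like shape
  InstrumentModel(wl, dark, response, lamp)
}

#' Default spectral restriction ranges per excitation wavelength
#'
#' The wavelength window retained for analysis, depending on the excitation
#' light (the lower limit keeps clear of the excitation band).
#'
#' @return data.frame with columns excitation_nm, lambda_min, lambda_max.
#' @export
defaultRangeTable <- function() {
  data.frame(
    excitation_nm = c(330, 365, 385, 405, 415),
    lambda_min = c(435.5, 435.5, 440.9, 490.9, 500.2),
    lambda_max = c(721.2, 722.0, 741.6, 795.8, 750.7))
}

#' Default spectral integration intervals per excitation wavelength
#'
#' Limits used for the spectral area-under-curve statistic.  The lower
#' limit rises with the excitation wavelength; comparisons between groups
#' are always made within one excitation, so differing limits across
#' excitations do not bias them.
#'
#' @return data.frame with columns excitation_nm, lower, upper.
#' @export
defaultIntegrationTable <- function() {
  data.frame(
    excitation_nm = c(330, 365, 385, 405, 415),
    lower = c(425, 425, 440, 490, 500),
    upper = c(800, 800, 800, 800, 800))
}

#' Moments of a normal distribution truncated at zero
#'
#' Closed-form mean and sd of \eqn{X \sim N(\mu, \sigma^2)} conditioned on
#' \eqn{X \ge 0}.  Used to document (and test) the realised moments of the
#' simulator's lipid-content draws, which are parameterised by the
#' underlying normal and truncated at zero.
#'
#' @param mean,sd parameters of the underlying (untruncated) normal.
#' @return list with elements \code{mean} and \code{sd} of the truncated
#'   distribution.
#' @export
truncatedNormalMoments <- function(mean, sd) {
  alpha <- -mean / sd
  z <- 1 - stats::pnorm(alpha)
  lambda <- stats::dnorm(alpha) / z
  m <- mean + sd * lambda
  v <- sd^2 * (1 + alpha * lambda - lambda^2)
  list(mean = m, sd = sqrt(v))
}
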