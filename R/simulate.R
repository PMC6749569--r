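#' Evaluate a fluorophore band shape on a wavelength grid
#'
#' Gaussian primary lobe plus an optional secondary Gaussian lobe mixed in
#' with weight \code{secondaryFraction}; the shape peaks near 1 at the
#' primary emission center.
#'
#' @param band a \linkS4class{FluorophoreBand}.
#' @param wavelength numeric grid (nm).
#' @return numeric vector of unitless band intensities.
#' @export
bandShape <- function(band, wavelength) {
  g <- exp(-0.5 * ((wavelength - band@emissionCenter) / band@emissionSigma)^2)
  if (band@secondaryFraction > 0) {
    g2 <- exp(-0.5 * ((wavelength - band@secondaryCenter) /
                        band@secondarySigma)^2)
    g <- (1 - band@secondaryFraction) * g + band@secondaryFraction * g2
  }
  g
}

.instrumentAt <- function(instrument, wavelength, what = c("dark", "response",
                                                           "lampReference")) {
  what <- match.arg(what)
  stats::approx(instrument@wavelength, slot(instrument, what), xout = wavelength,
                rule = 2)$y
}

.excitationEfficiency <- function(band, excitation_nm) {
  key <- as.character(excitation_nm)
  if (!key %in% names(band@excitationEfficiency))
    stop(sprintf("no excitation efficiency defined for %s nm in band '%s'",
                 key, band@name))
  unname(band@excitationEfficiency[key])
}

#' Simulate a complete fluorescence spectroscopy study
#'
#' Generates raw (uncorrected, un-normalized) spectrometer counts for every
#' group and excitation wavelength of the design, plus per-subject lipid
#' contents.  The clean signal of a spectrum is
#' \deqn{\sum_f A_f \, M_{f,subject} \, \eta_f(\lambda_{exc}) \, b_f(\lambda),}
#' where \eqn{A_f} is the group mean amplitude, \eqn{M_{f,subject}} a
#' lognormal per-subject multiplier (CV given by the stage profile),
#' \eqn{\eta_f} the excitation efficiency and \eqn{b_f} the band shape.  The
#' signal is multiplied by the instrument's relative response, dark counts
#' are added, and Gaussian noise with sd \code{noiseSD * (1 + signal/100)}
#' is added per point.
#'
#' The per-subject multiplier \eqn{M_{f,subject} = G_{subject} D_{f,subject}}
#' factorizes into a common intensity factor \eqn{G} shared by all bands
#' (lognormal with CV \code{subjectCV} from the stage profile) and a small
#' band-specific shape jitter \eqn{D_f} (lognormal with CV \code{shapeCV}).
#' The common factor scales the whole spectrum — it drives the
#' between-subject spread of the spectral area statistic but cancels under
#' single-wavelength normalization — while the shape jitter perturbs band
#' ratios, the quantity the classifier sees.
#'
#' Lipid content is drawn per subject from a normal truncated at zero with
#' the profile's (lipidMean, lipidSD).  One latent severity factor per
#' subject — the standardized truncated lipid draw — is mixed (weight
#' \code{coupling}) into the common intensity factor \eqn{G}, so a positive
#' rank correlation between spectral area and lipid content exists by
#' construction; \code{coupling = 0} disables it for null testing.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param panel a \linkS4class{FluorophorePanel}.
#' @param profiles named list of \linkS4class{StageProfile} (one per group
#'   row of the design).
#' @param instrument an \linkS4class{InstrumentModel}.
#' @param seed integer seed; identical seed and configuration give identical
#'   output.
#' @param coupling lipid-fluorescence coupling strength in [0, 1].
#' @param shapeCV coefficient of variation of the per-subject band-specific
#'   shape jitter; 0 disables it.
#' @return list with elements \code{spectra} (a named
#'   \code{\link[S4Vectors]{SimpleList}} of \linkS4class{SpectraSet}, one per
#'   excitation) and \code{lipid} (data.frame: subject_id, group, lipid_pct,
#'   severity).
#' @export
simulateStudy <- function(design = defaultStudyDesign(),
                          panel = defaultPanel(),
                          profiles = defaultStageProfiles(),
                          instrument = defaultInstrument(),
                          seed, coupling = 0.5, shapeCV = 0.10) {
  if (missing(seed)) stop("a seed must be supplied")
  stopifnot(coupling >= 0, coupling <= 1, shapeCV >= 0)
  groups <- rownames(design@counts)
  if (!all(groups %in% names(profiles)))
    stop("profiles must be named for every design group")
  bandNames <- names(panel)
  for (g in groups) {
    unknown <- setdiff(names(profiles[[g]]@amplitude), bandNames)
    if (length(unknown))
      stop(sprintf("unknown fluorophore(s) in profile '%s': %s", g,
                   paste(unknown, collapse = ", ")))
  }
  set.seed(as.integer(seed))

  ## per-subject draws: lipid content and band multipliers
  subjectTab <- list()
  multipliers <- list()   # [[group]][[subject]] named numeric over bands
  for (g in groups) {
    prof <- profiles[[g]]
    nSubj <- max(design@subjects[g, ])
    mu <- prof@lipidMean; sigma <- prof@lipidSD
    alpha <- -mu / sigma
    p0 <- stats::pnorm(alpha)
    mz <- stats::dnorm(alpha) / (1 - p0)           # E[z | z >= alpha]
    vz <- 1 + alpha * mz - mz^2
    sigmaG <- sqrt(log(1 + prof@subjectCV^2))
    sigmaS <- sqrt(log(1 + shapeCV^2))
    mult <- vector("list", nSubj)
    for (j in seq_len(nSubj)) {
      u <- stats::runif(1, p0, 1)
      z <- stats::qnorm(u)
      lipid <- mu + sigma * z
      severity <- (z - mz) / sqrt(vz)
      eps0 <- stats::rnorm(1)
      eps <- stats::rnorm(length(bandNames))
      names(eps) <- bandNames
      G <- exp(sigmaG * (coupling * severity +
                           sqrt(1 - coupling^2) * eps0))
      mult[[j]] <- G * exp(sigmaS * eps)
      subjectTab[[length(subjectTab) + 1L]] <- data.frame(
        subject_id = sprintf("%s_s%d", g, j), group = g,
        lipid_pct = lipid, severity = severity)
    }
    multipliers[[g]] <- mult
  }
  lipid <- do.call(rbind, subjectTab)
  rownames(lipid) <- NULL

  ## per-excitation spectra
  sets <- list()
  for (ex in design@excitations) {
    key <- as.character(ex)
    gr <- design@grid[[key]]
    wl <- seq(gr["start"], gr["stop"], by = gr["step"])
    shapes <- vapply(bandNames, function(b) bandShape(panel[[b]], wl),
                     numeric(length(wl)))
    eff <- vapply(bandNames, function(b)
      .excitationEfficiency(panel[[b]], ex), numeric(1))
    resp <- .instrumentAt(instrument, wl, "response")
    dark <- .instrumentAt(instrument, wl, "dark")
    cols <- list(); meta <- list()
    for (g in groups) {
      prof <- profiles[[g]]
      nSpec <- design@counts[g, key]
      nSubj <- design@subjects[g, key]
      subjIdx <- sort(rep_len(seq_len(nSubj), nSpec))
      amp <- prof@amplitude[bandNames]
      amp[is.na(amp)] <- 0
      for (i in seq_len(nSpec)) {
        j <- subjIdx[i]
        wts <- amp * eff * multipliers[[g]][[j]][bandNames]
        clean <- drop(shapes %*% wts)
        signal <- clean * resp
        noise <- stats::rnorm(length(wl), 0,
                              prof@noiseSD * (1 + signal / 100))
        cols[[length(cols) + 1L]] <- signal + dark + noise
        meta[[length(meta) + 1L]] <- data.frame(
          spectrum_id = sprintf("%s_%s_%03d", g, key, i),
          subject_id = sprintf("%s_s%d", g, j), group = g)
      }
    }
    meta <- do.call(rbind, meta)
    sets[[key]] <- SpectraSet(wl, do.call(cbind, cols), ex,
                              group = meta$group,
                              subject_id = meta$subject_id,
                              spectrum_id = meta$spectrum_id)
  }
  list(spectra = S4Vectors::SimpleList(sets), lipid = lipid)
}
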