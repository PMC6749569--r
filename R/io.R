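#' Write spectra to long-format CSV
#'
#' Columns: spectrum_id, subject_id, group, excitation_nm, wavelength_nm,
#' intensity.  Accepts a single \linkS4class{SpectraSet} or a list of them
#' (one per excitation).
#'
#' @param x a \linkS4class{SpectraSet} or list thereof.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSpectraCSV <- function(x, path) {
  sets <- if (is(x, "SpectraSet")) list(x) else as.list(x)
  tabs <- lapply(sets, function(s) {
    wl <- wavelengths(s)
    m <- intensities(s)
    data.table::data.table(
      spectrum_id = rep(spectrumIds(s), each = length(wl)),
      subject_id = rep(spectrumSubjects(s), each = length(wl)),
      group = rep(spectrumGroups(s), each = length(wl)),
      excitation_nm = excitation(s),
      wavelength_nm = rep(wl, times = ncol(m)),
      intensity = as.vector(m))
  })
  data.table::fwrite(data.table::rbindlist(tabs), path)
  invisible(path)
}

#' Read spectra from long-format CSV
#'
#' Inverse of \code{\link{writeSpectraCSV}}: reconstructs one
#' \linkS4class{SpectraSet} per excitation wavelength found in the file.
#'
#' @param path CSV file as written by \code{\link{writeSpectraCSV}}.
#' @return named list of \linkS4class{SpectraSet} (names = excitation nm).
#' @export
readSpectraCSV <- function(path) {
  dt <- data.table::fread(path)
  dt <- as.data.frame(dt)
  out <- lapply(split(dt, dt$excitation_nm), function(d) {
    d <- d[order(match(d$spectrum_id, unique(d$spectrum_id))), ]
    ids <- unique(d$spectrum_id)
    wl <- d$wavelength_nm[d$spectrum_id == ids[1]]
    m <- matrix(d$intensity, nrow = length(wl),
                dimnames = list(NULL, ids))
    first <- d[!duplicated(d$spectrum_id), ]
    SpectraSet(wl, m, first$excitation_nm[1], group = first$group,
               subject_id = first$subject_id, spectrum_id = ids)
  })
  names(out) <- vapply(out, function(s) as.character(excitation(s)),
                       character(1))
  out
}

#' Read an instrument model from two-column CSV files
#'
#' Each file holds columns (wavelength_nm, value); the dark, response and
#' optional lamp-reference tables are interpolated onto the dark file's
#' grid.
#'
#' @param darkPath,responsePath,lampPath CSV paths (lamp optional).
#' @return an \linkS4class{InstrumentModel}.
#' @export
readInstrumentCSV <- function(darkPath, responsePath, lampPath = NULL) {
  rd <- function(p) {
    d <- utils::read.csv(p)
    stopifnot(ncol(d) >= 2)
    d[order(d[[1]]), 1:2]
  }
  dark <- rd(darkPath)
  resp <- rd(responsePath)
  wl <- dark[[1]]
  r <- stats::approx(resp[[1]], resp[[2]], xout = wl, rule = 2)$y
  lamp <- if (is.null(lampPath)) rep(1, length(wl)) else {
    lt <- rd(lampPath)
    stats::approx(lt[[1]], lt[[2]], xout = wl, rule = 2)$y
  }
  InstrumentModel(wl, dark[[2]], r, lamp)
}
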