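test_that("dark subtraction is pointwise, clipped and grid-checked", {
  wl <- seq(400, 500, by = 1)
  s <- toySpectra(wl, cbind(rep(100, length(wl)), rep(10, length(wl))))
  out <- subtractDark(s, rep(30, length(wl)))
  expect_equal(unname(intensities(out)[, 1]), rep(70, length(wl)))
  # negative results clip to zero (physical counts)
  expect_equal(unname(intensities(out)[, 2]), rep(0, length(wl)))
  expect_identical(processingLog(out), "dark")

  # self-subtraction and zero dark
  raw <- matrix(runif(length(wl)), ncol = 1)
  s2 <- toySpectra(wl, raw)
  expect_equal(unname(intensities(subtractDark(s2, drop(raw)))[, 1]),
               rep(0, length(wl)))
  expect_equal(intensities(subtractDark(s2, rep(0, length(wl)))),
               intensities(s2))
  expect_error(subtractDark(s2, rep(1, 10)), "grid")
})

test_that("boxcar smoothing is a truncated-window moving average", {
  wl <- seq(1, 21)
  y <- 2 * wl + 3                        # linear ramp
  s <- toySpectra(wl, cbind(y))
  sm <- intensities(boxcarSmooth(s, 5))[, 1]
  # oracle: direct windowed mean
  oracle <- vapply(seq_along(y), function(i)
    mean(y[max(1, i - 2):min(length(y), i + 2)]), numeric(1))
  expect_equal(unname(sm), oracle)
  # interior of a linear ramp is unchanged; edges are truncated means
  expect_equal(sm[3:19], y[3:19])
  expect_equal(sm[1], mean(y[1:3]))

  expect_equal(intensities(boxcarSmooth(s, 1)), intensities(s))
  const <- toySpectra(wl, cbind(rep(4, 21)))
  expect_equal(unname(intensities(boxcarSmooth(const, 7))[, 1]), rep(4, 21))
  expect_error(boxcarSmooth(s, 4), "odd")
  expect_error(boxcarSmooth(s, -3), "odd")
  expect_error(boxcarSmooth(s, 23), "width")
})

test_that("sensitivity correction divides out the instrument response", {
  wl <- seq(450, 750, by = 1)
  truth <- exp(-((wl - 600) / 60)^2)
  resp <- 0.4 + 0.6 * cos((wl - 600) / 400)
  distorted <- toySpectra(wl, cbind(truth * resp))
  out <- correctSensitivity(distorted, resp)
  expect_lt(max(abs(intensities(out)[, 1] - truth) / truth), 1e-12)
  expect_identical(processingLog(out), "sensitivity")

  s <- toySpectra(wl, cbind(truth))
  expect_equal(intensities(correctSensitivity(s, rep(1, length(wl)))),
               intensities(s))
  # lamp round trip: response estimated as measured/reference makes any
  # spectrum recorded at another lamp power recover the reference shape up
  # to a scalar
  lampRef <- exp(-((wl - 700) / 200)^2)
  est <- (3 * lampRef * resp) / lampRef      # estimated relative response
  measured2 <- 5 * lampRef * resp            # same lamp, different power
  rec <- intensities(correctSensitivity(toySpectra(wl, cbind(measured2)),
                                        est))[, 1]
  expect_equal(rec / lampRef, rep(5 / 3, length(wl)))
  expect_error(correctSensitivity(s, rep(0, length(wl))), "> 0")
})

test_that("normalization pins the nearest grid point to one and is idempotent", {
  wl <- seq(425, 820, by = 0.77)          # 600.00 nm absent from this grid
  y <- 5 + sin(wl / 50)
  s <- toySpectra(wl, cbind(y, 2 * y))
  out <- normalizeAt(s, 600)
  i <- which.min(abs(wl - 600))
  expect_equal(unname(intensities(out)[i, ]), c(1, 1))
  # scaling a spectrum does not change its normalized shape
  expect_equal(intensities(out)[, 1], intensities(out)[, 2])
  # idempotence
  out2 <- normalizeAt(out, 600)
  expect_equal(intensities(out2), intensities(out))

  const <- toySpectra(wl, cbind(rep(7, length(wl))))
  expect_equal(unname(intensities(normalizeAt(const, 600))[, 1]),
               rep(1, length(wl)))
  zero <- toySpectra(wl, cbind(rep(0, length(wl))))
  expect_error(normalizeAt(zero, 600), "non-positive")
  expect_error(normalizeAt(s, 200), "outside")
})

test_that("range restriction keeps the closed excitation-dependent window", {
  wl <- seq(200, 1100, by = 0.77)
  s <- toySpectra(wl, cbind(seq_along(wl)), excitation_nm = 405)
  out <- restrictRange(s)
  expect_gte(min(wavelengths(out)), 490.9 - 1e-9)
  expect_lte(max(wavelengths(out)), 795.8 + 1e-9)
  # grid points are removed, never altered
  expect_true(all(wavelengths(out) %in% wl))

  # closed lower bound: first retained point of a 490.13 + 0.77k grid
  wl2 <- seq(490.13, 600, by = 0.77)
  s2 <- toySpectra(wl2, cbind(seq_along(wl2)), excitation_nm = 405)
  expect_equal(min(wavelengths(restrictRange(s2))), 490.90)

  inside <- toySpectra(seq(500, 700, by = 1), cbind(rep(1, 201)),
                       excitation_nm = 405)
  expect_equal(dim(restrictRange(inside)), dim(inside))
  s3 <- toySpectra(wl, cbind(seq_along(wl)), excitation_nm = 500)
  expect_error(restrictRange(s3), "no restriction range")
})

test_that("the preprocessing pipeline applies and logs steps in order", {
  sim <- simulateStudy(tinyDesign(405, nPerGroup = 4), seed = 2)
  inst <- defaultInstrument()
  pp <- preprocessSpectra(sim$spectra[["405"]], inst)
  expect_identical(processingLog(pp),
                   c("dark", "sensitivity", "boxcar(5)",
                     "restrict[490.9,795.8]", "normalize(600)"))
  # all steps except restriction preserve the grid
  mid <- boxcarSmooth(correctSensitivity(
    subtractDark(sim$spectra[["405"]], inst), inst), 5)
  expect_equal(wavelengths(mid), wavelengths(sim$spectra[["405"]]))
  expect_lt(length(wavelengths(pp)), length(wavelengths(mid)))
  i <- which.min(abs(wavelengths(pp) - 600))
  expect_equal(unname(intensities(pp)[i, ]),
               rep(1, ncol(pp)), tolerance = 1e-12)
})
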