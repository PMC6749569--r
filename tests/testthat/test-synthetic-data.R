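test_that("default design reproduces the study's spectrum counts", {
  d <- defaultStudyDesign()
  expect_equal(sum(d@counts), 1870L)
  expect_equal(unname(rowSums(d@counts)),
               c(683L, 583L, 604L))
  expect_equal(unname(d@counts["MCD2w", "415"]), 68L)
  expect_equal(unname(d@subjects[, "330"]), c(9L, 6L, 7L))
  expect_equal(unname(d@subjects["MCD2w", "415"]), 3L)

  sim <- simulateStudy(subsetDesign(d, c(330, 415)), seed = 3)
  expect_equal(unname(vapply(sim$spectra, ncol, integer(1))),
               unname(colSums(d@counts[, c("330", "415")])))
  tab <- table(spectrumGroups(sim$spectra[["330"]]))
  expect_equal(as.integer(tab[c("MCC", "MCD2w", "MCD8w")]),
               unname(d@counts[, "330"]))
  # only three MCD2w animals measured at 415 nm
  s415 <- sim$spectra[["415"]]
  expect_equal(length(unique(
    spectrumSubjects(s415)[spectrumGroups(s415) == "MCD2w"])), 3L)
})

test_that("default panel encodes the fluorophore excitation pattern", {
  panel <- defaultPanel()
  expect_identical(unname(panel[["NAD(P)H"]]@excitationEfficiency["415"]), 0)
  expect_identical(unname(panel[["NAD(P)H"]]@excitationEfficiency["405"]), 0)
  expect_identical(unname(panel[["vitamin A"]]@excitationEfficiency["405"]), 0)
  expect_equal(panel[["porphyrins"]]@secondaryCenter, 680)
  for (b in names(panel))
    expect_true(all(panel[[b]]@excitationEfficiency >= 0))
  # porphyrin excitation grows with excitation wavelength
  expect_true(all(diff(panel[["porphyrins"]]@excitationEfficiency) > 0))
  # flavins emit near 520 nm, lipofuscin/porphyrins near 620 nm
  expect_equal(panel[["flavins"]]@emissionCenter, 520)
  expect_equal(panel[["porphyrins"]]@emissionCenter, 620)
})

test_that("degenerate generator is deterministic and group-blind", {
  d <- tinyDesign(405, nPerGroup = 4)
  prof <- identicalProfiles(subjectCV = 0, noiseSD = 0)
  sim <- simulateStudy(d, profiles = prof, seed = 5, shapeCV = 0)
  m <- intensities(sim$spectra[["405"]])
  g <- spectrumGroups(sim$spectra[["405"]])
  # every spectrum identical across groups
  expect_equal(max(abs(sweep(m, 1, m[, 1]))), 0)
  expect_equal(length(unique(g)), 3L)

  # identical seed => byte-identical CSV output
  sim2 <- simulateStudy(d, profiles = prof, seed = 5, shapeCV = 0)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeSpectraCSV(sim$spectra, f1)
  writeSpectraCSV(sim2$spectra, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # and a different seed changes the noise
  sim3 <- simulateStudy(d, seed = 6)
  sim4 <- simulateStudy(d, seed = 7)
  expect_false(identical(intensities(sim3$spectra[["405"]]),
                         intensities(sim4$spectra[["405"]])))
})

test_that("lipid draws follow the zero-truncated normal generator", {
  # oracle: closed-form moments of N(mean, sd) conditioned on >= 0
  oracle <- truncatedNormalMoments(10.99, 6.83)
  # sanity of the closed form itself against direct numeric integration
  f <- function(x) x * dnorm(x, 10.99, 6.83)
  num <- integrate(f, 0, Inf)$value / pnorm(10.99 / 6.83)
  expect_equal(oracle$mean, num, tolerance = 1e-8)

  # Monte-Carlo draws from the generator (3-point grid keeps this cheap)
  groups <- c("MCC", "MCD2w", "MCD8w")
  nSub <- 3000L
  counts <- matrix(nSub, 3, 1, dimnames = list(groups, "405"))
  subjects <- matrix(nSub, 3, 1, dimnames = list(groups, "405"))
  d <- StudyDesign(405, counts, subjects,
                   list("405" = c(start = 600, stop = 602, step = 0.77)))
  sim <- simulateStudy(d, seed = 17)
  lip <- sim$lipid$lipid_pct[sim$lipid$group == "MCD8w"]
  expect_true(all(sim$lipid$lipid_pct >= 0))
  se <- oracle$sd / sqrt(nSub)
  expect_lt(abs(mean(lip) - oracle$mean), 3 * se)
  expect_equal(sd(lip), oracle$sd, tolerance = 0.05)
})

test_that("spectra means rise with stage above 550 nm and spread grows", {
  # full-size single-excitation study: n >= 100 spectra per group
  sim <- simulateStudy(subsetDesign(defaultStudyDesign(), 405), seed = 11)
  cc <- correctedSpectra(sim$spectra[["405"]])
  expect_true(all(table(spectrumGroups(cc)) >= 100))
  m <- intensities(cc)
  g <- spectrumGroups(cc)
  sel <- wavelengths(cc) > 550
  mMCC <- rowMeans(m[sel, g == "MCC"])
  m2w <- rowMeans(m[sel, g == "MCD2w"])
  m8w <- rowMeans(m[sel, g == "MCD8w"])
  expect_true(all(m2w >= mMCC))
  expect_true(all(m8w >= m2w))
  sdBy <- vapply(c("MCC", "MCD2w", "MCD8w"), function(k)
    mean(apply(m[sel, g == k], 1, sd)), numeric(1))
  expect_true(all(diff(sdBy) > 0))
})

test_that("lipid-fluorescence coupling induces a positive rank correlation", {
  sim <- simulateStudy(subsetDesign(defaultStudyDesign(), 405), seed = 11)
  cc <- correctedSpectra(sim$spectra[["405"]])
  auc <- suppressMessages(spectralAUC(cc))
  ps <- subjectMeanAUC(auc)
  lip <- sim$lipid[match(ps$subject_id, sim$lipid$subject_id), ]
  res <- spearmanVsLipid(ps$mean_auc, lip$lipid_pct)
  expect_gt(res$rho, 0)
  expect_lt(res$p, 0.05)
  expect_equal(res$n, 22L)
})

test_that("generator validates its inputs", {
  d <- tinyDesign(405, nPerGroup = 4)
  expect_error(simulateStudy(d), "seed")
  bad <- defaultStageProfiles()
  bad$MCC@amplitude <- c(bad$MCC@amplitude, collagen = 5)
  expect_error(simulateStudy(d, profiles = bad, seed = 1),
               "unknown fluorophore")
  expect_error(StageProfile("MCC", c("flavins" = 1), 0.1, -1, 1, 1),
               "noiseSD")
  expect_error(
    simulateStudy(tinyDesign(500, nPerGroup = 4), seed = 1),
    "excitation")
})
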