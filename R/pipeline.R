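#' Configuration of a full analysis run
#'
#' Collects every tunable of the pipeline into one serializable list so a
#' run can be re-executed bit-identically from its saved configuration.
#'
#' @param seed integer seed driving all randomness.
#' @param outputDir directory for run artifacts.
#' @param design a \linkS4class{StudyDesign}.
#' @param panel a \linkS4class{FluorophorePanel}.
#' @param profiles named list of \linkS4class{StageProfile}.
#' @param instrument an \linkS4class{InstrumentModel}.
#' @param coupling lipid-fluorescence coupling strength.
#' @param boxcarWidth odd smoothing window.
#' @param lambda_ref normalization wavelength (nm).
#' @param rangeTable,integrationTable see \code{\link{restrictRange}} and
#'   \code{\link{spectralAUC}}.
#' @param nComponents retained principal components.
#' @param alpha significance level for the tests.
#' @param priors QDA priors ("empirical" or "uniform").
#' @param rocScores "classification" (resubstitution posteriors) or "loocv"
#'   (held-out posteriors).
#' @param gridResolution canonical-plane raster nodes per axis.
#' @return a list of class \code{runConfig}.
#' @export
runConfig <- function(seed = 1, outputDir = tempfile("steatofluor_run_"),
                      design = defaultStudyDesign(),
                      panel = defaultPanel(),
                      profiles = defaultStageProfiles(),
                      instrument = defaultInstrument(),
                      coupling = 0.5, boxcarWidth = 5, lambda_ref = 600,
                      rangeTable = defaultRangeTable(),
                      integrationTable = defaultIntegrationTable(),
                      nComponents = 6, alpha = 0.05,
                      priors = "empirical",
                      rocScores = c("classification", "loocv"),
                      gridResolution = 400) {
  cfg <- list(seed = as.integer(seed), outputDir = outputDir, design = design,
              panel = panel, profiles = profiles, instrument = instrument,
              coupling = coupling, boxcarWidth = boxcarWidth,
              lambda_ref = lambda_ref, rangeTable = rangeTable,
              integrationTable = integrationTable,
              nComponents = nComponents, alpha = alpha, priors = priors,
              rocScores = match.arg(rocScores),
              gridResolution = gridResolution)
  class(cfg) <- "runConfig"
  cfg
}

.validateConfig <- function(cfg) {
  known <- cfg$rangeTable$excitation_nm
  bad <- setdiff(cfg$design@excitations, known)
  if (length(bad))
    stop(sprintf("configuration invalid: no restriction range for excitation %s nm",
                 paste(bad, collapse = ", ")))
  bad <- setdiff(cfg$design@excitations, cfg$integrationTable$excitation_nm)
  if (length(bad))
    stop(sprintf("configuration invalid: no integration interval for excitation %s nm",
                 paste(bad, collapse = ", ")))
  if (cfg$boxcarWidth < 1 || cfg$boxcarWidth %% 2 == 0)
    stop("configuration invalid: boxcar width must be a positive odd integer")
  invisible(TRUE)
}

.writeJSON <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

#' Execute the full analysis pipeline
#'
#' Runs simulate -> preprocess -> spectral AUC statistics -> PCA ->
#' covariance-equality gate -> QDA (classification + leave-one-out
#' cross-validation) -> canonical plane -> one-vs-rest ROC, independently
#' for every excitation wavelength of the design, and writes all artifacts
#' (spectra and lipid CSVs, AUC table, group-comparison report, paired
#' confusion matrices, error rates under both total-error definitions, ROC
#' report, canonical-plane raster, run log) plus a manifest with MD5
#' checksums into \code{config$outputDir}.  Identical configuration and
#' seed give identical checksums.
#'
#' @param config a \code{\link{runConfig}}.
#' @return invisibly, a list with the in-memory results per excitation and
#'   the manifest path.
#' @export
runAll <- function(config = runConfig()) {
  .validateConfig(config)
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(config$outputDir, "run.log")
  logCon <- file(logPath, "w")
  on.exit(close(logCon), add = TRUE)
  t0 <- proc.time()["elapsed"]
  say <- function(fmt, ...) writeLines(sprintf(
    "[%7.2fs] %s", proc.time()["elapsed"] - t0, sprintf(fmt, ...)), logCon)

  say("simulate: seed %d", config$seed)
  sim <- simulateStudy(config$design, config$panel, config$profiles,
                       config$instrument, seed = config$seed,
                       coupling = config$coupling)
  writeSpectraCSV(sim$spectra, file.path(config$outputDir, "spectra_raw.csv"))
  utils::write.csv(sim$lipid, file.path(config$outputDir, "lipid.csv"),
                   row.names = FALSE)

  results <- list()
  comparison <- list()
  for (key in names(sim$spectra)) {
    ex <- as.numeric(key)
    say("excitation %s nm: preprocess", key)
    ## corrected spectra feed the AUC statistics; the 600 nm-normalized
    ## spectra feed the classifier (normalization removes the intensity
    ## scale the AUC statistic lives on)
    corrected <- restrictRange(
      boxcarSmooth(
        correctSensitivity(
          subtractDark(sim$spectra[[key]], config$instrument),
          config$instrument),
        config$boxcarWidth),
      config$rangeTable)
    pp <- normalizeAt(corrected, config$lambda_ref)
    aucTab <- suppressMessages(spectralAUC(corrected, config$integrationTable))
    cmp <- anovaTukey(aucTab$auc, aucTab$group, config$alpha)
    perSubj <- subjectMeanAUC(aucTab)
    lip <- sim$lipid[match(perSubj$subject_id, sim$lipid$subject_id), ]
    sp <- spearmanVsLipid(perSubj$mean_auc, lip$lipid_pct)
    groupMeans <- tapply(aucTab$auc, aucTab$group, mean)
    groupSDs <- tapply(aucTab$auc, aucTab$group, stats::sd)
    comparison[[key]] <- list(
      excitation_nm = ex,
      auc_group_mean = as.list(groupMeans),
      auc_group_sd = as.list(groupSDs),
      anova = list(F = cmp$F, p = cmp$p),
      tukey = cmp$tukey,
      spearman_vs_lipid = sp)

    say("excitation %s nm: PCA + QDA", key)
    X <- t(intensities(pp))
    pca <- pcaFit(X, config$nComponents)
    scores <- pcaProject(pca, X)
    labels <- spectrumGroups(pp)
    gate <- covarianceEqualityTest(scores, labels, config$alpha)
    model <- qdaFit(scores, labels, config$priors)
    cmClass <- qdaClassify(scores, labels, config$priors)
    cmCV <- qdaLoocv(scores, labels, config$priors)
    say("excitation %s nm: canonical plane + ROC", key)
    plane <- canonicalPlane(scores, labels, config$gridResolution,
                            config$priors)
    posterior <- if (config$rocScores == "loocv")
      qdaLoocvPosteriors(scores, labels, config$priors)
    else qdaPredict(model, scores)$posterior
    roc <- rocReport(posterior, labels)

    results[[key]] <- list(
      excitation_nm = ex, spectra = pp, auc = aucTab, comparison = cmp,
      spearman = sp, pca = pca, scores = scores, gate = gate, model = model,
      confusionClassification = cmClass, confusionCV = cmCV,
      canonicalPlane = plane, roc = roc)

    utils::write.csv(aucTab, file.path(config$outputDir,
      sprintf("auc_%s.csv", key)), row.names = FALSE)
    utils::write.csv(plane@grid, file.path(config$outputDir,
      sprintf("canonical_grid_%s.csv", key)), row.names = FALSE)
  }

  say("render reports")
  rendered <- renderTables(results)
  for (nm in names(rendered))
    utils::write.csv(rendered[[nm]], file.path(config$outputDir,
      sprintf("%s.csv", nm)), row.names = FALSE)
  .writeJSON(lapply(comparison, function(cc) {
    cc$tukey <- as.list(cc$tukey); cc
  }), file.path(config$outputDir, "comparison_report.json"))
  .writeJSON(lapply(results, function(r) list(
    excitation_nm = r$excitation_nm,
    explained_variance = explainedVariance(r$pca),
    covariance_gate = r$gate[c("M", "statistic", "df", "p", "recommend")],
    roc_summary = r$roc$summary, roc_average = r$roc$average)),
    file.path(config$outputDir, "roc_report.json"))

  ## run.log carries wall-clock timings and is excluded so that manifests
  ## of identical runs are byte-identical
  files <- sort(setdiff(list.files(config$outputDir),
                        c("manifest.json", "run.log")))
  manifest <- data.frame(file = files,
    md5 = unname(tools::md5sum(file.path(config$outputDir, files))))
  .writeJSON(list(seed = config$seed, files = manifest),
             file.path(config$outputDir, "manifest.json"))
  say("done: %d artifacts", nrow(manifest))
  invisible(list(results = results, comparison = comparison,
                 manifest = manifest,
                 manifestPath = file.path(config$outputDir, "manifest.json"),
                 outputDir = config$outputDir))
}

#' Render the study's report tables from pipeline results
#'
#' Produces the four report layouts of the reference study: paired
#' "classification, cross-validation" confusion cells, per-group error
#' rates with the total error under both definitions (pooled share of all
#' observations, and unweighted mean of group error rates), the one-vs-rest
#' ROC performance summary, and the spectra-count table.  Percentages are
#' rounded to 1 decimal and ROC quantities to 3 decimals, matching the
#' report precision.
#'
#' @param results the \code{results} element of a \code{\link{runAll}}
#'   return value (or the return value itself).
#' @return named list of data.frames: \code{confusion_pairs},
#'   \code{error_rates}, \code{roc_summary}, \code{spectra_counts}.
#' @export
renderTables <- function(results) {
  if (!is.null(results$results)) results <- results$results
  confRows <- list(); errRows <- list(); rocRows <- list(); cntRows <- list()
  for (r in results) {
    key <- as.character(r$excitation_nm)
    mC <- r$confusionClassification@counts
    mV <- r$confusionCV@counts
    classes <- rownames(mC)
    rates <- list(classification = confusionRates(r$confusionClassification),
                  `cross-validation` = confusionRates(r$confusionCV))
    for (g in classes) {
      row <- data.frame(excitation_nm = r$excitation_nm, actual = g,
                        n = sum(mC[g, ]))
      for (pgrp in classes)
        row[[pgrp]] <- sprintf("%d, %d", mC[g, pgrp], mV[g, pgrp])
      row$success_pct <- sprintf("%.1f, %.1f",
        rates$classification$perGroup$success_pct[match(g, classes)],
        rates$`cross-validation`$perGroup$success_pct[match(g, classes)])
      confRows[[length(confRows) + 1L]] <- row
    }
    for (scheme in names(rates)) {
      rr <- rates[[scheme]]
      row <- data.frame(excitation_nm = r$excitation_nm, scheme = scheme)
      for (g in classes)
        row[[g]] <- round(rr$perGroup$error_pct[match(g, classes)], 1)
      row$total_pooled <- round(rr$totalErrorPooledPct, 1)
      row$total_mean <- round(rr$totalErrorMeanPct, 1)
      errRows[[length(errRows) + 1L]] <- row
    }
    rs <- r$roc$summary
    rs <- rbind(rs, data.frame(class = "Average", auc = r$roc$average$auc,
      optimal_sensitivity = r$roc$average$optimal_sensitivity,
      one_minus_optimal_specificity =
        r$roc$average$one_minus_optimal_specificity,
      optimal_cutoff = NA, youden_j = NA))
    rs <- cbind(excitation_nm = r$excitation_nm, rs)
    num <- vapply(rs, is.numeric, logical(1)) & names(rs) != "excitation_nm"
    rs[num] <- lapply(rs[num], round, digits = 3)
    rocRows[[length(rocRows) + 1L]] <- rs
    cnt <- table(spectrumGroups(r$spectra))
    cntRows[[length(cntRows) + 1L]] <- data.frame(
      excitation_nm = r$excitation_nm, group = names(cnt),
      n_spectra = as.integer(cnt))
  }
  countsWide <- NULL
  if (length(cntRows)) {
    long <- do.call(rbind, cntRows)
    countsWide <- stats::reshape(long, idvar = "group",
                                 timevar = "excitation_nm",
                                 direction = "wide")
    names(countsWide) <- sub("^n_spectra\\.", "", names(countsWide))
    countsWide$Total <- rowSums(countsWide[, -1, drop = FALSE])
    total <- c(group = "Total",
               as.list(colSums(countsWide[, -1, drop = FALSE])))
    countsWide <- rbind(countsWide, as.data.frame(total,
                                                  check.names = FALSE))
    rownames(countsWide) <- NULL
  } else {
    countsWide <- data.frame(group = character(), Total = integer())
  }
  bind <- function(rows, template) if (length(rows)) do.call(rbind, rows)
    else template
  list(
    confusion_pairs = bind(confRows,
      data.frame(excitation_nm = numeric(), actual = character())),
    error_rates = bind(errRows,
      data.frame(excitation_nm = numeric(), scheme = character())),
    roc_summary = bind(rocRows,
      data.frame(excitation_nm = numeric(), class = character())),
    spectra_counts = countsWide)
}
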