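#' Spectral area under the curve
#'
#' Trapezoidal integral of each spectrum over the grid points falling inside
#' the integration interval assigned to the set's excitation wavelength
#' (intersected with the measured grid; a message is emitted when the
#' interval extends beyond the grid, which is expected for some excitations
#' and harmless for within-excitation comparisons).
#'
#' @param x a preprocessed \linkS4class{SpectraSet}.
#' @param table data.frame with columns excitation_nm, lower, upper;
#'   default \code{\link{defaultIntegrationTable}()}.
#' @return data.frame: spectrum_id, subject_id, group, excitation_nm, auc
#'   (intensity x nm).
#' @export
spectralAUC <- function(x, table = defaultIntegrationTable()) {
  ex <- excitation(x)
  i <- match(ex, table$excitation_nm)
  if (is.na(i))
    stop(sprintf("no integration interval defined for excitation %g nm", ex))
  wl <- wavelengths(x)
  a <- table$lower[i]; b <- table$upper[i]
  tol <- 1e-9
  keep <- wl >= a - tol & wl <= b + tol
  if (sum(keep) < 2) stop("integration interval contains no grid segment")
  if (a < min(wl) - tol || b > max(wl) + tol)
    message(sprintf(
      "integration interval [%g, %g] truncated to measured grid [%.2f, %.2f] at %g nm",
      a, b, min(wl), max(wl), ex))
  w <- wl[keep]
  m <- intensities(x)[keep, , drop = FALSE]
  auc <- apply(m, 2, function(y) pracma::trapz(w, y))
  data.frame(spectrum_id = spectrumIds(x), subject_id = spectrumSubjects(x),
             group = spectrumGroups(x), excitation_nm = ex,
             auc = unname(auc))
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Compares a statistic (here, spectral AUC) across groups: overall F test,
#' then all pairwise Tukey honestly-significant-difference comparisons with
#' studentized-range adjusted p-values (Tukey-Kramer for unequal group
#' sizes), flagged at level \code{alpha}.
#'
#' @param values numeric vector of per-spectrum statistics.
#' @param groups group label per value (>= 2 groups, each with >= 2 values).
#' @param alpha significance level, default 0.05.
#' @return list with elements \code{F}, \code{p}, \code{df} (c(between,
#'   within)) and \code{tukey}: data.frame(pair, diff, p_adj, reject).
#' @export
anovaTukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("at least two groups are required")
  if (any(table(groups) < 2)) stop("every group needs at least two values")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      reject = tk[, "p adj"] < alpha, row.names = NULL)
  list(F = tab["groups", "F value"], p = tab["groups", "Pr(>F)"],
       df = c(between = tab["groups", "Df"],
              within = tab["Residuals", "Df"]),
       tukey = tukey, alpha = alpha)
}

#' Spearman correlation of per-subject spectral AUC with lipid content
#'
#' Rank correlation (average ranks for ties) with the t-approximation on
#' n - 2 degrees of freedom for the p-value.
#'
#' @param auc numeric per-subject mean AUC values.
#' @param lipid_pct numeric lipid contents (% area), paired by subject.
#' @return list with elements \code{rho}, \code{p} and \code{n}.
#' @export
spearmanVsLipid <- function(auc, lipid_pct) {
  if (length(auc) != length(lipid_pct))
    stop("auc and lipid_pct must be paired by subject")
  if (length(auc) < 4) stop("at least 4 subjects are required")
  if (stats::sd(auc) == 0 || stats::sd(lipid_pct) == 0)
    stop("correlation undefined for constant input")
  ct <- suppressWarnings(
    stats::cor.test(auc, lipid_pct, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(auc))
}

#' Per-subject mean spectral AUC
#'
#' Averages the per-spectrum AUC values of each subject, the unit on which
#' the correlation with lipid content is computed.
#'
#' @param aucTable data.frame as returned by \code{\link{spectralAUC}}.
#' @return data.frame: subject_id, group, mean_auc, n_spectra.
#' @export
subjectMeanAUC <- function(aucTable) {
  sp <- split(aucTable, aucTable$subject_id)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    subject_id = d$subject_id[1], group = d$group[1],
    mean_auc = mean(d$auc), n_spectra = nrow(d))))
  rownames(out) <- NULL
  out[order(out$subject_id), ]
}
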