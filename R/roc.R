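#' One-vs-rest ROC curve from classifier scores
#'
#' Builds the ROC curve of "predict positive iff score >= threshold" over
#' every distinct observed score, with sentinels at +/- Inf pinning the
#' (0, 0) and (1, 1) endpoints; tied scores collapse into a single step.
#' The area under the curve is computed by the trapezoidal rule, and the
#' Youden-optimal operating point (max sensitivity + specificity - 1, ties
#' resolved toward the lowest threshold, i.e. the most sensitive point) is
#' stored on the curve.
#'
#' @param scores numeric score (e.g. posterior probability of the positive
#'   class) per observation.
#' @param labels observation labels.
#' @param positiveClass label treated as positive; all others are negative.
#' @return a \linkS4class{ROCCurve}.
#' @export
rocCurve <- function(scores, labels, positiveClass) {
  pos <- as.character(labels) == positiveClass
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0)
    stop("both positive and negative observations are required")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(t) sum(scores[pos] >= t) / nP, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / nN, numeric(1))
  auc <- pracma::trapz(fpr, sens)
  j <- sens - fpr
  jmax <- max(j)
  opt <- max(which(j == jmax))   # lowest threshold among ties
  new("ROCCurve", positiveClass = positiveClass, thresholds = thr,
      sensitivity = sens, oneMinusSpecificity = fpr, auc = auc,
      youdenJ = jmax, optimalCutoff = thr[opt],
      optimalSensitivity = sens[opt], optimalSpecificity = 1 - fpr[opt])
}

#' Youden-optimal operating point of a ROC curve
#'
#' Maximizes \eqn{J = sensitivity + specificity - 1} over the curve's
#' thresholds; ties go to the lowest threshold (highest sensitivity).
#'
#' @param curve a \linkS4class{ROCCurve}.
#' @return list: \code{cutoff}, \code{sensitivity}, \code{specificity},
#'   \code{J}.
#' @export
youdenOptimal <- function(curve) {
  list(cutoff = curve@optimalCutoff,
       sensitivity = curve@optimalSensitivity,
       specificity = curve@optimalSpecificity,
       J = curve@youdenJ)
}

#' One-vs-rest ROC report for a multi-class posterior matrix
#'
#' Builds one ROC curve per class (that class positive, the others
#' negative) from the posterior scores of a classifier, plus the arithmetic
#' averages of AUC, optimal sensitivity and 1 - optimal specificity across
#' classes.
#'
#' @param posterior matrix of class posteriors, observations x classes
#'   (column names = class labels).
#' @param labels actual label per observation.
#' @return list: \code{curves} (named list of \linkS4class{ROCCurve}),
#'   \code{summary} (data.frame: class, auc, optimal_sensitivity,
#'   one_minus_optimal_specificity, optimal_cutoff, youden_j),
#'   \code{average} (list: auc, optimal_sensitivity,
#'   one_minus_optimal_specificity).
#' @export
rocReport <- function(posterior, labels) {
  classes <- colnames(posterior)
  if (!all(unique(as.character(labels)) %in% classes))
    stop("labels contain classes missing from the posterior matrix")
  curves <- lapply(classes, function(k)
    rocCurve(posterior[, k], labels, k))
  names(curves) <- classes
  summary <- do.call(rbind, lapply(curves, function(cv) data.frame(
    class = cv@positiveClass, auc = cv@auc,
    optimal_sensitivity = cv@optimalSensitivity,
    one_minus_optimal_specificity = 1 - cv@optimalSpecificity,
    optimal_cutoff = cv@optimalCutoff, youden_j = cv@youdenJ)))
  rownames(summary) <- NULL
  average <- list(auc = mean(summary$auc),
                  optimal_sensitivity = mean(summary$optimal_sensitivity),
                  one_minus_optimal_specificity =
                    mean(summary$one_minus_optimal_specificity))
  list(curves = curves, summary = summary, average = average)
}
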