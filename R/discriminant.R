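#' Fit a principal component model to a spectra matrix
#'
#' Eigen-decomposition of the covariance of mean-centered rows (one
#' observation = one normalized spectrum), retaining \code{nComponents}
#' components (default 6).  A warning is issued when the retained
#' components explain less than \code{varianceFloor} of the total variance.
#'
#' @param x numeric matrix, observations in rows.
#' @param nComponents number of components to keep, default 6.
#' @param varianceFloor explained-variance fraction below which to warn,
#'   default 0.90.
#' @return a \linkS4class{PCAModel}.
#' @export
pcaFit <- function(x, nComponents = 6, varianceFloor = 0.90) {
  x <- as.matrix(x)
  maxRank <- min(nrow(x) - 1L, ncol(x))
  if (nComponents > maxRank)
    stop(sprintf("nComponents (%d) exceeds the rank bound (%d)",
                 nComponents, maxRank))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  varexp <- pc$sdev^2 / sum(pc$sdev^2)
  kept <- sum(varexp[seq_len(nComponents)])
  if (kept < varianceFloor)
    warning(sprintf("retained %d components explain only %.1f%% of variance",
                    nComponents, 100 * kept))
  new("PCAModel", center = pc$center,
      loadings = pc$rotation[, seq_len(nComponents), drop = FALSE],
      varianceExplained = varexp, nComponents = as.integer(nComponents))
}

#' Project observations onto a fitted principal component model
#'
#' @param model a \linkS4class{PCAModel}.
#' @param x numeric matrix, observations in rows (same variables as the fit).
#' @return score matrix, observations x retained components.
#' @export
pcaProject <- function(model, x) {
  x <- as.matrix(x)
  sweep(x, 2, model@center) %*% model@loadings
}

#' Explained-variance fraction of the retained components
#' @param model a \linkS4class{PCAModel}.
#' @return fraction in [0, 1].
#' @export
explainedVariance <- function(model)
  sum(model@varianceExplained[seq_len(model@nComponents)])

.splitByGroup <- function(x, labels) {
  labels <- as.character(labels)
  lapply(split(seq_along(labels), labels),
         function(i) x[i, , drop = FALSE])
}

#' Box's M test of covariance-matrix equality
#'
#' Likelihood-ratio statistic
#' \deqn{M = (N-k)\ln|S_p| - \sum_k (n_k-1)\ln|S_k|}
#' with the standard chi-squared approximation
#' \eqn{\chi^2 = (1-c)M} on \eqn{p(p+1)(k-1)/2} degrees of freedom,
#' where \eqn{S_p} is the pooled covariance and \eqn{c} the Box correction
#' factor.  Gates the choice of discriminant model: quadratic (QDA) is
#' recommended when equality is rejected at level \code{alpha}, linear (LDA)
#' otherwise.
#'
#' @param x numeric matrix of observations (rows) in feature space, or a
#'   named list of per-group matrices.
#' @param labels group label per row (ignored when \code{x} is a list).
#' @param alpha significance level, default 0.05.
#' @return list: \code{M}, \code{statistic} (corrected chi-squared),
#'   \code{df}, \code{p}, \code{recommend} ("QDA" or "LDA").
#' @export
covarianceEqualityTest <- function(x, labels = NULL, alpha = 0.05) {
  byGroup <- if (is.list(x) && !is.data.frame(x)) lapply(x, as.matrix)
             else .splitByGroup(as.matrix(x), labels)
  k <- length(byGroup)
  if (k < 2) stop("at least two groups are required")
  p <- ncol(byGroup[[1]])
  n <- vapply(byGroup, nrow, integer(1))
  if (any(n <= p))
    stop("every group needs more observations than feature dimensions")
  S <- lapply(byGroup, stats::cov)
  N <- sum(n)
  Sp <- Reduce(`+`, Map(function(Si, ni) (ni - 1) * Si, S, n)) / (N - k)
  ld <- function(A) {
    d <- determinant(A, logarithm = TRUE)
    if (d$sign <= 0) stop("singular covariance matrix in Box's M test")
    as.numeric(d$modulus)
  }
  M <- (N - k) * ld(Sp) - sum(mapply(function(Si, ni) (ni - 1) * ld(Si), S, n))
  cf <- (sum(1 / (n - 1)) - 1 / (N - k)) *
    (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (k - 1))
  stat <- M * (1 - cf)
  df <- p * (p + 1) * (k - 1) / 2
  pval <- stats::pchisq(stat, df, lower.tail = FALSE)
  list(M = M, statistic = stat, df = df, p = pval,
       recommend = if (pval < alpha) "QDA" else "LDA", alpha = alpha)
}

#' Fit a quadratic discriminant model
#'
#' Class means and class-specific sample covariances (denominator
#' \eqn{n_k - 1}); priors default to the empirical class frequencies.  A
#' covariance that is exactly singular gets a small ridge
#' (\code{1e-10 x trace}) with a warning; if it remains singular the fit
#' fails naming the group.
#'
#' @param x numeric matrix of observations (rows) in feature space.
#' @param labels class label per row; every class needs more observations
#'   than feature dimensions.
#' @param priors "empirical" (default), "uniform", or a named numeric
#'   vector summing to 1.
#' @return a \linkS4class{QDAModel}.
#' @export
qdaFit <- function(x, labels, priors = "empirical") {
  x <- as.matrix(x)
  labels <- as.character(labels)
  byGroup <- .splitByGroup(x, labels)
  classes <- sort(names(byGroup))
  n <- vapply(byGroup[classes], nrow, integer(1))
  p <- ncol(x)
  if (any(n <= p))
    stop(sprintf("group(s) %s have too few observations for a %d-dim covariance",
                 paste(classes[n <= p], collapse = ", "), p))
  pr <- if (identical(priors, "empirical")) n / sum(n)
        else if (identical(priors, "uniform")) stats::setNames(
          rep(1 / length(classes), length(classes)), classes)
        else priors[classes]
  if (abs(sum(pr) - 1) > 1e-8) stop("priors must sum to 1")
  means <- lapply(byGroup[classes], colMeans)
  covs <- lapply(byGroup[classes], stats::cov)
  logDets <- numeric(length(classes)); names(logDets) <- classes
  for (k in classes) {
    d <- determinant(covs[[k]], logarithm = TRUE)
    if (d$sign <= 0 || !is.finite(as.numeric(d$modulus))) {
      warning(sprintf("covariance of group '%s' is singular; adding ridge", k))
      covs[[k]] <- covs[[k]] + diag(1e-10 * sum(diag(covs[[k]])), p)
      d <- determinant(covs[[k]], logarithm = TRUE)
      if (d$sign <= 0)
        stop(sprintf("covariance of group '%s' is singular", k))
    }
    logDets[k] <- as.numeric(d$modulus)
  }
  new("QDAModel", labels = classes, priors = pr, means = means,
      covariances = covs, logDets = logDets)
}

#' Posterior class probabilities and labels from a quadratic discriminant model
#'
#' Evaluates the Gaussian discriminant
#' \deqn{d_k(x) = \ln\pi_k - \tfrac12\ln|\Sigma_k|
#'   - \tfrac12 (x-\mu_k)^T \Sigma_k^{-1} (x-\mu_k)}
#' for each class and converts to posteriors by a numerically stable
#' softmax.  The predicted label is the argmax; exact ties go to the
#' lexicographically first label (with a message).
#'
#' @param model a \linkS4class{QDAModel}.
#' @param x numeric vector (one observation) or matrix (rows =
#'   observations) matching the model dimension.
#' @return list: \code{label} (character vector), \code{posterior}
#'   (matrix, observations x classes), \code{discriminant} (same shape).
#' @export
qdaPredict <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  p <- length(model@means[[1]])
  if (ncol(x) != p)
    stop(sprintf("observation dimension %d does not match model dimension %d",
                 ncol(x), p))
  classes <- model@labels
  disc <- matrix(NA_real_, nrow(x), length(classes),
                 dimnames = list(NULL, classes))
  for (k in classes) {
    ct <- chol(model@covariances[[k]])
    dev <- sweep(x, 2, model@means[[k]])
    maha <- colSums(backsolve(ct, t(dev), transpose = TRUE)^2)
    disc[, k] <- log(model@priors[k]) - 0.5 * model@logDets[k] - 0.5 * maha
  }
  mx <- apply(disc, 1, max)
  post <- exp(disc - mx)
  post <- post / rowSums(post)
  idx <- apply(disc, 1, function(d) {
    w <- which(d == max(d))
    if (length(w) > 1) message("discriminant tie broken lexicographically")
    w[1]
  })
  list(label = classes[idx], posterior = post, discriminant = disc)
}

#' Resubstitution confusion matrix of a quadratic discriminant model
#'
#' Fits QDA on all observations and classifies those same observations
#' (the "classification" scheme of the study reports).
#'
#' @inheritParams qdaFit
#' @return a \linkS4class{ConfusionMatrix} with scheme "classification".
#' @export
qdaClassify <- function(x, labels, priors = "empirical") {
  model <- qdaFit(x, labels, priors)
  pred <- qdaPredict(model, x)$label
  .confusionFrom(labels, pred, model@labels, "classification")
}

#' Leave-one-out cross-validated confusion matrix
#'
#' For each observation, refits the quadratic discriminant model on all
#' other observations and predicts the held-out one.  Deterministic.
#'
#' @inheritParams qdaFit
#' @return a \linkS4class{ConfusionMatrix} with scheme "cross-validation".
#' @export
qdaLoocv <- function(x, labels, priors = "empirical") {
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  classes <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts - 1 <= ncol(x)))
    stop("leave-one-out deletion leaves too few observations in some group")
  pred <- character(n)
  for (i in seq_len(n)) {
    m <- qdaFit(x[-i, , drop = FALSE], labels[-i], priors)
    pred[i] <- qdaPredict(m, x[i, ])$label
  }
  .confusionFrom(labels, pred, classes, "cross-validation")
}

#' Leave-one-out cross-validated posterior scores
#'
#' Same refit loop as \code{\link{qdaLoocv}}, but returns the held-out
#' posterior matrix (for honest ROC evaluation).
#'
#' @inheritParams qdaFit
#' @return matrix of posteriors, observations x classes.
#' @export
qdaLoocvPosteriors <- function(x, labels, priors = "empirical") {
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  post <- matrix(NA_real_, nrow(x), length(classes),
                 dimnames = list(NULL, classes))
  for (i in seq_len(nrow(x))) {
    m <- qdaFit(x[-i, , drop = FALSE], labels[-i], priors)
    post[i, ] <- qdaPredict(m, x[i, ])$posterior
  }
  post
}

.confusionFrom <- function(actual, predicted, classes, scheme) {
  counts <- table(factor(actual, levels = classes),
                  factor(predicted, levels = classes))
  m <- matrix(as.integer(counts), length(classes), length(classes),
              dimnames = list(classes, classes))
  ConfusionMatrix(m, scheme)
}

#' Success and error rates of a confusion matrix
#'
#' Per-group success is the diagonal share of the row total; error is its
#' complement.  The total error is reported under both conventions found in
#' practice: pooled (misclassified observations over all observations) and
#' the unweighted mean of the per-group error rates.
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @return list: \code{perGroup} data.frame(group, n, success_pct,
#'   error_pct), \code{totalErrorPooledPct}, \code{totalErrorMeanPct},
#'   \code{totalSuccessPct} (pooled), \code{scheme}.
#' @export
confusionRates <- function(cm) {
  m <- cm@counts
  rowTotals <- rowSums(m)
  if (any(rowTotals == 0)) stop("confusion matrix has an empty actual group")
  success <- 100 * diag(m) / rowTotals
  perGroup <- data.frame(group = rownames(m), n = as.integer(rowTotals),
                         success_pct = unname(success),
                         error_pct = unname(100 - success))
  pooledErr <- 100 * (sum(m) - sum(diag(m))) / sum(m)
  list(perGroup = perGroup,
       totalErrorPooledPct = pooledErr,
       totalErrorMeanPct = mean(100 - success),
       totalSuccessPct = 100 - pooledErr,
       scheme = cm@scheme)
}

#' Canonical discriminant plane with gridded decision boundaries
#'
#' Canonical axes are the leading eigenvectors of \eqn{W^{-1}B} (pooled
#' within-class scatter \eqn{W}, between-class scatter \eqn{B}), scaled to
#' unit pooled within-class variance; with three groups there are exactly
#' two.  Observations are projected onto the plane, and a quadratic
#' discriminant model refit on the 2-D canonical scores classifies each
#' node of a regular grid spanning the observed scores (plus a 10% margin)
#' to raster the decision boundaries.
#'
#' @param x numeric matrix of observations (rows) in feature space.
#' @param labels class label per row (3 classes).
#' @param gridResolution nodes per axis for the boundary raster,
#'   default 400.
#' @param priors passed to the 2-D QDA refit.
#' @return a \linkS4class{CanonicalPlane}.
#' @export
canonicalPlane <- function(x, labels, gridResolution = 400,
                           priors = "empirical") {
  x <- as.matrix(x)
  labels <- as.character(labels)
  byGroup <- .splitByGroup(x, labels)
  classes <- sort(names(byGroup))
  k <- length(classes)
  n <- vapply(byGroup[classes], nrow, integer(1))
  N <- sum(n)
  grand <- colMeans(x)
  W <- Reduce(`+`, lapply(byGroup, function(g)
    (nrow(g) - 1) * stats::cov(g)))
  B <- Reduce(`+`, Map(function(g, ni) {
    d <- colMeans(g) - grand
    ni * tcrossprod(d)
  }, byGroup[classes], n))
  Winv <- tryCatch(solve(W), error = function(e)
    stop("singular pooled within-class scatter"))
  eig <- eigen(Winv %*% B)
  ord <- order(Re(eig$values), decreasing = TRUE)
  nAxes <- min(2L, k - 1L)
  vals <- Re(eig$values[ord])[seq_len(nAxes)]
  A <- Re(eig$vectors[, ord[seq_len(nAxes)], drop = FALSE])
  if (nAxes < 2L) {  # rank-deficient label set: pad a null second axis
    A <- cbind(A, 0)
    vals <- c(vals, 0)
  }
  ## scale each axis to unit pooled within-class variance
  for (j in 1:2) {
    s <- sqrt(drop(t(A[, j]) %*% (W / (N - k)) %*% A[, j]))
    if (s > 0) A[, j] <- A[, j] / s
  }
  scores <- sweep(x, 2, grand) %*% A
  colnames(scores) <- c("can1", "can2")
  centroids <- do.call(rbind, lapply(classes, function(g)
    colMeans(scores[labels == g, , drop = FALSE])))
  rownames(centroids) <- classes
  ## decision-boundary raster from a QDA refit on the canonical scores
  pad <- function(r) r + c(-1, 1) * 0.10 * diff(r)
  rx <- pad(range(scores[, 1])); ry <- pad(range(scores[, 2]))
  gx <- seq(rx[1], rx[2], length.out = gridResolution)
  gy <- seq(ry[1], ry[2], length.out = gridResolution)
  grid <- expand.grid(can1 = gx, can2 = gy)
  q2 <- qdaFit(scores, labels, priors)
  grid$predicted <- qdaPredict(q2, as.matrix(grid))$label
  new("CanonicalPlane", axes = A, eigenvalues = vals, center = grand,
      scores = scores, labels = labels, centroids = centroids, grid = grid)
}
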