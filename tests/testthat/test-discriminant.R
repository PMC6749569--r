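test_that("PCA matches a direct covariance eigendecomposition", {
  set.seed(21)
  x <- matrix(rnorm(15), 5, 3)
  fit <- pcaFit(x, nComponents = 2)
  eig <- eigen(cov(x), symmetric = TRUE)
  varexp <- eig$values / sum(eig$values)
  expect_equal(fit@varianceExplained, varexp, tolerance = 1e-12)
  for (j in 1:2)   # loadings agree up to sign
    expect_equal(abs(drop(crossprod(fit@loadings[, j], eig$vectors[, j]))), 1,
                 tolerance = 1e-10)
  expect_equal(unname(crossprod(fit@loadings)), diag(2), tolerance = 1e-12)

  # projection reproduces prcomp scores
  expect_equal(unname(pcaProject(fit, x)),
               unname(prcomp(x)$x[, 1:2]), tolerance = 1e-12)

  # variation along a single direction: PC1 explains everything
  v <- c(1, 2, -1) / sqrt(6)
  x1 <- outer(rnorm(10), v)
  f1 <- suppressWarnings(pcaFit(x1, nComponents = 1))
  expect_equal(f1@varianceExplained[1], 1)

  expect_error(pcaFit(x, nComponents = 5), "rank")
  expect_warning(pcaFit(matrix(rnorm(40), 10, 4), nComponents = 1,
                        varianceFloor = 0.99), "explain")
})

test_that("Box's M is zero for identical groups and gates toward LDA/QDA", {
  set.seed(31)
  g <- matrix(rnorm(60), 20, 3)
  x <- rbind(g, g, g)
  lab <- rep(c("a", "b", "c"), each = 20)
  res <- covarianceEqualityTest(x, lab)
  expect_equal(res$M, 0, tolerance = 1e-9)
  expect_equal(res$df, 12)
  expect_identical(res$recommend, "LDA")

  # grossly unequal covariances are detected
  y <- rbind(matrix(rnorm(300), ncol = 3), matrix(rnorm(300, sd = 4), ncol = 3))
  res2 <- covarianceEqualityTest(y, rep(c("a", "b"), each = 100))
  expect_lt(res2$p, 1e-10)
  expect_identical(res2$recommend, "QDA")
  expect_error(covarianceEqualityTest(matrix(rnorm(12), 4, 3),
                                      c("a", "a", "b", "b")),
               "more observations")
})

test_that("QDA posteriors equal the explicit Gaussian Bayes rule", {
  d <- gaussianClasses(n = 25, seed = 41)
  model <- qdaFit(d$x, d$labels)
  pred <- qdaPredict(model, d$x)
  expect_equal(unname(rowSums(pred$posterior)), rep(1, nrow(d$x)),
               tolerance = 1e-12)
  expect_true(all(pred$posterior > 0 & pred$posterior < 1))

  # oracle: densities computed from the fitted means/covariances directly
  dens <- vapply(model@labels, function(k) {
    S <- model@covariances[[k]]
    mu <- model@means[[k]]
    apply(d$x, 1, function(v) {
      q <- drop(t(v - mu) %*% solve(S) %*% (v - mu))
      model@priors[k] * exp(-q / 2) / sqrt((2 * pi)^3 * det(S))
    })
  }, numeric(nrow(d$x)))
  bayes <- dens / rowSums(dens)
  expect_equal(unname(pred$posterior), unname(bayes), tolerance = 1e-10)

  # independent library cross-check
  mq <- MASS::qda(d$x, grouping = d$labels)
  expect_equal(unname(pred$posterior),
               unname(predict(mq, d$x)$posterior), tolerance = 1e-8)

  # adding a constant to all discriminants leaves posteriors unchanged
  shifted <- exp(pred$discriminant + 7)
  expect_equal(unname(shifted / rowSums(shifted)), unname(pred$posterior),
               tolerance = 1e-10)

  expect_error(qdaPredict(model, c(1, 2)), "dimension")
})

test_that("1-D decision points match the closed-form quadratic roots", {
  # equal variances and priors: boundary at the midpoint of the means
  set.seed(51)
  xa <- rnorm(40, 0, 1); xb <- rnorm(40, 4, 1)
  m <- qdaFit(cbind(c(xa, xb)), rep(c("a", "b"), each = 40))
  mid <- (m@means$a + m@means$b) / 2
  # with equal sample variances the flip would be exactly at mid; force them
  m@covariances$a <- matrix(1); m@covariances$b <- matrix(1)
  m@logDets[] <- 0
  m@priors[] <- 0.5
  expect_identical(qdaPredict(m, mid - 1e-6)$label, "a")
  expect_identical(qdaPredict(m, mid + 1e-6)$label, "b")

  # unequal variances: roots of the quadratic equal-discriminant equation
  xc <- rnorm(60, 1, 0.8); xd <- rnorm(60, 5, 2.5)
  m2 <- qdaFit(cbind(c(xc, xd)), rep(c("c", "d"), each = 60))
  s1 <- drop(m2@covariances$c); s2 <- drop(m2@covariances$d)
  mu1 <- drop(m2@means$c); mu2 <- drop(m2@means$d)
  p1 <- m2@priors["c"]; p2 <- m2@priors["d"]
  A <- 1 / s2 - 1 / s1
  B <- 2 * (mu1 / s1 - mu2 / s2)
  C <- mu2^2 / s2 - mu1^2 / s1 + log(s2 / s1) - 2 * log(p1 / p2)
  roots <- sort(Re(polyroot(c(C, B, A))))
  for (r in roots) {
    da <- qdaPredict(m2, r - 1e-7)$label
    db <- qdaPredict(m2, r + 1e-7)$label
    expect_false(identical(da, db))
  }

  # single class: posterior 1 everywhere
  m3 <- qdaFit(cbind(rnorm(10)), rep("only", 10))
  p <- qdaPredict(m3, cbind(c(-5, 0, 5)))
  expect_equal(unname(p$posterior[, 1]), rep(1, 3))
  expect_identical(p$label, rep("only", 3))
})

test_that("LOOCV equals an explicit manual refit loop", {
  # far-apart clusters: cross-validated success is 100%
  set.seed(61)
  x <- cbind(c(rnorm(10), rnorm(10, 50)), c(rnorm(10), rnorm(10, 50)))
  lab <- rep(c("lo", "hi"), each = 10)
  cm <- qdaLoocv(x, lab)
  expect_equal(sum(diag(cm@counts)), 20L)
  expect_identical(cm@scheme, "cross-validation")
  # equals resubstitution when classes never overlap
  expect_equal(cm@counts, qdaClassify(x, lab)@counts)

  # n = 9 toy set vs a brute-force Gaussian-Bayes refit loop
  set.seed(62)
  x9 <- cbind(c(rnorm(4, 0, 1), rnorm(5, 2, 2)))
  l9 <- rep(c("p", "q"), c(4, 5))
  pred <- character(9)
  for (i in 1:9) {
    xt <- x9[-i, 1]; lt <- l9[-i]
    post <- vapply(c("p", "q"), function(k) {
      xi <- xt[lt == k]
      (length(xi) / 8) * dnorm(x9[i, 1], mean(xi), sd(xi))
    }, numeric(1))
    pred[i] <- names(which.max(post))
  }
  oracle <- table(factor(l9, c("p", "q")), factor(pred, c("p", "q")))
  cm9 <- qdaLoocv(x9, l9)
  expect_equal(unname(cm9@counts), unname(matrix(as.integer(oracle), 2, 2)))

  expect_error(qdaLoocv(cbind(rnorm(4)), rep(c("a", "b"), 2)), "too few")
})

test_that("confusion rates report both total-error definitions", {
  m <- matrix(c(8, 2, 0,
                1, 9, 0,
                0, 3, 7), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  r <- confusionRates(ConfusionMatrix(m))
  expect_equal(r$perGroup$success_pct, c(80, 90, 70))
  expect_equal(r$totalErrorPooledPct, 100 * 6 / 30)
  expect_equal(r$totalErrorMeanPct, mean(c(20, 10, 30)))
  expect_equal(r$totalSuccessPct, 80)

  perfect <- ConfusionMatrix(diag(5L)[1:3, 1:3] * 10L)
  dimnames(perfect@counts) <- list(c("A", "B", "C"), c("A", "B", "C"))
  rp <- confusionRates(perfect)
  expect_true(all(rp$perGroup$error_pct == 0))
  expect_equal(rp$totalErrorPooledPct, 0)

  bad <- m; bad["B", ] <- 0L
  expect_error(confusionRates(ConfusionMatrix(bad)), "empty")
})

test_that("canonical plane matches the generalized eigenproblem oracle", {
  d <- gaussianClasses(n = 30, dim = 3, shift = c(0, 3, -3), seed = 71)
  pl <- canonicalPlane(d$x, d$labels, gridResolution = 25)
  expect_equal(ncol(pl@axes), 2L)
  expect_equal(ncol(pl@scores), 2L)

  # oracle: eigenvalues of W^{-1} B by direct inversion
  groups <- split(seq_len(nrow(d$x)), d$labels)
  grand <- colMeans(d$x)
  W <- Reduce(`+`, lapply(groups, function(i)
    (length(i) - 1) * cov(d$x[i, ])))
  B <- Reduce(`+`, lapply(groups, function(i) {
    dd <- colMeans(d$x[i, ]) - grand
    length(i) * tcrossprod(dd)
  }))
  ev <- sort(Re(eigen(solve(W) %*% B)$values), decreasing = TRUE)[1:2]
  expect_equal(pl@eigenvalues, ev, tolerance = 1e-8)

  # axes have unit pooled within-class variance
  N <- nrow(d$x); k <- 3
  for (j in 1:2)
    expect_equal(drop(t(pl@axes[, j]) %*% (W / (N - k)) %*% pl@axes[, j]),
                 1, tolerance = 1e-8)

  # raster covers the observed scores and uses the class labels
  expect_true(all(pl@grid$predicted %in% c("A", "B", "C")))
  expect_equal(nrow(pl@grid), 25^2)
  expect_true(min(pl@grid$can1) <= min(pl@scores[, 1]))
  expect_true(max(pl@grid$can2) >= max(pl@scores[, 2]))

  # merging two groups into one label leaves a single discriminant axis
  lab2 <- ifelse(d$labels == "C", "AB", "AB2")
  lab2[d$labels == "B"] <- "AB"   # two of the three groups share a label
  pl2 <- suppressWarnings(canonicalPlane(d$x, lab2, gridResolution = 10))
  expect_lt(pl2@eigenvalues[2] / pl2@eigenvalues[1], 1e-10)
})
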