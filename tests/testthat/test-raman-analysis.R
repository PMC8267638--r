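test_that("PCA detects the intrinsic dimension of planar data", {
  set.seed(1)
  basis <- matrix(rnorm(2 * 40), 2, 40)
  X <- matrix(rnorm(60 * 2), 60, 2) %*% basis +
    matrix(rep(rnorm(40), each = 60), 60)
  model <- fitSpectralPCA(X, 0.99)
  expect_equal(model@nComponents, 2L)
  expect_true(all(diff(model@varianceExplained) <= 1e-12))
})

test_that("PCA loadings are invariant to sample duplication (up to sign)", {
  set.seed(2)
  X <- matrix(rnorm(30 * 12), 30, 12)
  m1 <- fitSpectralPCA(X, 0.9)
  m2 <- fitSpectralPCA(rbind(X, X), 0.9)
  k <- min(m1@nComponents, m2@nComponents)
  for (j in seq_len(k))
    expect_equal(abs(sum(m1@loadings[, j] * m2@loadings[, j])), 1,
                 tolerance = 1e-6)
  expect_error(fitSpectralPCA(X[1, , drop = FALSE]), "at least 2")
  expect_error(fitSpectralPCA(X, variance_target = 0), "variance_target")
})

test_that("PCA reconstruction error is non-increasing in component count", {
  set.seed(3)
  X <- matrix(rnorm(50 * 20), 50, 20) %*% diag(seq(2, 0.1,
                                                   length.out = 20))
  model <- fitSpectralPCA(X, 1, max_components = 10)
  errs <- vapply(1:10, function(k) {
    L <- model@loadings[, seq_len(k), drop = FALSE]
    Xc <- sweep(X, 2, model@center)
    sum((Xc - Xc %*% L %*% t(L))^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("spectral PCA separates the six synthetic classes", {
  X <- NULL; labs <- character(0)
  for (cl in pituitaryClasses()) {
    sp <- tissueClassSpec(cl, noise_sd = 0.05)
    pm <- preprocessMap(generateRamanMap(sp, n_positions = 25,
                                         seed = match(cl,
                                                      pituitaryClasses()),
                                         axis = seq(600, 3100, by = 4)))
    X <- rbind(X, spectra(pm))
    labs <- c(labs, rep(cl, nrow(spectra(pm))))
  }
  model <- fitSpectralPCA(X, 0.999, max_components = 3)
  sc <- projectSpectra(model, X)
  expect_gt(meanSilhouette(sc, labs, d = 3), 0)
})

test_that("the SVM separates separable clouds and fails chance on permuted labels", {
  set.seed(4)
  a <- matrix(rnorm(40 * 2), 40, 2)
  b <- matrix(rnorm(40 * 2, mean = 6), 40, 2)
  X <- rbind(a, b); y <- rep(c("a", "b"), each = 40)
  fit <- trainSpectraSVM(X, y)
  expect_equal(as.character(predict(fit, X)), y)
  expect_error(trainSpectraSVM(X, rep("a", 80)), "2 classes")
  ## permutation null on a balanced 6-class problem ~ 1/6
  set.seed(5)
  X6 <- matrix(rnorm(120 * 4), 120, 4)
  y6 <- rep(letters[1:6], each = 20)
  accs <- vapply(1:20, function(i) {
    yp <- sample(y6)
    tr <- rep(c(TRUE, FALSE), length.out = 120)
    fit <- trainSpectraSVM(X6[tr, ], yp[tr])
    mean(predict(fit, X6[!tr, ]) == yp[!tr])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 6), 0.1)
})

test_that("multiclass metrics match the arithmetic oracle", {
  cm <- matrix(c(8, 0, 1, 1, 9, 0, 1, 1, 9), 3, 3,
               dimnames = list(c("c0", "c1", "c2"), c("c0", "c1", "c2")))
  rep <- multiclassMetrics(cm)
  m0 <- rep@metrics[rep@metrics$class == "c0", ]
  expect_equal(m0$sensitivity, 0.8)
  expect_equal(m0$specificity, 0.95)
  ## brute-force per-sample oracle on random predictions
  set.seed(6)
  classes <- letters[1:4]
  truth <- sample(classes, 200, replace = TRUE)
  pred <- sample(classes, 200, replace = TRUE)
  cm2 <- unclass(table(factor(truth, classes), factor(pred, classes)))
  rep2 <- multiclassMetrics(cm2)
  for (cl in classes) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    tn <- sum(truth != cl & pred != cl)
    row <- rep2@metrics[rep2@metrics$class == cl, ]
    expect_equal(row$sensitivity, tp / (tp + fn))
    expect_equal(row$specificity, tn / (tn + fp))
    expect_equal(row$accuracy, (tp + tn) / 200)
  }
})

test_that("perfect and degenerate predictions yield the contract metrics", {
  cm <- diag(c(10, 12, 9))
  dimnames(cm) <- list(letters[1:3], letters[1:3])
  rep <- multiclassMetrics(cm)
  expect_true(all(rep@metrics$accuracy == 1))
  expect_true(all(rep@metrics$sensitivity == 1))
  ## everything predicted as class a on a balanced set
  cm2 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  cm2[, 1] <- 10
  rep2 <- multiclassMetrics(cm2)
  expect_equal(rep2@metrics$sensitivity[rep2@metrics$class == "a"], 1)
  expect_equal(rep2@metrics$specificity[rep2@metrics$class == "a"], 0)
})

test_that("band ratios follow forced arithmetic and scale invariance", {
  ax <- seq(600, 3100, 1)
  s <- 0.8 * exp(-(ax - 1445)^2 / 128) + 0.2 * exp(-(ax - 720)^2 / 128)
  r <- bandRatio(s, ax, 1445, 720)
  expect_equal(r, mean(s[abs(ax - 1445) <= 5]) /
                 mean(s[abs(ax - 720) <= 5]))
  expect_equal(bandRatio(5.5 * s, ax, 1445, 720), r)
  expect_warning(bad <- bandRatio(s - 10, ax, 1445, 720),
                 "non-positive")
  expect_true(is.na(bad))
  expect_error(bandRatio(s, ax, 9999, 720), "outside")
})

test_that("lipids/DNA ratio orders lactotroph above gland on noise-free maps", {
  r3 <- vapply(c("gland", "lactotroph"), function(cl) {
    sp <- tissueClassSpec(cl, noise_sd = 0)
    pm <- preprocessMap(generateRamanMap(sp, n_positions = 1, seed = 1))
    bandRatio(spectra(pm)[1, ], wavenumbers(pm), 1445, 720)
  }, numeric(1))
  expect_gt(r3["lactotroph"], r3["gland"])
})

test_that("one-way ANOVA behaves at both extremes", {
  expect_message(p <- anovaRatios(data.frame(R = rep(1, 6)),
                                  rep(c("a", "b"), each = 3)),
                 "degenerate")
  expect_equal(unname(p), 1)
  set.seed(7)
  p2 <- anovaRatios(data.frame(R = c(rnorm(50), rnorm(50, 5))),
                    rep(c("a", "b"), each = 50))
  expect_lt(unname(p2), 1e-6)
  expect_error(anovaRatios(data.frame(R = 1:3), c("a", "a", "b")),
               ">= 2 samples")
})
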