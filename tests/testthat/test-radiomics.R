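fullMask <- function(n, m = n) matrix(TRUE, n, m)

test_that("fixed-bin-size discretization follows the binning formula", {
  img <- matrix(c(0, 0.5, 1.0, 2.6), 2, 2)
  d <- discretizeImage(img, fullMask(2), 1)
  expect_equal(sort(as.vector(d@bins)), c(1, 1, 2, 3))
  expect_equal(d@nBins, 3L)
  ## constant region
  dc <- discretizeImage(matrix(4, 3, 3), fullMask(3), 0.5)
  expect_equal(unique(as.vector(dc@bins)), 1L)
  expect_equal(dc@nBins, 1L)
  ## shift invariance (min-anchored)
  d2 <- discretizeImage(img + 7.3, fullMask(2), 1)
  expect_equal(d2@bins, d@bins)
  expect_error(discretizeImage(img, matrix(FALSE, 2, 2), 1), "empty mask")
  expect_error(discretizeImage(img, fullMask(2), 0), "bin_width")
})

test_that("cohort-global bin width is the largest keeping every image multi-bin", {
  imgs <- list(a = matrix(c(0, 3, 1, 2), 2, 2),
               b = matrix(c(0, 8, 4, 2), 2, 2))
  msks <- list(fullMask(2), fullMask(2))
  expect_equal(selectBinWidth(imgs, msks, c(1, 2, 3, 4)), 2)
  expect_error(selectBinWidth(list(matrix(1, 2, 2)), list(fullMask(2)),
                              c(1, 2)), "multi-bin")
  expect_error(selectBinWidth(imgs, msks, c(-1, 2)), "positive")
  ## the reported per-modality widths are expressible as pinned widths
  pinned <- c(OCT = 2.78, TPEF = 1.25, MPM = 1.3, SHG = 1.28)
  expect_true(all(pinned > 0))
})

test_that("GLCM matches brute-force pair enumeration", {
  bins <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  d <- discretizeImage(matrix(c(1, 1, 2, 2), 2, 2), fullMask(2), 1)
  P <- glcmMatrix(d)
  expect_equal(P, oracleGLCM(d@bins, d@mask))
  expect_equal(sum(P), 1)
  expect_equal(P, t(P))
  ## constant 2x2 image: single bin carries all mass
  dcst <- discretizeImage(matrix(5, 2, 2), fullMask(2), 1)
  expect_equal(glcmMatrix(dcst), matrix(1))
  ## random masked images against the oracle
  set.seed(11)
  for (rep in 1:10) {
    img <- matrix(sample(1:4, 36, TRUE), 6, 6)
    msk <- matrix(runif(36) > 0.25, 6, 6)
    if (!any(msk)) next
    d <- discretizeImage(img, msk, 1)
    expect_equal(glcmMatrix(d), oracleGLCM(d@bins, d@mask))
  }
})

test_that("isolated masked pixels yield a flagged undefined GLCM", {
  msk <- matrix(FALSE, 5, 5); msk[1, 1] <- TRUE; msk[5, 5] <- TRUE
  d <- discretizeImage(matrix(runif(25), 5, 5), msk, 0.1)
  expect_warning(P <- glcmMatrix(d), "undefined")
  expect_true(all(is.na(P)))
  expect_true(all(is.na(glcmFeatures(P))))
})

test_that("GLCM features hit their closed-form anchor cases", {
  f1 <- glcmFeatures(matrix(1))
  expect_equal(unname(f1["joint_entropy"]), 0)
  expect_equal(unname(f1["joint_energy"]), 1)
  f2 <- glcmFeatures(matrix(0.25, 2, 2))
  expect_equal(unname(f2["joint_entropy"]), 2)
  set.seed(12)
  M <- matrix(runif(9), 3, 3); M <- (M + t(M)); M <- M / sum(M)
  expect_lte(glcmFeatures(M)[["joint_entropy"]], 2 * log2(3))
})

test_that("pooled GLCM features are invariant to 90-degree rotation", {
  set.seed(13)
  img <- matrix(sample(1:3, 49, TRUE), 7, 7)
  d1 <- discretizeImage(img, fullMask(7), 1)
  rot <- t(img[nrow(img):1, ])
  d2 <- discretizeImage(rot, fullMask(7), 1)
  expect_equal(glcmFeatures(glcmMatrix(d1)), glcmFeatures(glcmMatrix(d2)),
               tolerance = 1e-12)
})

test_that("GLSZM matches the flood-fill oracle", {
  bins <- matrix(c(1, 2, 1, 1, 2, 1, 2, 2, 1), 3, 3, byrow = TRUE)
  d <- discretizeImage(bins, fullMask(3), 1)
  expect_equal(glszmMatrix(d), oracleGLSZM(d@bins, d@mask))
  ## constant image: one zone of size N^2
  dc <- discretizeImage(matrix(2, 4, 4), fullMask(4), 1)
  Z <- glszmMatrix(dc)
  expect_equal(dim(Z), c(1L, 16L))
  expect_equal(Z[1, 16], 1)
  ## zone-count conservation on random masked images
  set.seed(14)
  for (rep in 1:10) {
    img <- matrix(sample(1:3, 49, TRUE), 7, 7)
    msk <- matrix(runif(49) > 0.2, 7, 7)
    if (!any(msk)) next
    d <- discretizeImage(img, msk, 1)
    Z <- glszmMatrix(d)
    O <- oracleGLSZM(d@bins, d@mask)
    expect_equal(Z, O)
    expect_equal(sum(Z), sum(O))
  }
})

test_that("GLSZM features follow the non-uniformity formulas", {
  ## single zone
  Z1 <- matrix(1, 1, 1)
  f1 <- glszmFeatures(Z1, 1)
  expect_equal(unname(f1["zone_size_nonuniformity"]), 1)
  expect_equal(unname(f1["gray_level_nonuniformity"]), 1)
  ## two zones, same size, different levels
  Z2 <- matrix(0, 2, 3); Z2[1, 3] <- 1; Z2[2, 3] <- 1
  f2 <- glszmFeatures(Z2, 6)
  expect_equal(unname(f2["zone_size_nonuniformity"]), 2)
  expect_equal(unname(f2["gray_level_nonuniformity"]), 1)
  ## k zones all distinct in size and level
  Z3 <- diag(3)
  f3 <- glszmFeatures(Z3, 6)
  expect_equal(unname(f3["zone_size_nonuniformity"]), 1)
  expect_equal(unname(f3["gray_level_nonuniformity"]), 1)
  expect_error(glszmFeatures(matrix(0, 2, 2), 4), "zero zones")
})

test_that("first-order features match their closed forms", {
  img <- matrix(c(1, 2, 3, 4), 2, 2)
  d <- discretizeImage(img, fullMask(2), 1)
  f <- firstOrderFeatures(img, fullMask(2), d)
  expect_equal(unname(f["mean"]), 2.5)
  expect_equal(unname(f["range"]), 3)
  expect_lt(abs(f["skewness"]), 1e-12)
  cst <- matrix(3, 3, 3)
  dc <- discretizeImage(cst, fullMask(3), 1)
  fc <- firstOrderFeatures(cst, fullMask(3), dc)
  expect_equal(unname(fc[c("variance", "entropy", "range")]), c(0, 0, 0))
})

test_that("automatic masks recover the tissue support", {
  img <- matrix(0, 64, 64)
  yy <- row(img); xx <- col(img)
  disc <- (yy - 32)^2 + (xx - 32)^2 <= 20^2
  img[disc] <- 1
  m <- makeMask(img)
  expect_gt(sum(m & disc) / sum(m | disc), 0.9)
  expect_warning(m0 <- makeMask(matrix(0, 8, 8)), "constant")
  expect_true(all(m0))
  ## generated planes: mask covers >= 95% of the generator-truth tissue
  for (s in 1:6) {
    cl <- pituitaryClasses()[(s %% 6) + 1]
    pl <- generatePlane(tissueClassSpec(cl), seed = 100 + s)
    mm <- makeMask(modalityImage(pl, "TPEF"))
    expect_gt(sum(mm & tissueMask(pl)) / sum(tissueMask(pl)), 0.95)
  }
})

test_that("per-plane extraction yields a fixed-length named row", {
  bw <- c(OCT = 0.5, TPEF = 0.3, SHG = 0.1, MPM = 0.3)
  p1 <- generatePlane(tissueClassSpec("gland"), shape = c(64, 64),
                      seed = 21)
  p2 <- generatePlane(tissueClassSpec("lactotroph"), shape = c(64, 64),
                      seed = 22)
  r1 <- extractFeatures(p1, bw)
  r2 <- extractFeatures(p2, bw)
  expect_equal(names(r1), names(r2))
  expect_equal(length(r1), 4 * (17 + 21 + 16))
  expect_true(all(is.finite(r1)))
  ## all-true mask vs automatic mask: both finite, different values
  rAll <- extractFeatures(p1, bw, masks = stats::setNames(
    rep(list(matrix(TRUE, 64, 64)), 4), c("OCT", "TPEF", "SHG", "MPM")))
  expect_true(all(is.finite(rAll)))
  expect_false(isTRUE(all.equal(r1, rAll)))
})

test_that("redundancy reduction removes duplicates and keeps independent features", {
  set.seed(15)
  tab <- data.frame(a = rnorm(40))
  tab$b <- tab$a * 2 + 1e-9 * rnorm(40)   # duplicate of a
  tab$c <- rnorm(40)
  tab$d <- rnorm(40)
  red <- reduceRedundancy(tab, 0.85)
  expect_equal(sum(c("a", "b") %in% colnames(red)), 1)
  expect_true(all(c("c", "d") %in% colnames(red)))
  C <- abs(cor(as.matrix(red)))
  diag(C) <- 0
  expect_lt(max(C), 0.85)
  ## constant features are dropped first with a message
  tab$e <- 1
  expect_message(red2 <- reduceRedundancy(tab, 0.85), "constant")
  expect_false("e" %in% colnames(red2))
  expect_error(reduceRedundancy(tab[1:2, ]), ">= 3 samples")
})
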