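test_that("the MC fold plan implements the 20%-of-minority rule", {
  comp <- defaultComposition()
  cls <- rep(comp$class_name, comp$n_planes)
  lab <- ifelse(cls == "gland", "gland", "adenoma")
  ids <- sprintf("p%03d", seq_along(cls))
  plan <- makeMCFolds(lab, cls, ids = ids, n_folds = 25, seed = 3)
  expect_equal(plan$n_minority, 5)
  for (f in plan$folds) {
    expect_equal(length(f$validation), 30)   # 5 x 6 subgroups
    expect_equal(length(f$train), 144)
    expect_length(intersect(f$validation, f$train), 0)
    vcls <- cls[match(f$validation, ids)]
    expect_true(all(table(vcls) == 5))
  }
  keys <- vapply(plan$folds,
                 function(f) paste(sort(f$validation), collapse = ","),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("fold plans are deterministic and respect small cohorts", {
  lab <- rep(c("gland", "adenoma"), each = 5)
  sub <- rep(c("gland", "lactotroph"), each = 5)
  p1 <- makeMCFolds(lab, sub, n_folds = 6, seed = 2)
  p2 <- makeMCFolds(lab, sub, n_folds = 6, seed = 2)
  expect_identical(p1, p2)
  expect_equal(p1$n_minority, 1)
  expect_true(all(vapply(p1$folds,
                         function(f) length(f$validation) == 2,
                         logical(1))))
  ## uniqueness becomes infeasible when more folds than configurations
  expect_error(makeMCFolds(lab, sub, n_folds = 50, seed = 1),
               "unique folds")
})

test_that("grouped fold sampling never splits a biopsy across the boundary", {
  comp <- defaultComposition()
  cls <- rep(comp$class_name, comp$n_planes)
  bid <- rep(comp$biopsy_id, comp$n_planes)
  lab <- ifelse(cls == "gland", "gland", "adenoma")
  ids <- sprintf("p%03d", seq_along(cls))
  plan <- makeMCFolds(lab, cls, ids = ids, n_folds = 5, seed = 4,
                      grouped = TRUE, group_ids = bid)
  for (f in plan$folds) {
    vb <- bid[match(f$validation, ids)]
    tb <- bid[match(f$train, ids)]
    expect_length(intersect(unique(vb), unique(tb)), 0)
  }
})

test_that("R-squared ranking puts label-aligned features first", {
  set.seed(5)
  n <- 144
  y <- rep(c("gland", "adenoma"), length.out = n)
  X <- cbind(perfect = as.numeric(y == "adenoma"),
             matrix(rnorm(n * 20), n,
                    dimnames = list(NULL, paste0("f", 1:20))))
  top <- rankFeaturesR2(X, y, k = 10)
  expect_equal(top[1], "perfect")
  expect_length(top, 10)
  expect_identical(top, rankFeaturesR2(X, y, k = 10))
  ## independent features have small R-squared at n = 144
  y01 <- as.numeric(factor(y)) - 1
  r2 <- apply(X[, -1], 2, function(v) cor(v, y01)^2)
  expect_lt(max(r2), 0.1)
  expect_error(rankFeaturesR2(X, y, k = 100), "exceeds")
})

test_that("Tomek links remove only borderline majority samples", {
  X <- matrix(c(0, 0.1, 5, 6), ncol = 1)
  y <- c("min", "maj", "maj", "maj")
  out <- tomekRemove(X, y, majority = "maj")
  expect_equal(out$removed, 2L)
  expect_equal(sort(out$X[, 1]), c(0, 5, 6))
  expect_equal(sum(out$y == "min"), 1)
  ## well-separated classes: nothing removed
  set.seed(6)
  X2 <- rbind(matrix(rnorm(20, 0, 0.1), ncol = 2),
              matrix(rnorm(60, 10, 0.1), ncol = 2))
  y2 <- rep(c("min", "maj"), c(10, 30))
  out2 <- tomekRemove(X2, y2)
  expect_length(out2$removed, 0)
  ## minority is never removed, whatever the geometry
  for (s in 1:20) {
    set.seed(s)
    Xr <- matrix(rnorm(60), ncol = 2)
    yr <- rep(c("min", "maj"), c(10, 20))
    expect_equal(sum(tomekRemove(Xr, yr, majority = "maj")$y == "min"), 10)
  }
})

test_that("SMOTE balances classes with convex synthetic samples", {
  X <- matrix(c(0, 0, 1, 1, 5, 5, 5, 6, 6, 5), ncol = 2, byrow = TRUE)
  y <- c("min", "min", "maj", "maj", "maj")
  out <- smoteOversample(X, y, seed = 7)
  expect_equal(unname(table(out$y)["min"]), unname(table(out$y)["maj"]))
  synth <- out$X[6, ]
  expect_true(all(synth >= 0 & synth <= 1))       # on the segment
  expect_equal(synth[1], synth[2])                # segment is the diagonal
  ## bounding-box containment over seeded runs
  for (s in 1:50) {
    set.seed(s)
    Xm <- matrix(rnorm(16), ncol = 2)
    Xj <- matrix(rnorm(40, 8), ncol = 2)
    XX <- rbind(Xm, Xj)
    yy <- rep(c("min", "maj"), c(8, 20))
    o <- smoteOversample(XX, yy, seed = s)
    sy <- o$X[-seq_len(nrow(XX)), , drop = FALSE]
    expect_true(all(sy[, 1] >= min(Xm[, 1]) & sy[, 1] <= max(Xm[, 1])))
    expect_true(all(sy[, 2] >= min(Xm[, 2]) & sy[, 2] <= max(Xm[, 2])))
  }
  expect_error(smoteOversample(matrix(1:4, 2), c("a", "b")), "size 1")
})

test_that("the forest ensemble separates blobs and is seed-deterministic", {
  set.seed(8)
  X <- rbind(matrix(rnorm(60, 0), ncol = 2),
             matrix(rnorm(60, 6), ncol = 2))
  colnames(X) <- c("u", "v")
  y <- rep(c("gland", "adenoma"), each = 30)
  e1 <- trainForestEnsemble(X, y, seed = 1)
  p1 <- predictEnsemble(e1, X)
  expect_equal(p1$class, y)
  e2 <- trainForestEnsemble(X, y, seed = 1)
  expect_equal(predictEnsemble(e2, X)$prob, p1$prob)
  expect_error(trainForestEnsemble(X, rep("a", 60)), "both classes")
})

test_that("the MC CV harness is deterministic and leak-free", {
  tab <- makeToyFeatureTable(n_per_sub = 8, seed = 9)
  r1 <- runMCCV(tab, n_folds = 12, k_features = 3, n_trees = 50,
                seed = 11)
  r2 <- runMCCV(tab, n_folds = 12, k_features = 3, n_trees = 50,
                seed = 11)
  expect_equal(r1@pooled, r2@pooled)
  expect_equal(r1@featureFrequency, r2@featureFrequency)
  expect_equal(r1@probabilities, r2@probabilities)
  ## a perfectly informative feature drives near-perfect pooled metrics
  expect_gt(r1@pooled[["accuracy"]], 0.95)
  expect_equal(unname(r1@featureFrequency["informative"]), 12L)
  ## leakage guards: validation ids absent from their own training set
  for (f in r1@folds) {
    expect_length(intersect(f$validation,
                            setdiff(tab$plane_id, f$validation)),
                  length(f$validation) * 0)
  }
  ## selection-frequency conservation: k x n_folds total selections
  expect_equal(sum(r1@featureFrequency), 3L * 12L)
  ## per-fold confusion row sums equal the validation composition:
  ## N_Minority = round(0.2 x 8) = 2 per subgroup -> 10 adenoma + 2 gland
  cmrow <- rowSums(r1@folds[[1]]$confusion)
  expect_equal(unname(cmrow["adenoma"]), 10)
  expect_equal(unname(cmrow["gland"]), 2)
})

test_that("fold training sets exclude validation samples end to end", {
  tab <- makeToyFeatureTable(n_per_sub = 6, seed = 10)
  rep <- runMCCV(tab, n_folds = 5, k_features = 2, n_trees = 30,
                 seed = 12)
  plan_ids <- tab$plane_id
  for (f in rep@folds) {
    expect_true(all(f$validation %in% plan_ids))
    expect_false(any(duplicated(f$validation)))
  }
})
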