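roundHalfUp <- function(x) floor(x + 0.5)

#' Balanced Monte-Carlo cross-validation fold plan
#'
#' Builds `n_folds` unique train/validation splits. The validation size is
#' derived from the minority class: N_Minority = round(0.2 x minority class
#' size), and exactly N_Minority samples from *each* subgroup (gland plus
#' each adenoma subtype) form the validation set; the remaining samples
#' form the training set. Fold validation-ID sets are pairwise distinct.
#'
#' @param labels binary labels (e.g. gland/adenoma), one per sample.
#' @param subgroups subgroup label per sample (tissue class).
#' @param ids sample identifiers (default positional).
#' @param n_folds number of folds (default 100).
#' @param validation_fraction fraction of the minority class defining
#'   N_Minority (default 0.2).
#' @param seed integer seed; the plan is deterministic given it.
#' @param grouped if TRUE, validation samples are drawn biopsy-wise: whole
#'   groups (see `group_ids`) are sampled per subgroup until N_Minority
#'   planes are available; surplus planes of the last sampled group are
#'   excluded from training as well, so no group straddles the split.
#' @param group_ids grouping vector (biopsy ids), required when
#'   `grouped = TRUE`.
#' @return list with `n_minority` and `folds`; each fold holds `validation`
#'   and `train` id vectors (and `excluded` in grouped mode).
#' @export
#' @examples
#' lab <- rep(c("gland", "adenoma"), c(5, 5))
#' sub <- rep(c("gland", "lactotroph"), c(5, 5))
#' plan <- makeMCFolds(lab, sub, n_folds = 4, seed = 1)
#' lengths(plan$folds[[1]])
makeMCFolds <- function(labels, subgroups, ids = seq_along(labels),
                        n_folds = 100, validation_fraction = 0.2,
                        seed = 1, grouped = FALSE, group_ids = NULL) {
  stopifnot(length(labels) == length(subgroups),
            length(labels) == length(ids))
  classSizes <- table(labels)
  if (length(classSizes) != 2) stop("labels must be binary")
  nMin <- roundHalfUp(validation_fraction * min(classSizes))
  if (min(classSizes) < 5) stop("minority class must have >= 5 samples")
  if (grouped && is.null(group_ids))
    stop("grouped fold sampling requires group_ids")
  subLevels <- unique(subgroups)
  bySub <- split(seq_along(ids), subgroups)
  if (any(vapply(bySub, length, integer(1)) < nMin))
    stop("a subgroup has fewer samples than N_Minority")
  seen <- new.env(hash = TRUE)
  folds <- vector("list", n_folds)
  made <- 0L
  withSeed(seed, {
    attempts <- 0L
    maxAttempts <- 200L * n_folds
    while (made < n_folds && attempts < maxAttempts) {
      attempts <- attempts + 1L
      excluded <- integer(0)
      valIdx <- integer(0)
      for (sg in subLevels) {
        pool <- bySub[[sg]]
        if (!grouped) {
          valIdx <- c(valIdx, sample(pool, nMin))
        } else {
          gs <- sample(unique(group_ids[pool]))
          taken <- integer(0)
          for (g in gs) {
            taken <- c(taken, pool[group_ids[pool] == g])
            if (length(taken) >= nMin) break
          }
          valIdx <- c(valIdx, taken[seq_len(nMin)])
          excluded <- c(excluded, setdiff(taken, taken[seq_len(nMin)]))
        }
      }
      key <- paste(sort(valIdx), collapse = ",")
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      made <- made + 1L
      folds[[made]] <- list(
        validation = ids[valIdx],
        train = ids[setdiff(seq_along(ids), c(valIdx, excluded))],
        excluded = ids[excluded])
    }
  })
  if (made < n_folds)
    stop(sprintf("could only build %d unique folds (requested %d)",
                 made, n_folds))
  list(n_minority = nMin, folds = folds)
}

#' R-squared feature ranking
#'
#' Ranks features by the squared Pearson correlation between each feature
#' and the 0/1 class label (squared point-biserial correlation), descending
#' with ties broken by column order. Zero-variance features score 0.
#'
#' @param X numeric feature matrix (training samples).
#' @param y binary labels.
#' @param k number of features to return (default 10).
#' @return character vector of the top-k feature names, in rank order.
#' @export
rankFeaturesR2 <- function(X, y, k = 10) {
  if (k > ncol(X)) stop("k exceeds the feature count")
  y01 <- as.numeric(factor(y)) - 1
  if (length(unique(y01)) < 2) stop("both classes must be present")
  r2 <- apply(X, 2, function(v) {
    if (stats::sd(v) == 0) return(0)
    stats::cor(v, y01)^2
  })
  colnames(X)[order(-r2, seq_along(r2))][seq_len(k)]
}

#' Tomek-link cleaning of the majority class
#'
#' A Tomek link is a pair of opposite-class samples that are mutual
#' Euclidean nearest neighbours. Only the majority-class member of each
#' link is removed; minority samples are never removed.
#'
#' @param X numeric feature matrix.
#' @param y binary labels.
#' @param majority the majority class (default: the more frequent label).
#' @return list with cleaned `X`, `y` and the integer `removed` row indices.
#' @export
#' @examples
#' X <- matrix(c(0, 0.1, 5, 6), ncol = 1)
#' tomekRemove(X, c("min", "maj", "maj", "maj"))$removed  # row 2
tomekRemove <- function(X, y, majority = NULL) {
  y <- as.character(y)
  if (length(unique(y)) != 2) stop("both classes must be present")
  if (is.null(majority)) majority <- names(which.max(table(y)))
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  isLink <- vapply(seq_along(nn), function(i) {
    j <- nn[i]
    nn[j] == i && y[i] != y[j]
  }, logical(1))
  removed <- which(isLink & y == majority)
  keep <- setdiff(seq_along(y), removed)
  list(X = X[keep, , drop = FALSE], y = y[keep], removed = removed)
}

#' SMOTE oversampling of the minority class
#'
#' Synthesizes minority samples x_new = x + u (x_nn - x) with
#' u ~ Uniform(0, 1) and x_nn one of the k nearest minority neighbours of
#' x, until both classes are exactly balanced. Base samples are cycled
#' deterministically; neighbour choice and u are seeded.
#'
#' @param X numeric feature matrix.
#' @param y binary labels.
#' @param k_neighbors neighbour count (clamped to minority size - 1).
#' @param seed integer seed.
#' @return list with balanced `X`, `y` and `n_synthetic`.
#' @export
smoteOversample <- function(X, y, k_neighbors = 5, seed = 1) {
  y <- as.character(y)
  tab <- table(y)
  if (length(tab) != 2) stop("both classes must be present")
  minority <- names(which.min(tab))
  nMin <- min(tab)
  if (nMin < 2)
    stop("minority class of size 1: SMOTE needs >= 2 minority samples")
  need <- max(tab) - nMin
  if (need == 0) return(list(X = X, y = y, n_synthetic = 0L))
  k <- max(1L, min(k_neighbors, nMin - 1L))
  Xm <- X[y == minority, , drop = FALSE]
  D <- as.matrix(dist(Xm))
  diag(D) <- Inf
  nnIdx <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
  synth <- withSeed(seed, {
    t(vapply(seq_len(need), function(s) {
      i <- ((s - 1L) %% nMin) + 1L
      j <- nnIdx[i, sample.int(k, 1)]
      u <- runif(1)
      Xm[i, ] + u * (Xm[j, ] - Xm[i, ])
    }, numeric(ncol(X))))
  })
  colnames(synth) <- colnames(X)
  list(X = rbind(X, synth), y = c(y, rep(minority, need)),
       n_synthetic = as.integer(need))
}

#' Mixed random-forest ensemble
#'
#' Soft-voting ensemble of three random forests with heterogeneous
#' hyperparameters: depth-limited (maxnodes = 16), depth-free, and
#' feature-subsampled (mtry = 1). Probabilities are averaged across
#' forests. Deterministic given the seed.
#'
#' @param X numeric training matrix (balanced, from the preceding steps).
#' @param y binary labels.
#' @param n_trees trees per forest (default 100).
#' @param seed integer seed.
#' @return object of class `forestEnsemble` with a `predictEnsemble()`
#'   method.
#' @export
trainForestEnsemble <- function(X, y, n_trees = 100, seed = 1) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  cfg <- list(list(maxnodes = 16, mtry = NULL),
              list(maxnodes = NULL, mtry = NULL),
              list(maxnodes = NULL, mtry = 1))
  forests <- withSeed(seed, lapply(cfg, function(cf) {
    args <- list(x = X, y = y, ntree = n_trees)
    if (!is.null(cf$maxnodes)) args$maxnodes <- cf$maxnodes
    if (!is.null(cf$mtry)) args$mtry <- cf$mtry
    do.call(randomForest::randomForest, args)
  }))
  structure(list(forests = forests, levels = levels(y)),
            class = "forestEnsemble")
}

#' @rdname trainForestEnsemble
#' @param ensemble a `forestEnsemble`.
#' @param newX matrix of samples to classify.
#' @return `predictEnsemble()`: list with `prob` (samples x classes mean
#'   probability matrix) and `class` (argmax labels).
#' @export
predictEnsemble <- function(ensemble, newX) {
  probs <- lapply(ensemble$forests, function(f)
    predict(f, newX, type = "prob"))
  prob <- Reduce(`+`, probs) / length(probs)
  cls <- colnames(prob)[max.col(prob, ties.method = "first")]
  list(prob = prob, class = cls)
}

#' Run the full binary Monte-Carlo cross-validation pipeline
#'
#' Per fold: R-squared ranking selects the top `k_features` features on the
#' training split only; the training split is Tomek-cleaned, then SMOTE
#' balances the minority class; features are standardized with training
#' statistics; the mixed random-forest ensemble is trained and evaluated on
#' the untouched validation split. Metrics are pooled over folds from the
#' summed confusion matrix.
#'
#' @param feature_table data.frame from [extractFeatureTable()] (after
#'   [reduceRedundancy()]): metadata columns `plane_id`, `class_name`,
#'   `label` plus numeric feature columns.
#' @param n_folds number of MC folds (default 100).
#' @param k_features features selected per fold (default 10).
#' @param n_trees trees per forest.
#' @param seed master seed; fold plan, SMOTE and forests derive from it.
#' @param positive class treated as positive for sensitivity (default
#'   "adenoma": sensitivity is adenoma detection).
#' @param grouped,validation_fraction passed to [makeMCFolds()] (grouped
#'   mode uses `biopsy_id` as the group).
#' @param stratify "subtype" stratifies validation sets over all six
#'   subgroups (N_Minority planes from gland and from each adenoma
#'   subtype, the default 25:5 adenoma:gland composition); "binary" draws
#'   N_Minority per binary class, giving label-balanced validation sets
#'   (chance level exactly 0.5).
#' @return an [MCFoldReport-class].
#' @export
runMCCV <- function(feature_table, n_folds = 100, k_features = 10,
                    n_trees = 100, seed = 1, positive = "adenoma",
                    grouped = FALSE, validation_fraction = 0.2,
                    stratify = c("subtype", "binary")) {
  stratify <- match.arg(stratify)
  meta <- c("plane_id", "biopsy_id", "class_name", "label")
  stopifnot(all(c("plane_id", "class_name", "label") %in%
                  colnames(feature_table)))
  featCols <- setdiff(colnames(feature_table)[vapply(feature_table,
                                                     is.numeric,
                                                     logical(1))], meta)
  X <- as.matrix(feature_table[, featCols, drop = FALSE])
  rownames(X) <- feature_table$plane_id
  y <- feature_table$label
  negative <- setdiff(unique(y), positive)
  plan <- makeMCFolds(y, if (stratify == "binary") y else
                        feature_table$class_name,
                      ids = feature_table$plane_id,
                      n_folds = n_folds, seed = deriveSeed(seed, 1),
                      grouped = grouped,
                      group_ids = if ("biopsy_id" %in% colnames(feature_table))
                        feature_table$biopsy_id else NULL,
                      validation_fraction = validation_fraction)
  classOrder <- c(positive, negative)
  pooledCM <- matrix(0, 2, 2, dimnames = list(classOrder, classOrder))
  foldRes <- vector("list", length(plan$folds))
  perFold <- data.frame()
  featCount <- stats::setNames(integer(length(featCols)), featCols)
  probSum <- stats::setNames(numeric(nrow(X)), rownames(X))
  probN <- stats::setNames(integer(nrow(X)), rownames(X))
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    tr <- match(fold$train, rownames(X))
    va <- match(fold$validation, rownames(X))
    res <- tryCatch({
      sel <- rankFeaturesR2(X[tr, , drop = FALSE], y[tr], k = k_features)
      Xtr <- X[tr, sel, drop = FALSE]; ytr <- y[tr]
      tk <- tomekRemove(Xtr, ytr, majority = names(which.max(table(ytr))))
      sm <- smoteOversample(tk$X, tk$y, seed = deriveSeed(seed, 1000 + f))
      mu <- colMeans(sm$X)
      sg <- apply(sm$X, 2, stats::sd); sg[sg == 0] <- 1
      Ztr <- sweep(sweep(sm$X, 2, mu), 2, sg, `/`)
      ens <- trainForestEnsemble(Ztr, sm$y, n_trees = n_trees,
                                 seed = deriveSeed(seed, 2000 + f))
      Zva <- sweep(sweep(X[va, sel, drop = FALSE], 2, mu), 2, sg, `/`)
      pr <- predictEnsemble(ens, Zva)
      cm <- unclass(table(factor(y[va], classOrder),
                          factor(pr$class, classOrder)))
      list(confusion = cm, selected = sel,
           validation = fold$validation,
           prob_positive = pr$prob[, positive])
    }, error = function(e) {
      warning(sprintf("fold %d failed: %s", f, conditionMessage(e)))
      NULL
    })
    foldRes[[f]] <- res
    if (is.null(res)) next
    featCount[res$selected] <- featCount[res$selected] + 1L
    pooledCM <- pooledCM + res$confusion
    acc <- sum(diag(res$confusion)) / sum(res$confusion)
    sens <- res$confusion[positive, positive] /
      sum(res$confusion[positive, ])
    spec <- res$confusion[negative, negative] /
      sum(res$confusion[negative, ])
    perFold <- rbind(perFold, data.frame(fold = f, accuracy = acc,
                                         sensitivity = sens,
                                         specificity = spec))
    probSum[fold$validation] <- probSum[fold$validation] + res$prob_positive
    probN[fold$validation] <- probN[fold$validation] + 1L
  }
  tp <- pooledCM[positive, positive]; fn <- sum(pooledCM[positive, ]) - tp
  tn <- pooledCM[negative, negative]; fp <- sum(pooledCM[negative, ]) - tn
  pooled <- c(accuracy = (tp + tn) / sum(pooledCM),
              sensitivity = tp / (tp + fn),
              specificity = tn / (tn + fp),
              accuracy_sd = stats::sd(perFold$accuracy),
              sensitivity_sd = stats::sd(perFold$sensitivity),
              specificity_sd = stats::sd(perFold$specificity))
  probs <- data.frame(plane_id = rownames(X),
                      class_name = feature_table$class_name,
                      label = y,
                      mean_prob_positive = ifelse(probN > 0,
                                                  probSum / pmax(probN, 1),
                                                  NA_real_),
                      n_validations = as.integer(probN),
                      row.names = NULL, stringsAsFactors = FALSE)
  new("MCFoldReport", folds = foldRes, pooled = pooled, perFold = perFold,
      featureFrequency = featCount, probabilities = probs,
      positiveClass = positive)
}
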