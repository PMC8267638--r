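#' Fit a principal-component model to spectra
#'
#' Centers the spectra and retains the smallest number of components whose
#' cumulative explained variance reaches `variance_target`, capped at
#' `max_components`.
#'
#' @param X spectra matrix (rows = spectra).
#' @param variance_target cumulative explained-variance target in (0, 1].
#' @param max_components cap on retained components.
#' @return a [SpectralPCA-class].
#' @export
#' @examples
#' X <- matrix(rnorm(200), 20, 10)
#' fitSpectralPCA(X, 0.9)
fitSpectralPCA <- function(X, variance_target = 0.95, max_components = 20) {
  if (nrow(X) < 2) stop("need at least 2 spectra")
  if (variance_target <= 0 || variance_target > 1)
    stop("variance_target must be in (0, 1]")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  n <- nrow(Xc); p <- ncol(Xc)
  if (p <= n) {
    ee <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
    vals <- pmax(ee$values, 0)
    vecs <- ee$vectors
  } else {
    ee <- eigen(tcrossprod(Xc) / (n - 1), symmetric = TRUE)
    vals <- pmax(ee$values, 0)
    keep <- vals > max(vals) * 1e-12
    vecs <- crossprod(Xc, ee$vectors[, keep, drop = FALSE])
    vecs <- sweep(vecs, 2, sqrt(colSums(vecs^2)), `/`)
    vals <- vals[keep]
  }
  frac <- vals / sum(vals)
  m <- min(which(cumsum(frac) >= variance_target - 1e-12))
  m <- min(m, max_components, length(vals))
  new("SpectralPCA", center = ctr,
      loadings = vecs[, seq_len(m), drop = FALSE],
      varianceExplained = frac[seq_len(m)], nComponents = as.integer(m))
}

#' Project spectra onto a fitted principal-component model
#'
#' @param model a [SpectralPCA-class].
#' @param X spectra matrix with the same wavenumber axis the model was
#'   fitted on.
#' @return scores matrix (rows = spectra, cols = components).
#' @export
projectSpectra <- function(model, X) {
  sweep(X, 2, model@center) %*% model@loadings
}

#' Train a multi-class SVM on PCA scores
#'
#' One-vs-one support-vector machine (linear kernel by default; PCA scores
#' are low-dimensional). Deterministic given the data and configuration.
#'
#' @param scores numeric matrix of PCA scores.
#' @param labels class labels, one per row; at least two classes.
#' @param kernel "linear" or "radial".
#' @param cost soft-margin cost.
#' @return a fitted `svm` model from e1071.
#' @export
trainSpectraSVM <- function(scores, labels, kernel = c("linear", "radial"),
                            cost = 10) {
  kernel <- match.arg(kernel)
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("need at least 2 classes")
  if (nrow(scores) != length(labels))
    stop("one score row per label required")
  e1071::svm(x = scores, y = labels, kernel = kernel, cost = cost,
             scale = FALSE)
}

#' One-vs-rest metrics from a pooled confusion matrix
#'
#' For each class c: sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' accuracy = (TP+TN)/total, all computed one-vs-rest from the confusion
#' matrix (rows = truth, columns = predicted).
#'
#' @param confusion square numeric matrix with identical row/column names.
#' @return a [MulticlassReport-class].
#' @export
#' @examples
#' cm <- matrix(c(8, 0, 1, 1, 9, 0, 1, 1, 9), 3, 3,
#'              dimnames = list(letters[1:3], letters[1:3]))
#' multiclassMetrics(cm)
multiclassMetrics <- function(confusion) {
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square")
  if (any(confusion < 0)) stop("confusion entries must be >= 0")
  total <- sum(confusion)
  met <- t(vapply(seq_len(nrow(confusion)), function(i) {
    tp <- confusion[i, i]
    fn <- sum(confusion[i, ]) - tp
    fp <- sum(confusion[, i]) - tp
    tn <- total - tp - fn - fp
    c(accuracy = (tp + tn) / total,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }, numeric(3)))
  metrics <- data.frame(class = rownames(confusion), met,
                        row.names = NULL, stringsAsFactors = FALSE)
  new("MulticlassReport", confusion = confusion, metrics = metrics)
}

#' Evaluate a classifier on held-out scores
#'
#' @param classifier a model with a `predict` method returning class labels.
#' @param test_scores score matrix of the held-out set.
#' @param test_labels true labels.
#' @param classes full class set defining the confusion-matrix order
#'   (defaults to the classifier's levels).
#' @return a [MulticlassReport-class].
#' @export
evaluateMulticlass <- function(classifier, test_scores, test_labels,
                               classes = NULL) {
  if (nrow(test_scores) == 0) stop("empty test set")
  pred <- predict(classifier, test_scores)
  if (is.null(classes)) classes <- levels(factor(pred))
  if (!all(test_labels %in% classes))
    stop("test label outside the class set")
  cm <- table(factor(test_labels, classes), factor(pred, classes))
  multiclassMetrics(unclass(cm))
}

#' Stratified cross-validated PCA-SVM subtype classification
#'
#' Splits spectra into stratified folds; per fold, fits the PCA on the
#' training spectra only, trains the SVM on the training scores and
#' predicts the held-out fold. Confusion counts are pooled over folds.
#'
#' @param X preprocessed spectra matrix.
#' @param labels class label per spectrum.
#' @param n_folds number of folds (default 5).
#' @param variance_target,max_components passed to [fitSpectralPCA()].
#' @param kernel,cost passed to [trainSpectraSVM()].
#' @param seed integer seed for the fold assignment.
#' @param groups optional grouping factor (e.g. biopsy); when given, whole
#'   groups are assigned to folds so spectra from one group never straddle
#'   the train/test boundary.
#' @return a [MulticlassReport-class].
#' @export
ramanSubtypeCV <- function(X, labels, n_folds = 5, variance_target = 0.95,
                           max_components = 20,
                           kernel = "linear", cost = 10, seed = 1,
                           groups = NULL) {
  labels <- factor(labels)
  classes <- levels(labels)
  fold <- integer(length(labels))
  withSeed(seed, {
    if (is.null(groups)) {
      for (cl in classes) {
        idx <- which(labels == cl)
        fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
    } else {
      groups <- as.character(groups)
      for (cl in classes) {
        g <- unique(groups[labels == cl])
        gf <- stats::setNames(sample(rep_len(seq_len(n_folds), length(g))), g)
        idx <- which(labels == cl)
        fold[idx] <- gf[groups[idx]]
      }
    }
  })
  cm <- matrix(0, length(classes), length(classes),
               dimnames = list(classes, classes))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    pca <- fitSpectralPCA(X[tr, , drop = FALSE], variance_target,
                          max_components)
    svmfit <- trainSpectraSVM(projectSpectra(pca, X[tr, , drop = FALSE]),
                              labels[tr], kernel = kernel, cost = cost)
    pred <- predict(svmfit, projectSpectra(pca, X[!tr, , drop = FALSE]))
    cm <- cm + unclass(table(factor(labels[!tr], classes),
                             factor(pred, classes)))
  }
  multiclassMetrics(cm)
}

#' Band-intensity ratio of a preprocessed spectrum
#'
#' Ratio of mean intensities over +/- `halfwidth` windows at the numerator
#' and denominator band centers. Scale-invariant. A non-positive
#' denominator-band intensity is flagged invalid (NA with a warning).
#'
#' @param spectrum preprocessed spectrum.
#' @param axis wavenumber axis.
#' @param numerator_center,denominator_center band centers in cm^-1.
#' @param halfwidth window half-width in cm^-1.
#' @return positive ratio, or NA if invalid.
#' @export
#' @examples
#' ax <- seq(600, 3100, 1)
#' s <- exp(-(ax - 1445)^2 / 128) * 0.8 + exp(-(ax - 720)^2 / 128) * 0.2
#' bandRatio(s, ax, 1445, 720)  # ~4
bandRatio <- function(spectrum, axis, numerator_center,
                      denominator_center, halfwidth = 5) {
  wn <- abs(axis - numerator_center) <= halfwidth
  wd <- abs(axis - denominator_center) <= halfwidth
  if (!any(wn) || !any(wd)) stop("band center outside the axis")
  den <- mean(spectrum[wd])
  if (den <= 0) {
    warning("non-positive denominator band intensity; ratio flagged NA")
    return(NA_real_)
  }
  mean(spectrum[wn]) / den
}

#' Per-spectrum diagnostic ratio table
#'
#' Computes the three diagnostic band ratios for every spectrum of the
#' given preprocessed maps: R1 = I(1660)/I(1335) (proteins/collagen),
#' R2 = I(1445)/I(1520) (lipids/carotenoids), R3 = I(1445)/I(720)
#' (lipids/DNA).
#'
#' @param maps list of preprocessed [RamanMap-class] objects.
#' @param halfwidth window half-width in cm^-1.
#' @return data.frame with columns `map_id`, `class_name`, `R1`, `R2`, `R3`.
#' @export
ratioTable <- function(maps, halfwidth = 5) {
  rows <- lapply(maps, function(m) {
    ax <- m@wavenumbers
    win <- function(ctr) rowMeans(m@spectra[, abs(ax - ctr) <= halfwidth,
                                            drop = FALSE])
    data.frame(map_id = m@mapId, class_name = m@className,
               R1 = win(1660) / win(1335),
               R2 = win(1445) / win(1520),
               R3 = win(1445) / win(720),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' One-way ANOVA per ratio
#'
#' F-test of group differences for each ratio column. Fully degenerate
#' input (zero within-group variance everywhere and equal group means) is
#' handled by the p = 1 convention with a message.
#'
#' @param ratio_values data.frame or matrix of ratio columns.
#' @param group_labels group label per row; >= 2 groups with >= 2 samples
#'   each.
#' @return named numeric vector of p-values, one per ratio column.
#' @export
#' @examples
#' anovaRatios(data.frame(R = c(1, 2, 5, 6)), c("a", "a", "b", "b"))
anovaRatios <- function(ratio_values, group_labels) {
  g <- factor(group_labels)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(table(g) < 2)) stop("need >= 2 samples per group")
  ratio_values <- as.data.frame(ratio_values)
  vapply(ratio_values, function(v) {
    ok <- is.finite(v)
    vv <- v[ok]; gg <- droplevels(g[ok])
    gm <- tapply(vv, gg, mean)
    ssw <- sum(tapply(vv, gg, function(x) sum((x - mean(x))^2)))
    if (ssw == 0 && max(gm) - min(gm) == 0) {
      message("anovaRatios: fully degenerate groups; p = 1 convention")
      return(1)
    }
    fit <- stats::aov(vv ~ gg)
    summary(fit)[[1]][["Pr(>F)"]][1]
  }, numeric(1))
}
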