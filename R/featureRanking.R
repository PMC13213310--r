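#' Random-forest configuration for discriminant-wavenumber ranking
#'
#' @param nTrees number of trees (default 100).
#' @param splitCriterion split criterion; only `"gini"` is supported (the
#'   CART default used throughout).
#' @param nFolds stratified cross-validation folds (default 10).
#' @param seed random seed fixed for reproducibility (default 42).
#' @param classBalancing `"balanced_subsample"` (class-balanced bootstrap per
#'   tree, the default) or `"none"`.
#' @param topK number of top-ranked wavenumbers selected downstream
#'   (default 15).
#' @return a validated list of class `RFConfig`.
#' @export
rfConfig <- function(nTrees = 100L, splitCriterion = "gini", nFolds = 10L,
                     seed = 42L, classBalancing = c("balanced_subsample",
                                                    "none"),
                     topK = 15L) {
  splitCriterion <- match.arg(splitCriterion, "gini")
  classBalancing <- match.arg(classBalancing)
  if (nFolds < 2) stop("nFolds must be >= 2")
  if (topK < 1) stop("topK must be >= 1")
  structure(list(nTrees = as.integer(nTrees), splitCriterion = splitCriterion,
                 nFolds = as.integer(nFolds), seed = as.integer(seed),
                 classBalancing = classBalancing, topK = as.integer(topK)),
            class = "RFConfig")
}

.asFeatureMatrix <- function(x, labels) {
  if (is(x, "RamanSpectra")) {
    X <- t(intensityMatrix(x))
    colnames(X) <- paste0("wn", seq_len(ncol(X)))
    if (is.character(labels) && length(labels) == 1) {
      meta <- spectrumMeta(x)
      if (!labels %in% colnames(meta))
        stop("unknown metadata field: ", labels)
      labels <- meta[[labels]]
    }
    list(X = X, y = factor(labels), wavenumber = wavenumbers(x))
  } else {
    X <- as.matrix(x)
    colnames(X) <- paste0("wn", seq_len(ncol(X)))
    list(X = X, y = factor(labels), wavenumber = NULL)
  }
}

.fitForest <- function(X, y, config) {
  if (config$classBalancing == "balanced_subsample") {
    nmin <- min(table(y))
    randomForest::randomForest(X, y, ntree = config$nTrees,
                               strata = y,
                               sampsize = rep(nmin, nlevels(y)),
                               replace = TRUE)
  } else {
    randomForest::randomForest(X, y, ntree = config$nTrees)
  }
}

.stratifiedFolds <- function(y, nFolds) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
  }
  fold
}

#' Train a random forest with stratified cross-validation
#'
#' Trains an ensemble of `nTrees` CART trees (Gini impurity splitting) to
#' separate the label classes; class imbalance is addressed by a
#' class-balanced bootstrap per tree. Stratified `nFolds`-fold
#' cross-validation reports held-out accuracy per fold (a guard against
#' overfitting, not a selection gate), after which the ensemble is refit on
#' all data under the fixed seed.
#'
#' @param x a [RamanSpectra-class] (features = channels) or a numeric matrix
#'   (rows = observations).
#' @param labels class labels: a metadata column name (for `RamanSpectra`
#'   input; default `"tissue_class"`) or a vector.
#' @param config an [rfConfig()].
#' @param cv run the cross-validation loop (set `FALSE` to fit the ranking
#'   ensemble only).
#' @return list of class `RFTrainResult`: `forest` (the refit ensemble),
#'   `cv` (`data.frame` fold/accuracy, `NULL` when `cv = FALSE`),
#'   `cvAccuracyMean`, `cvAccuracySd`, `wavenumber`, `config`.
#' @export
trainRFCV <- function(x, labels = "tissue_class", config = rfConfig(),
                      cv = TRUE) {
  fm <- .asFeatureMatrix(x, labels)
  y <- droplevels(fm$y)
  if (nlevels(y) < 2) stop("label error: need at least 2 classes")
  if (cv && min(table(y)) < config$nFolds)
    stop("stratification error: smallest class (", min(table(y)),
         ") has fewer members than nFolds (", config$nFolds, ")")
  cvtab <- NULL
  if (cv) {
    set.seed(config$seed)
    fold <- .stratifiedFolds(y, config$nFolds)
    acc <- vapply(seq_len(config$nFolds), function(f) {
      tr <- fold != f
      forest <- .fitForest(fm$X[tr, , drop = FALSE], y[tr], config)
      pred <- stats::predict(forest, fm$X[!tr, , drop = FALSE])
      mean(pred == y[!tr])
    }, numeric(1))
    cvtab <- data.frame(fold = seq_len(config$nFolds), accuracy = acc)
  }
  set.seed(config$seed)
  forest <- .fitForest(fm$X, y, config)
  structure(list(forest = forest, cv = cvtab,
                 cvAccuracyMean = if (cv) mean(cvtab$accuracy) else NA_real_,
                 cvAccuracySd = if (cv) stats::sd(cvtab$accuracy) else NA_real_,
                 wavenumber = fm$wavenumber, config = config),
            class = "RFTrainResult")
}

#' Rank wavenumbers by random-forest importance
#'
#' Maps the ensemble's mean decrease in Gini impurity per channel to
#' wavenumbers, normalizes the scores to sum 1 and sorts them in decreasing
#' importance (ties broken by ascending wavenumber).
#'
#' @param fit an `RFTrainResult` from [trainRFCV()].
#' @param wavenumber wavenumber axis matching the feature columns (taken from
#'   the training object when it was a `RamanSpectra`).
#' @return a [FeatureRanking-class].
#' @export
rankWavenumbers <- function(fit, wavenumber = NULL) {
  imp <- randomForest::importance(fit$forest)[, "MeanDecreaseGini"]
  if (is.null(wavenumber)) wavenumber <- fit$wavenumber
  if (is.null(wavenumber))
    stop("wavenumber axis required (matrix-trained ensemble)")
  if (length(wavenumber) != length(imp))
    stop("wavenumber axis length does not match feature count")
  tot <- sum(imp)
  if (tot <= 0) stop("all importances are zero; ranking undefined")
  imp <- unname(imp / tot)
  ord <- order(-imp, wavenumber)
  new("FeatureRanking", wavenumbers = wavenumber[ord],
      importances = imp[ord],
      cvAccuracyMean = fit$cvAccuracyMean,
      cvAccuracySd = fit$cvAccuracySd)
}

setMethod("show", "FeatureRanking", function(object) {
  n <- length(object@wavenumbers)
  cat("FeatureRanking over", n, "wavenumbers\n")
  top <- utils::head(seq_len(n), 5)
  cat("  top:", paste(sprintf("%.0f cm-1 (%.3f)", object@wavenumbers[top],
                              object@importances[top]), collapse = ", "), "\n")
  if (!is.na(object@cvAccuracyMean))
    cat(sprintf("  CV accuracy: %.3f +/- %.3f\n",
                object@cvAccuracyMean, object@cvAccuracySd))
})

#' Select the top-k discriminant wavenumbers
#'
#' @param ranking a [FeatureRanking-class].
#' @param k number of wavenumbers to keep (default 15).
#' @return numeric vector of `k` wavenumbers sorted by decreasing importance
#'   (ties by ascending wavenumber).
#' @export
selectTopK <- function(ranking, k = 15L) {
  if (k <= 0) stop("parameter error: k must be positive")
  if (k > length(ranking@wavenumbers))
    stop("parameter error: k exceeds the number of ranked wavenumbers")
  ranking@wavenumbers[seq_len(k)]
}

#' Export a ranking as a data.frame
#'
#' @param x a [FeatureRanking-class].
#' @param ... ignored.
#' @return `data.frame` with columns `rank`, `wavenumber`, `importance`.
#' @export
as.data.frame.FeatureRanking <- function(x, ...) {
  data.frame(rank = seq_along(x@wavenumbers),
             wavenumber = x@wavenumbers, importance = x@importances)
}
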