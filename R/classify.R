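#' @include AllGenerics.R
NULL

#' Stratified k-fold assignment
#'
#' Assigns every epoch to one of \code{k} folds so that each fold
#' approximately preserves the class proportions. The assignment depends
#' only on the label vector and the seed, never on the feature family, so
#' different families are compared on identical splits.
#'
#' @param labels class label per epoch.
#' @param k number of folds (default 5).
#' @param seed RNG seed (default 42).
#' @return integer fold index (1..k) per epoch.
#' @export
stratifiedFolds <- function(labels, k = 5L, seed = 42L) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < k))
    stop("every class needs at least ", k, " epochs for ", k,
         "-fold stratification (smallest class has ", min(counts), ")")
  rng <- .seededRNG(seed)
  fold <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    idx <- idx[rng$permute(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# small RNG sandbox: runs seeded draws without disturbing the caller's RNG
.seededRNG <- function(seed) {
  env <- new.env()
  run <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                       globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv()))
              rm(".Random.seed", envir = globalenv()))
    set.seed(env$state)
    out <- expr()
    env$state <- sample.int(.Machine$integer.max, 1L)
    out
  }
  env$state <- as.integer(seed)
  list(
    permute = function(n) run(function() sample.int(n)),
    seedFor = function(offset) (as.integer(seed) + offset) %% 2147483647L
  )
}

# macro-averaged F1 (%) from a confusion matrix (rows = truth, cols = pred)
.macroF1 <- function(conf) {
  classes <- rownames(conf)
  f1 <- vapply(classes, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  100 * mean(f1)
}

.fitPredict <- function(classifier, xtr, ytr, xte, seed) {
  ytr <- factor(ytr)
  switch(classifier,
    svm = {
      g <- 1 / (ncol(xtr) * max(stats::var(as.vector(xtr)), 1e-12))
      fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = 1, gamma = g,
                        scale = FALSE)
      as.character(stats::predict(fit, xte))
    },
    nb = {
      fit <- e1071::naiveBayes(xtr, ytr)
      as.character(stats::predict(fit, xte))
    },
    knn = {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      set.seed(seed)  # knn breaks ties at random
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      as.character(class::knn(xtr, xte, ytr, k = 5))
    },
    stop("unknown classifier '", classifier, "'"))
}

#' Train and evaluate one classifier under stratified cross-validation
#'
#' Stratified k-fold cross-validation with per-fold accuracy and
#' macro-averaged F1 (both in percent). Features are standardized (zero
#' mean, unit variance) using training-fold statistics only; features with
#' (near-)zero variance in the training fold — e.g. the structural zeros of
#' a flattened PLI diagonal — are excluded from the model in that fold.
#' Classifier settings: SVM with RBF kernel, cost 1, gamma = 1/(dim * var);
#' Gaussian naive Bayes; KNN with k = 5 and Euclidean distance.
#'
#' @param features a \linkS4class{FeatureSet}.
#' @param classifier one of "svm", "nb", "knn".
#' @param nFolds number of folds (default 5).
#' @param seed seed controlling fold assignment and tie-breaking
#'   (default 42).
#' @return list with classifier, family, accuracy/f1 means and SDs (%),
#'   per-fold data.frame, pooled confusion matrix, fold assignment and seed.
#' @export
trainEval <- function(features, classifier = c("svm", "nb", "knn"),
                      nFolds = 5L, seed = 42L) {
  stopifnot(is(features, "FeatureSet"))
  classifier <- match.arg(classifier)
  x <- features@matrix
  y <- features@labels
  fold <- stratifiedFolds(y, nFolds, seed)
  classes <- sort(unique(y))
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(classes, classes))
  perFold <- data.frame(fold = seq_len(nFolds), accuracy = NA_real_,
                        f1 = NA_real_)
  for (f in seq_len(nFolds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < length(classes))
      stop("a class is absent from training fold ", f,
           "; stratification violated")
    mu <- colMeans(x[tr, , drop = FALSE])
    sd_ <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
    keep <- which(sd_ > 1e-12)
    if (!length(keep)) stop("no informative features in training fold ", f)
    xs <- sweep(sweep(x[, keep, drop = FALSE], 2L, mu[keep], "-"),
                2L, sd_[keep], "/")
    pred <- .fitPredict(classifier, xs[tr, , drop = FALSE], y[tr],
                        xs[!tr, , drop = FALSE],
                        seed = (as.integer(seed) + f) %% 2147483647L)
    truth <- y[!tr]
    cf <- table(factor(truth, classes), factor(pred, classes))
    conf <- conf + cf
    perFold$accuracy[f] <- 100 * mean(pred == truth)
    perFold$f1[f] <- .macroF1(cf)
  }
  list(classifier = classifier, family = features@family,
       accuracy_mean = mean(perFold$accuracy),
       accuracy_sd = stats::sd(perFold$accuracy),
       f1_mean = mean(perFold$f1), f1_sd = stats::sd(perFold$f1),
       per_fold = perFold, confusion = conf, fold = fold,
       seed = as.integer(seed))
}

#' Compare feature families across classifiers
#'
#' Evaluates every (family, classifier) combination on identical stratified
#' splits (the fold assignment depends only on labels and seed) and returns
#' the comparison grid.
#'
#' @param featureSets named list of \linkS4class{FeatureSet}s built on the
#'   same epochs (identical label vectors required).
#' @param classifiers classifiers to run (default all three).
#' @param nFolds,seed passed to \code{\link{trainEval}}.
#' @return data.frame with one row per family x classifier: accuracy and
#'   F1 means and SDs in percent.
#' @export
compareFamilies <- function(featureSets, classifiers = c("svm", "nb", "knn"),
                            nFolds = 5L, seed = 42L) {
  stopifnot(is.list(featureSets), length(featureSets) >= 1L)
  labs <- lapply(featureSets, conditionLabels)
  if (!all(vapply(labs, identical, logical(1), labs[[1]])))
    stop("feature sets are built on mismatched epoch sets")
  rows <- list()
  for (fs in featureSets) for (clf in classifiers) {
    r <- trainEval(fs, clf, nFolds, seed)
    rows[[length(rows) + 1L]] <- data.frame(
      family = r$family, classifier = clf,
      accuracy_mean = r$accuracy_mean, accuracy_sd = r$accuracy_sd,
      f1_mean = r$f1_mean, f1_sd = r$f1_sd, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
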