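# Cell-type classification on the four recovered biophysical features
# (D, RI_C, RI_N, N/C), following the measurement pipeline's classifier
# configuration: standardized features, quadratic kernel, box constraint 1,
# one-vs-one multiclass voting.

CELL_CLASSES <- c("RBC", "T", "B", "M", "Macro", "CTC")
FEATURES <- c("diameter_um", "ri_cytosol", "ri_nucleus", "nc_ratio")

SUPPORTED_ALGORITHMS <- c("quadratic-svm", "linear-svm", "fine-gaussian-svm",
                          "medium-knn", "kernel-naive-bayes")

# Feature matrix with validation; RBC-style records without a nucleus index
# get RI_N imputed as RI_C (a homogeneous sphere has a single index).
feature_matrix <- function(records, require_label = FALSE) {
  miss <- setdiff(c(FEATURES[-3]), names(records))
  if (length(miss))
    stop("missing feature columns: ", paste(miss, collapse = ", "))
  if (!"ri_nucleus" %in% names(records))
    records$ri_nucleus <- NA_real_
  records$ri_nucleus <- ifelse(is.na(records$ri_nucleus),
                               records$ri_cytosol, records$ri_nucleus)
  bad <- !is.finite(records$diameter_um) | records$diameter_um <= 0 |
    !is.finite(records$ri_cytosol) | records$ri_cytosol < 1.30 |
    records$ri_cytosol > 1.60 |
    !is.finite(records$ri_nucleus) | records$ri_nucleus < 1.30 |
    records$ri_nucleus > 1.60 |
    !is.finite(records$nc_ratio) | records$nc_ratio <= 0 |
    records$nc_ratio > 1
  if (any(bad))
    stop("feature values out of range in record(s) ",
         paste(utils::head(which(bad), 10), collapse = ", "),
         if (sum(bad) > 10) " ..." else "")
  if (require_label) {
    if (!"label" %in% names(records) || anyNA(records$label))
      stop("all records must carry a class label")
    unknown <- setdiff(unique(as.character(records$label)), CELL_CLASSES)
    if (length(unknown))
      stop("unknown class label(s): ", paste(unknown, collapse = ", "),
           " (allowed: ", paste(CELL_CLASSES, collapse = ", "), ")")
  }
  as.matrix(records[, FEATURES])
}

kde_naive_bayes_fit <- function(xs, y) {
  classes <- levels(y)
  dens <- lapply(classes, function(cl) {
    xc <- xs[y == cl, , drop = FALSE]
    lapply(seq_len(ncol(xs)), function(j) {
      v <- xc[, j]
      bw <- tryCatch(stats::bw.nrd0(v), error = function(e) NA_real_)
      if (!is.finite(bw) || bw <= 0) bw <- max(stats::sd(v), 1e-3)
      density(v, bw = bw, n = 512, from = min(v) - 4 * bw,
              to = max(v) + 4 * bw)
    })
  })
  names(dens) <- classes
  priors <- table(y) / length(y)
  list(dens = dens, priors = priors, classes = classes)
}

kde_naive_bayes_predict <- function(fit, xs) {
  n <- nrow(xs)
  ll <- matrix(0, n, length(fit$classes),
               dimnames = list(NULL, fit$classes))
  floor_d <- 1e-9
  for (cl in fit$classes) {
    s <- rep(log(as.numeric(fit$priors[[cl]])), n)
    for (j in seq_len(ncol(xs))) {
      d <- fit$dens[[cl]][[j]]
      f <- approx(d$x, d$y, xout = xs[, j], yleft = 0, yright = 0)$y
      s <- s + log(pmax(f, floor_d))
    }
    ll[, cl] <- s
  }
  factor(fit$classes[max.col(ll, ties.method = "first")],
         levels = fit$classes)
}

#' Train a cell-type classifier on labelled biophysical features
#'
#' Features are z-score standardized with statistics from the training data
#' only.  The default algorithm is the quadratic-kernel SVM with box
#' constraint 1 and one-vs-one multiclass voting; the comparison set of the
#' original study (linear SVM, fine-Gaussian SVM, medium KNN with k = 10,
#' kernel naive Bayes) is also available.
#'
#' @param records Data frame with columns `diameter_um`, `ri_cytosol`,
#'   `ri_nucleus` (may be `NA` for anucleate cells; imputed as
#'   `ri_cytosol`), `nc_ratio` and `label`.
#' @param algorithm One of `"quadratic-svm"`, `"linear-svm"`,
#'   `"fine-gaussian-svm"`, `"medium-knn"`, `"kernel-naive-bayes"`.
#' @param seed Integer seed fixed before fitting.
#' @return An object of class `cell_classifier`.
#' @export
train_cell_classifier <- function(records, algorithm = "quadratic-svm",
                                  seed = 1L) {
  if (!algorithm %in% SUPPORTED_ALGORITHMS)
    stop("unknown algorithm '", algorithm, "'; options: ",
         paste(SUPPORTED_ALGORITHMS, collapse = ", "))
  xs <- feature_matrix(records, require_label = TRUE)
  y <- factor(as.character(records$label),
              levels = intersect(CELL_CLASSES, unique(records$label)))
  if (nlevels(y) < 2L)
    stop("training data must contain at least 2 classes")
  center <- colMeans(xs)
  scale_ <- apply(xs, 2, sd)
  scale_[scale_ == 0] <- 1
  xz <- scale(xs, center = center, scale = scale_)
  set.seed(seed)
  model <- switch(
    algorithm,
    "quadratic-svm" = e1071::svm(xz, y, kernel = "polynomial", degree = 2,
                                 gamma = 1, coef0 = 1, cost = 1,
                                 scale = FALSE),
    "linear-svm" = e1071::svm(xz, y, kernel = "linear", cost = 1,
                              scale = FALSE),
    # MATLAB's "fine" preset: kernel scale sqrt(P)/4 -> gamma = 8/P
    "fine-gaussian-svm" = e1071::svm(xz, y, kernel = "radial",
                                     gamma = 8 / ncol(xz), cost = 1,
                                     scale = FALSE),
    "medium-knn" = list(x = xz, y = y, k = 10L),
    "kernel-naive-bayes" = kde_naive_bayes_fit(xz, y))
  structure(list(algorithm = algorithm, model = model, center = center,
                 scale = scale_, classes = levels(y), seed = seed),
            class = "cell_classifier")
}

#' @export
print.cell_classifier <- function(x, ...) {
  cat("<cell_classifier>", x$algorithm, "on",
      paste(x$classes, collapse = "/"), "\n")
  invisible(x)
}

#' Predict cell types for a feature table
#'
#' Every record receives exactly one of the trained classes; there is no
#' rejection option.  Out-of-range features raise an error naming the
#' offending records.
#'
#' @param object A [train_cell_classifier()] fit.
#' @param newdata Data frame of feature records.
#' @param ... Unused.
#' @return `newdata` with a `label` column of predicted classes (factor).
#' @export
predict.cell_classifier <- function(object, newdata, ...) {
  if (nrow(newdata) == 0L) {
    newdata$label <- factor(character(), levels = object$classes)
    return(newdata)
  }
  xs <- feature_matrix(newdata)
  xz <- scale(xs, center = object$center, scale = object$scale)
  pred <- switch(
    object$algorithm,
    "medium-knn" = class::knn(object$model$x, xz, object$model$y,
                              k = object$model$k),
    "kernel-naive-bayes" = kde_naive_bayes_predict(object$model, xz),
    predict(object$model, xz))
  newdata$label <- factor(as.character(pred), levels = object$classes)
  newdata
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated accuracy comparison of classification algorithms
#'
#' Stratified k-fold cross-validation with identical fold assignment for
#' every algorithm, so accuracies are directly comparable.
#'
#' @param records Labelled feature records (see [train_cell_classifier()]).
#' @param algorithms Character vector of algorithm names.
#' @param cv_folds Number of folds (>= 2).
#' @param seed Seed controlling the fold assignment and any fit randomness.
#' @return Data frame with `algorithm`, `accuracy` (fraction correct over
#'   all held-out records) and `rank`, sorted by decreasing accuracy.
#' @export
compare_algorithms <- function(records, algorithms = SUPPORTED_ALGORITHMS,
                               cv_folds = 5L, seed = 1L) {
  stopifnot(cv_folds >= 2L)
  y <- factor(as.character(records$label),
              levels = intersect(CELL_CLASSES, unique(records$label)))
  fold <- stratified_folds(y, cv_folds, seed)
  acc <- vapply(algorithms, function(alg) {
    correct <- 0L
    for (f in seq_len(cv_folds)) {
      tr <- records[fold != f, , drop = FALSE]
      te <- records[fold == f, , drop = FALSE]
      clf <- train_cell_classifier(tr, algorithm = alg, seed = seed)
      pred <- predict(clf, te[setdiff(names(te), "label")])
      correct <- correct + sum(as.character(pred$label) ==
                                 as.character(te$label))
    }
    correct / nrow(records)
  }, numeric(1))
  out <- data.frame(algorithm = algorithms, accuracy = as.numeric(acc))
  out <- out[order(-out$accuracy, out$algorithm), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Cross-validated accuracy of one algorithm
#'
#' @inheritParams compare_algorithms
#' @param algorithm Algorithm name.
#' @return Fraction of held-out records classified correctly.
#' @export
cv_accuracy <- function(records, algorithm = "quadratic-svm", cv_folds = 5L,
                        seed = 1L) {
  compare_algorithms(records, algorithms = algorithm, cv_folds = cv_folds,
                     seed = seed)$accuracy[1]
}
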