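# the eight-classifier stress-grading bench

bench_algorithms <- function()
  c("GaussianNB", "PAC", "NC", "KNN", "RF", "SVC", "GBDT", "XGB")

# ---- one-vs-all SVM (binary e1071 machines, max decision value) ----

ova_svm_fit <- function(x, y, kernel, cost, gamma = NULL, degree = 3) {
  classes <- sort(unique(y))
  machines <- lapply(classes, function(k) {
    yy <- factor(ifelse(y == k, "pos", "neg"), levels = c("pos", "neg"))
    args <- list(x = x, y = yy, kernel = kernel, cost = cost,
                 degree = degree, scale = FALSE)
    if (!is.null(gamma) && kernel != "linear") args$gamma <- gamma
    do.call(e1071::svm, args)
  })
  structure(list(classes = classes, machines = machines, kernel = kernel,
                 cost = cost, gamma = gamma, degree = degree),
            class = "ova_svm")
}

#' @export
predict.ova_svm <- function(object, newdata, ...) {
  dv <- vapply(object$machines, function(m) {
    p <- stats::predict(m, newdata, decision.values = TRUE)
    v <- attr(p, "decision.values")
    # e1071 orients the value toward the class named first in the column
    # label (order of appearance in the training data), not the factor level
    if (identical(colnames(v), "neg/pos")) -as.numeric(v) else as.numeric(v)
  }, numeric(nrow(newdata)))
  dv <- matrix(dv, nrow = nrow(newdata))
  object$classes[max.col(dv, ties.method = "first")]
}

# stratified fold assignment, deterministic under seed
stratified_folds <- function(y, folds, seed = 1L) {
  with_local_seed(seed, {
    id <- integer(length(y))
    for (k in unique(y)) {
      rows <- sample(which(y == k))
      id[rows] <- rep_len(seq_len(folds), length(rows))
    }
    id
  })
}

#' Grid search for the one-vs-all SVM
#'
#' Exhaustive search over kernel x cost x kernel-scale combinations scored
#' by stratified cross-validated accuracy; ties resolve to the first
#' combination in grid order.  The four candidate kernels are linear,
#' radial-basis (Gaussian), polynomial and sigmoid.
#'
#' @param x Training feature matrix.
#' @param y Training labels (1..3).
#' @param kernels Kernel set to search.
#' @param costs Soft-margin cost grid.
#' @param gammas Kernel-scale grid (non-linear kernels).
#' @param degree Polynomial degree (fixed).
#' @param folds Number of stratified CV folds (>= 2).
#' @param seed Seed for fold assignment.
#' @return List: `model` (an `ova_svm` refitted on all of `x`), `kernel`,
#'   `cost`, `gamma`, `cv_accuracy`, and the full `grid` with scores.
#' @export
grid_search_svm <- function(x, y,
                            kernels = c("linear", "radial", "polynomial",
                                        "sigmoid"),
                            costs = c(0.1, 1, 10, 100),
                            gammas = c(0.05, 0.5),
                            degree = 3, folds = 5L, seed = 1L) {
  if (folds < 2L) stop("`folds` must be >= 2")
  x <- as.matrix(x)
  grid <- do.call(rbind, lapply(kernels, function(kn) {
    g <- if (kn == "linear") NA_real_ else gammas
    expand.grid(kernel = kn, cost = costs, gamma = g,
                stringsAsFactors = FALSE)
  }))
  fold_id <- stratified_folds(y, folds, seed)
  if (any(vapply(seq_len(folds), function(f)
    length(unique(y[fold_id != f])) < length(unique(y)), logical(1))))
    stop("a fold is missing a class; use fewer folds")
  grid$cv_accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    acc <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- ova_svm_fit(x[tr, , drop = FALSE], y[tr],
                         kernel = grid$kernel[i], cost = grid$cost[i],
                         gamma = if (is.na(grid$gamma[i])) NULL else grid$gamma[i],
                         degree = degree)
      mean(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    mean(acc)
  }, numeric(1))
  best <- which.max(grid$cv_accuracy)   # first maximum in grid order
  model <- ova_svm_fit(x, y, kernel = grid$kernel[best],
                       cost = grid$cost[best],
                       gamma = if (is.na(grid$gamma[best])) NULL else grid$gamma[best],
                       degree = degree)
  list(model = model, kernel = grid$kernel[best], cost = grid$cost[best],
       gamma = grid$gamma[best], cv_accuracy = grid$cv_accuracy[best],
       grid = grid)
}

# ---- passive-aggressive classifier (one-vs-all PA-I) ----

pac_fit <- function(x, y, C = 1, epochs = 5L, seed = 1L) {
  classes <- sort(unique(y))
  d <- ncol(x)
  W <- matrix(0, length(classes), d)
  b <- numeric(length(classes))
  with_local_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(nrow(x))
      for (i in ord) {
        xi <- x[i, ]
        nrm <- sum(xi^2) + 1
        for (kk in seq_along(classes)) {
          yy <- if (y[i] == classes[kk]) 1 else -1
          loss <- max(0, 1 - yy * (sum(W[kk, ] * xi) + b[kk]))
          if (loss > 0) {
            tau <- min(C, loss / nrm)
            W[kk, ] <- W[kk, ] + tau * yy * xi
            b[kk] <- b[kk] + tau * yy
          }
        }
      }
    }
  })
  structure(list(W = W, b = b, classes = classes), class = "pac")
}

#' @export
predict.pac <- function(object, newdata, ...) {
  s <- as.matrix(newdata) %*% t(object$W) +
    matrix(object$b, nrow(newdata), length(object$b), byrow = TRUE)
  object$classes[max.col(s, ties.method = "first")]
}

# ---- nearest centroid ----

nc_fit <- function(x, y) {
  classes <- sort(unique(y))
  centroids <- t(vapply(classes, function(k)
    colMeans(x[y == k, , drop = FALSE]), numeric(ncol(x))))
  structure(list(centroids = centroids, classes = classes), class = "ncentroid")
}

#' @export
predict.ncentroid <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  d2 <- vapply(seq_along(object$classes), function(k)
    rowSums(sweep(X, 2L, object$centroids[k, ])^2), numeric(nrow(X)))
  object$classes[max.col(-matrix(d2, nrow(X)), ties.method = "first")]
}

# ---- the bench ----

#' Train the stress-grading classifier bench
#'
#' Fits the requested subset of the eight classifiers on the training split
#' of a labeled cohort: Gaussian naive Bayes, passive-aggressive classifier
#' (one-vs-all PA-I), nearest centroid, k-nearest neighbours, random
#' forest, one-vs-all SVM with kernel grid search, the reference
#' gradient-boosted trees ([gbdt_fit()], 300 rounds at step size 0.1), and
#' extreme gradient boosting through the xgboost backend with the tuned
#' hyperparameters (softmax objective, 3 classes, tree depth 12, minimum
#' child weight 3, split penalty gamma 0.1).
#'
#' @param cohort A [labeled_cohort()] with (normalized) features.
#' @param algorithms Subset of
#'   `c("GaussianNB","PAC","NC","KNN","RF","SVC","GBDT","XGB")`.
#' @param seed Seed controlling every stochastic learner.
#' @param knn_k Neighbours for KNN.
#' @param rf_trees Trees in the random forest.
#' @param gbdt_trees,gbdt_rate,gbdt_depth Reference-GBDT configuration.
#' @param xgb_rounds,xgb_eta Boosting rounds and learning rate for XGB (its
#'   remaining hyperparameters are fixed to the tuned values).
#' @param svm_folds Cross-validation folds of the SVM grid search.
#' @return Object of class `stress_bench` (list of fitted models plus the
#'   training configuration).
#' @export
stress_bench <- function(cohort, algorithms = bench_algorithms(), seed = 1L,
                         knn_k = 5L, rf_trees = 500L,
                         gbdt_trees = 300L, gbdt_rate = 0.1, gbdt_depth = 3L,
                         xgb_rounds = 100L, xgb_eta = 0.3, svm_folds = 5L) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  algorithms <- match.arg(algorithms, bench_algorithms(), several.ok = TRUE)
  xtr <- cohort$features[cohort$train_idx, , drop = FALSE]
  ytr <- cohort$labels[cohort$train_idx]
  if (length(unique(ytr)) < 2L)
    stop("training data contain a single stress level; cannot fit")
  if (any(tabulate(ytr, 3L) == 0L))
    stop("a stress level is missing from the training data")

  models <- list()
  for (alg in algorithms) {
    models[[alg]] <- switch(alg,
      GaussianNB = e1071::naiveBayes(xtr, factor(ytr, levels = 1:3)),
      PAC = pac_fit(xtr, ytr, seed = seed),
      NC = nc_fit(xtr, ytr),
      KNN = list(x = xtr, y = ytr, k = knn_k),
      RF = with_local_seed(seed,
        randomForest::randomForest(xtr, factor(ytr, levels = 1:3),
                                   ntree = rf_trees)),
      SVC = grid_search_svm(xtr, ytr, folds = svm_folds, seed = seed),
      GBDT = gbdt_fit(xtr, ytr, n_trees = gbdt_trees,
                      learning_rate = gbdt_rate, max_depth = gbdt_depth),
      XGB = {
        dtr <- xgboost::xgb.DMatrix(xtr, label = ytr - 1L)
        xgboost::xgb.train(
          params = list(objective = "multi:softmax", num_class = 3L,
                        max_depth = 12L, min_child_weight = 3,
                        gamma = 0.1, eta = xgb_eta, nthread = 1L,
                        seed = as.integer(seed)),
          data = dtr, nrounds = xgb_rounds, verbose = 0)
      })
  }
  structure(list(models = models, algorithms = algorithms, seed = seed,
                 config = list(knn_k = knn_k, rf_trees = rf_trees,
                               gbdt_trees = gbdt_trees, gbdt_rate = gbdt_rate,
                               gbdt_depth = gbdt_depth,
                               xgb_rounds = xgb_rounds, xgb_eta = xgb_eta,
                               svm_folds = svm_folds)),
            class = "stress_bench")
}

# predictions of one fitted bench member on a feature matrix
bench_predict_one <- function(bench, alg, X) {
  m <- bench$models[[alg]]
  if (is.null(m)) stop("algorithm not fitted: ", alg)
  p <- switch(alg,
    GaussianNB = as.integer(as.character(stats::predict(m, X))),
    PAC = as.integer(predict(m, X)),
    NC = as.integer(predict(m, X)),
    KNN = with_local_seed(bench$seed,
      as.integer(as.character(class::knn(m$x, X, factor(m$y), k = m$k)))),
    RF = as.integer(as.character(stats::predict(m, X))),
    SVC = as.integer(predict(m$model, X)),
    GBDT = as.integer(as.character(predict(m, X))),
    XGB = as.integer(stats::predict(m, xgboost::xgb.DMatrix(X))) + 1L)
  if (anyNA(p) || !all(p %in% 1:3))
    stop("model ", alg, " predicted labels outside {1, 2, 3}")
  p
}

#' Predict stress levels from a fitted bench
#'
#' @param object A [stress_bench()].
#' @param newdata Feature matrix on the training feature scale.
#' @param ... Unused.
#' @return Integer matrix of predicted levels, one column per algorithm.
#' @export
predict.stress_bench <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  vapply(object$algorithms, function(a) bench_predict_one(object, a, X),
         integer(nrow(X)))
}

#' @export
print.stress_bench <- function(x, ...) {
  cat(sprintf("<stress_bench> %d fitted classifiers (seed %d): %s\n",
              length(x$models), x$seed,
              paste(x$algorithms, collapse = ", ")))
  if ("SVC" %in% x$algorithms)
    cat(sprintf("  SVC grid search selected the %s kernel (cost %g, CV accuracy %.3f)\n",
                x$models$SVC$kernel, x$models$SVC$cost,
                x$models$SVC$cv_accuracy))
  invisible(x)
}

#' Per-level classification report
#'
#' Per-level correct/total counts with rank (within-level recall) accuracy
#' and overall accuracy, the layout in which three-level stress benches are
#' conventionally reported.
#'
#' @param correct Integer vector of correctly predicted counts per level
#'   (levels 1..3).
#' @param total Integer vector of test-set counts per level.
#' @return Object of class `class_report` with fields `correct`, `total`,
#'   `rank_accuracy` (percent, per level) and `total_accuracy` (percent).
#' @export
class_report <- function(correct, total) {
  correct <- as.integer(correct); total <- as.integer(total)
  if (length(correct) != length(total)) stop("length mismatch")
  if (any(correct < 0L) || any(total < 0L) || any(correct > total))
    stop("need 0 <= correct <= total per level")
  structure(list(correct = correct, total = total,
                 rank_accuracy = 100 * correct / total,
                 total_accuracy = 100 * sum(correct) / sum(total)),
            class = "class_report")
}

#' @export
print.class_report <- function(x, digits = 2, ...) {
  cat("Stress Level  Prediction Accuracy/Test Set  Rank Accuracy (%)\n")
  for (lv in seq_along(x$correct))
    cat(sprintf("%12d  %28s  %17s\n", lv,
                sprintf("%d/%d", x$correct[lv], x$total[lv]),
                formatC(x$rank_accuracy[lv], format = "f", digits = digits)))
  cat(sprintf("Total Accuracy (%%): %s\n",
              formatC(x$total_accuracy, format = "f", digits = digits)))
  invisible(x)
}

#' Evaluate a fitted bench on the held-out split
#'
#' @param bench A [stress_bench()].
#' @param cohort The [labeled_cohort()] whose `test_idx` rows are scored.
#' @return Named list of [class_report()] objects, one per algorithm.
#' @export
evaluate_bench <- function(bench, cohort) {
  stopifnot(inherits(bench, "stress_bench"), inherits(cohort, "labeled_cohort"))
  if (!length(cohort$test_idx)) stop("test split is empty")
  X <- cohort$features[cohort$test_idx, , drop = FALSE]
  y <- cohort$labels[cohort$test_idx]
  out <- lapply(bench$algorithms, function(a) {
    p <- bench_predict_one(bench, a, X)
    class_report(vapply(1:3, function(lv) sum(p == lv & y == lv), integer(1)),
                 tabulate(y, 3L))
  })
  names(out) <- bench$algorithms
  out
}

#' Render bench reports as a comparison table
#'
#' @param reports Named list of [class_report()]s from [evaluate_bench()].
#' @return A data.frame in the conventional comparison layout (one row per
#'   algorithm and level).
#' @export
report_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(a) {
    r <- reports[[a]]
    data.frame(
      Algorithm = a, Stress_Level = seq_along(r$correct),
      Prediction = sprintf("%d/%d", r$correct, r$total),
      Rank_Accuracy = round(r$rank_accuracy, 2),
      Total_Accuracy = round(r$total_accuracy, 2))
  }))
}
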