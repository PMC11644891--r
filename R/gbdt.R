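# exact-split regression trees + reference gradient boosting
#
# The boosting loop follows the classical scheme: start from the constant
# minimizer of the loss, then repeatedly fit a depth-limited regression tree
# to the negative gradient (pseudo-residuals), set each leaf to the
# loss-minimizing constant for its region, and add the tree scaled by the
# learning rate.  For multiclass deviance this is the one-tree-per-class
# reduction with softmax probabilities.

# greedy exact split search minimizing SSE of r over rows
best_split <- function(X, r, rows, min_leaf) {
  n <- length(rows)
  best <- list(gain = 0, var = NA_integer_, val = NA_real_)
  if (n < 2L * min_leaf) return(best)
  base <- sum(r[rows])^2 / n
  for (j in seq_len(ncol(X))) {
    xv <- X[rows, j]
    o <- order(xv)
    sx <- xv[o]
    cs <- cumsum(r[rows][o])
    tot <- cs[n]
    i <- seq_len(n - 1L)
    ok <- i >= min_leaf & i <= n - min_leaf & sx[i] < sx[i + 1L]
    if (!any(ok)) next
    score <- cs[i]^2 / i + (tot - cs[i])^2 / (n - i)
    score[!ok] <- -Inf
    ib <- which.max(score)
    gain <- score[ib] - base
    if (gain > best$gain + 1e-12) {
      best <- list(gain = gain, var = j, val = (sx[ib] + sx[ib + 1L]) / 2)
    }
  }
  best
}

# returns a flat node table; leaves carry the row sets for leaf-value fitting
fit_reg_tree <- function(X, r, max_depth = 3L, min_split = 10L, min_leaf = 5L) {
  nodes <- list()
  new_node <- function(node) { nodes[[length(nodes) + 1L]] <<- node; length(nodes) }
  grow <- function(rows, depth) {
    id <- new_node(list(leaf = TRUE, rows = rows, var = NA, val = NA,
                        left = NA, right = NA))
    if (depth >= max_depth || length(rows) < min_split) return(id)
    sp <- best_split(X, r, rows, min_leaf)
    if (is.na(sp$var)) return(id)
    go_left <- X[rows, sp$var] <= sp$val
    l <- grow(rows[go_left], depth + 1L)
    rgt <- grow(rows[!go_left], depth + 1L)
    nodes[[id]] <<- list(leaf = FALSE, rows = NULL, var = sp$var,
                         val = sp$val, left = l, right = rgt)
    id
  }
  grow(seq_len(nrow(X)), 0L)
  nodes
}

# leaf index for every row of X
tree_leaf_of <- function(nodes, X) {
  out <- integer(nrow(X))
  assign_rows <- function(id, rows) {
    if (!length(rows)) return(invisible())
    nd <- nodes[[id]]
    if (nd$leaf) { out[rows] <<- id; return(invisible()) }
    gl <- X[rows, nd$var] <= nd$val
    assign_rows(nd$left, rows[gl])
    assign_rows(nd$right, rows[!gl])
  }
  assign_rows(1L, seq_len(nrow(X)))
  out
}

#' Reference gradient-boosted decision trees
#'
#' A transparent, from-scratch gradient-boosting learner built on
#' depth-limited exact-split regression trees.  For `loss = "squared"` it
#' boosts plain residuals from the constant mean.  For
#' `loss = "deviance"` (multiclass) it starts each class score at the log
#' prior, fits one tree per class and round to the softmax pseudo-residuals
#' `y_k - p_k`, and sets each leaf to the standard multinomial
#' loss-minimizing value \eqn{\frac{K-1}{K}\,\sum r / \sum |r|(1-|r|)},
#' scaled by the learning rate.
#'
#' @param x Numeric feature matrix.
#' @param y Labels: a factor/integer vector for `"deviance"`, numeric for
#'   `"squared"`.
#' @param n_trees Number of boosting rounds `M`.
#' @param learning_rate Shrinkage `nu` applied to every tree.
#' @param max_depth Maximum tree depth.
#' @param min_split,min_leaf Minimum node size to attempt a split / minimum
#'   rows per leaf.
#' @param loss `"deviance"` (classification) or `"squared"` (regression).
#' @return Object of class `gbdt`.
#' @seealso [predict.gbdt()]
#' @export
gbdt_fit <- function(x, y, n_trees = 300L, learning_rate = 0.1,
                     max_depth = 3L, min_split = 10L, min_leaf = 5L,
                     loss = c("deviance", "squared")) {
  loss <- match.arg(loss)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.numeric(x)) stop("features must be numeric")
  if (nrow(x) != length(y)) stop("rows(x) must equal length(y)")
  if (n_trees < 1L) stop("`n_trees` must be >= 1")

  pack_tree <- function(nodes, gamma_by_leaf) {
    lapply(seq_along(nodes), function(i) {
      nd <- nodes[[i]]
      list(leaf = nd$leaf, var = nd$var, val = nd$val,
           left = nd$left, right = nd$right,
           gamma = if (nd$leaf) gamma_by_leaf[[as.character(i)]] else NA_real_)
    })
  }

  if (loss == "squared") {
    y <- as.numeric(y)
    f0 <- mean(y)
    f <- rep(f0, length(y))
    trees <- vector("list", n_trees)
    for (m in seq_len(n_trees)) {
      r <- y - f
      nodes <- fit_reg_tree(x, r, max_depth, min_split, min_leaf)
      leaves <- tree_leaf_of(nodes, x)
      gm <- tapply(r, leaves, mean)
      trees[[m]] <- pack_tree(nodes, as.list(gm))
      f <- f + learning_rate * as.numeric(gm[as.character(leaves)])
    }
    model <- list(loss = loss, f0 = f0, trees = trees,
                  learning_rate = learning_rate, classes = NULL)
  } else {
    yf <- factor(y)
    classes <- levels(yf)
    K <- length(classes)
    if (K < 2L) stop("classification needs at least 2 classes")
    n <- length(yf)
    Y <- matrix(0, n, K)
    Y[cbind(seq_len(n), as.integer(yf))] <- 1
    prior <- pmax(colMeans(Y), 1e-12)
    f0 <- log(prior)
    F <- matrix(rep(f0, each = n), n, K)
    trees <- vector("list", n_trees)
    for (m in seq_len(n_trees)) {
      P <- exp(F - apply(F, 1L, max))
      P <- P / rowSums(P)
      round_trees <- vector("list", K)
      for (k in seq_len(K)) {
        r <- Y[, k] - P[, k]
        nodes <- fit_reg_tree(x, r, max_depth, min_split, min_leaf)
        leaves <- tree_leaf_of(nodes, x)
        num <- tapply(r, leaves, sum)
        den <- tapply(abs(r) * (1 - abs(r)), leaves, sum)
        gm <- (K - 1) / K * num / pmax(den, 1e-12)
        round_trees[[k]] <- pack_tree(nodes, as.list(gm))
        F[, k] <- F[, k] + learning_rate * as.numeric(gm[as.character(leaves)])
      }
      trees[[m]] <- round_trees
    }
    model <- list(loss = loss, f0 = f0, trees = trees,
                  learning_rate = learning_rate, classes = classes)
  }
  structure(c(model, list(n_trees = n_trees, max_depth = max_depth)),
            class = "gbdt")
}

tree_predict <- function(tree, X) {
  out <- numeric(nrow(X))
  walk <- function(id, rows) {
    if (!length(rows)) return(invisible())
    nd <- tree[[id]]
    if (nd$leaf) { out[rows] <<- nd$gamma; return(invisible()) }
    gl <- X[rows, nd$var] <= nd$val
    walk(nd$left, rows[gl])
    walk(nd$right, rows[!gl])
  }
  walk(1L, seq_len(nrow(X)))
  out
}

#' Predict from a reference GBDT model
#'
#' @param object A [gbdt_fit()] model.
#' @param newdata Numeric feature matrix.
#' @param type `"class"` (default for deviance models), `"prob"` for softmax
#'   probabilities, `"response"` for raw scores / regression values.
#' @param ... Unused.
#' @return Class labels, probability matrix, or numeric predictions.
#' @export
predict.gbdt <- function(object, newdata,
                         type = c("class", "prob", "response"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (object$loss == "squared") {
    f <- rep(object$f0, nrow(X))
    for (tr in object$trees)
      f <- f + object$learning_rate * tree_predict(tr, X)
    return(f)
  }
  K <- length(object$classes)
  F <- matrix(rep(object$f0, each = nrow(X)), nrow(X), K)
  for (rt in object$trees)
    for (k in seq_len(K))
      F[, k] <- F[, k] + object$learning_rate * tree_predict(rt[[k]], X)
  if (type == "response") return(F)
  P <- exp(F - apply(F, 1L, max))
  P <- P / rowSums(P)
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.gbdt <- function(x, ...) {
  cat(sprintf("<gbdt> %s, %d rounds, depth %d, learning rate %g\n",
              if (x$loss == "squared") "squared-loss regression"
              else sprintf("%d-class deviance", length(x$classes)),
              x$n_trees, x$max_depth, x$learning_rate))
  invisible(x)
}
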