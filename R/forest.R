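#' Compact random forest (CART bagging with feature subsampling)
#'
#' A self-contained random-forest classifier: bootstrap-bagged binary CART
#' trees with Gini splitting and per-node random feature subsets. Class
#' balance is handled by stratified bootstrap sampling (each tree sees the
#' same number of cases per class). Small and deterministic given the seed;
#' built for the modest feature tables this package produces, not as a
#' general-purpose learner.
#'
#' @param x numeric matrix or data.frame of features.
#' @param y factor (or coercible) of class labels; >= 2 classes.
#' @param n_trees number of trees.
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param min_node minimum cases in a splittable node.
#' @param max_depth depth cap.
#' @param seed integer seed.
#' @return object of class `rf_model` with `trees`, `classes`,
#'   `feature_names`, `importance` (mean decrease in Gini).
#' @export
rf_fit <- function(x, y, n_trees = 200L, mtry = NULL, min_node = 2L,
                   max_depth = 25L, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least two classes")
  yi <- as.integer(y)
  p <- ncol(x)
  mtry <- mtry %||% max(1L, floor(sqrt(p)))
  C <- nlevels(y)
  per_class <- min(table(yi))
  importance <- stats::setNames(numeric(p),
                                colnames(x) %||% paste0("f", seq_len(p)))
  trees <- vector("list", n_trees)
  with_seed(seed, {
    for (t in seq_len(n_trees)) {
      # stratified bootstrap: per_class draws with replacement per class
      boot <- unlist(lapply(seq_len(C), function(cl) {
        pool <- which(yi == cl)
        pool[sample.int(length(pool), per_class, replace = TRUE)]
      }))
      tr <- grow_tree(x, yi, boot, C, mtry, min_node, max_depth)
      trees[[t]] <- tr
      importance <- importance + tr$importance
    }
  })
  structure(list(trees = trees, classes = levels(y),
                 feature_names = colnames(x) %||% paste0("f", seq_len(p)),
                 importance = importance / n_trees,
                 n_trees = n_trees, mtry = mtry, seed = seed),
            class = "rf_model")
}

gini_impurity <- function(counts, n) 1 - sum((counts / n)^2)

grow_tree <- function(x, yi, idx, C, mtry, min_node, max_depth) {
  # nodes stored as parallel vectors; feature = NA marks a leaf
  env <- new.env()
  env$feature <- integer(0); env$thr <- numeric(0)
  env$left <- integer(0); env$right <- integer(0)
  env$pred <- integer(0)
  env$importance <- numeric(ncol(x))
  n_total <- length(idx)
  new_node <- function() {
    k <- length(env$feature) + 1L
    env$feature[k] <- NA_integer_; env$thr[k] <- NA_real_
    env$left[k] <- 0L; env$right[k] <- 0L; env$pred[k] <- 0L
    k
  }
  build <- function(rows, depth) {
    k <- new_node()
    counts <- tabulate(yi[rows], C)
    env$pred[k] <- which.max(counts)
    n <- length(rows)
    if (n < 2L * min_node || depth >= max_depth || sum(counts > 0) == 1L)
      return(k)
    g0 <- gini_impurity(counts, n)
    feats <- sample.int(ncol(x), mtry)
    best <- list(gain = 1e-12)
    for (j in feats) {
      v <- x[rows, j]
      ord <- order(v)
      vs <- v[ord]
      if (vs[1] == vs[n]) next
      ys <- yi[rows][ord]
      cnt <- vapply(seq_len(C), function(cl) cumsum(ys == cl),
                    numeric(n))
      i <- seq_len(n - 1L)
      cntL <- cnt[i, , drop = FALSE]
      cntR <- matrix(cnt[n, ], n - 1L, C, byrow = TRUE) - cntL
      impL <- 1 - rowSums((cntL / i)^2)
      impR <- 1 - rowSums((cntR / (n - i))^2)
      imp <- (i * impL + (n - i) * impR) / n
      valid <- vs[i] < vs[i + 1L]
      if (!any(valid)) next
      imp[!valid] <- Inf
      b <- which.min(imp)
      gain <- g0 - imp[b]
      if (gain > best$gain) {
        best <- list(gain = gain, j = j, thr = (vs[b] + vs[b + 1L]) / 2,
                     lrows = rows[ord[seq_len(b)]],
                     rrows = rows[ord[(b + 1L):n]])
      }
    }
    if (is.null(best$j)) return(k)
    env$feature[k] <- best$j
    env$thr[k] <- best$thr
    env$importance[best$j] <- env$importance[best$j] +
      best$gain * n / n_total
    env$left[k] <- build(best$lrows, depth + 1L)
    env$right[k] <- build(best$rrows, depth + 1L)
    k
  }
  build(idx, 0L)
  list(feature = env$feature, thr = env$thr, left = env$left,
       right = env$right, pred = env$pred, importance = env$importance)
}

#' Predict with an [rf_fit()] forest
#'
#' @param object an `rf_model`.
#' @param newdata feature matrix or data.frame with the training columns.
#' @param type `"class"` for majority-vote labels, `"prob"` for vote
#'   fractions.
#' @param ... unused.
#' @return factor of predictions or a matrix of class-vote fractions.
#' @export
predict.rf_model <- function(object, newdata, type = c("class", "prob"),
                             ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    missing <- setdiff(object$feature_names, names(newdata))
    if (length(missing) > 0)
      stop("missing features: ", paste(missing, collapse = ", "))
    newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  }
  storage.mode(newdata) <- "double"
  n <- nrow(newdata)
  C <- length(object$classes)
  votes <- matrix(0, n, C, dimnames = list(NULL, object$classes))
  for (tr in object$trees) {
    node <- rep(1L, n)
    repeat {
      split <- !is.na(tr$feature[node])
      if (!any(split)) break
      j <- tr$feature[node[split]]
      goleft <- newdata[cbind(which(split), j)] <= tr$thr[node[split]]
      node[split] <- ifelse(goleft, tr$left[node[split]],
                            tr$right[node[split]])
    }
    pred <- tr$pred[node]
    votes[cbind(seq_len(n), pred)] <- votes[cbind(seq_len(n), pred)] + 1
  }
  if (type == "prob") return(votes / object$n_trees)
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}
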