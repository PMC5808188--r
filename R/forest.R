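#' Random forest for pixel classification
#'
#' A self-contained random-forest classifier (no external RF library in the
#' runtime): an ensemble of CART-style decision trees, each grown on a
#' bootstrap sample of the training rows, choosing at every split node the
#' best Gini-impurity split among `mtry` randomly sampled features, and
#' combined by majority vote. Ties in the vote go to the lowest class code
#' so predictions are deterministic.
#'
#' Trees are grown to purity (no depth pruning beyond a defensive cap),
#' matching the standard RF recipe for classification.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y integer class codes (>= 1).
#' @param n_trees number of trees, default 100.
#' @param mtry features sampled per split, default 2.
#' @param seed RNG seed controlling bootstraps and feature sampling.
#' @param min_node minimum node size to attempt a split, default 2.
#' @param max_depth defensive recursion cap, default 30.
#' @return object of class `rf_model`.
#' @export
rf_train <- function(x, y, n_trees = 100, mtry = 2, seed = 42L,
                     min_node = 2L, max_depth = 30L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), n_trees >= 1)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("training data must contain >= 2 classes")
  if (mtry < 1 || mtry > ncol(x)) stop("mtry must be in 1..n_features")
  n <- nrow(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- grow_tree(x, y, boot, classes, mtry, min_node, max_depth)
  }
  structure(list(trees = trees, classes = classes, n_features = ncol(x),
                 feature_names = colnames(x),
                 n_trees = n_trees, mtry = mtry, seed = as.integer(seed)),
            class = "rf_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Grow one CART tree on x[boot, ]. Nodes are stored as parallel vectors:
# feature/threshold for internal nodes, pred for leaves, left/right child ids.
grow_tree <- function(x, y, boot, classes, mtry, min_node, max_depth) {
  K <- length(classes)
  ycode <- match(y, classes)
  env <- new.env(parent = emptyenv())
  env$feature <- integer(0); env$threshold <- numeric(0)
  env$left <- integer(0); env$right <- integer(0); env$pred <- integer(0)

  new_node <- function() {
    id <- length(env$feature) + 1L
    env$feature[id] <- NA_integer_; env$threshold[id] <- NA_real_
    env$left[id] <- 0L; env$right[id] <- 0L; env$pred[id] <- NA_integer_
    id
  }

  build <- function(idx, depth) {
    id <- new_node()
    yy <- ycode[idx]
    counts <- tabulate(yy, nbins = K)
    # leaf conditions: pure, tiny, or depth cap
    if (length(idx) < min_node || depth >= max_depth ||
        sum(counts > 0) == 1L) {
      env$pred[id] <- which.max(counts)  # ties -> lowest class index
      return(id)
    }
    sp <- best_split(x, idx, yy, counts, mtry)
    if (is.null(sp)) {
      env$pred[id] <- which.max(counts)
      return(id)
    }
    go_left <- x[idx, sp$feature] <= sp$threshold
    env$feature[id] <- sp$feature
    env$threshold[id] <- sp$threshold
    lid <- build(idx[go_left], depth + 1L)
    rid <- build(idx[!go_left], depth + 1L)
    env$left[id] <- lid; env$right[id] <- rid
    id
  }

  best_split <- function(x, idx, yy, counts, mtry) {
    n <- length(idx)
    K <- length(counts)
    parent_gini <- 1 - sum((counts / n)^2)
    feats <- sample.int(ncol(x), mtry)
    best <- NULL; best_imp <- parent_gini - 1e-12
    for (j in feats) {
      xs <- x[idx, j]
      o <- order(xs)
      xo <- xs[o]; yo <- yy[o]
      valid <- which(xo[-n] < xo[-1])     # split between distinct values
      if (!length(valid)) next
      cum <- matrix(0, n, K)
      for (k in seq_len(K)) cum[, k] <- cumsum(yo == k)
      i <- valid
      nl <- i; nr <- n - i
      gl <- 1 - rowSums((cum[i, , drop = FALSE] / nl)^2)
      cr <- matrix(counts, length(i), K, byrow = TRUE) - cum[i, , drop = FALSE]
      gr <- 1 - rowSums((cr / nr)^2)
      w <- (nl * gl + nr * gr) / n
      b <- which.min(w)
      if (w[b] < best_imp) {
        best_imp <- w[b]
        best <- list(feature = j,
                     threshold = (xo[i[b]] + xo[i[b] + 1L]) / 2)
      }
    }
    best
  }

  root <- build(boot, 0L)
  list(feature = env$feature, threshold = env$threshold,
       left = env$left, right = env$right, pred = env$pred, root = root)
}

#' Predict class codes with a random forest
#'
#' Vectorized tree descent: all rows advance one level per iteration, so
#' prediction cost scales with tree depth rather than sample count in R
#' overhead terms. Majority vote over trees; ties resolved to the lowest
#' class code.
#'
#' @param model an `rf_model` from [rf_train()].
#' @param x numeric feature matrix with `model$n_features` columns.
#' @param votes if `TRUE`, also return the vote count matrix.
#' @return integer vector of predicted class codes (or a list with `pred`
#'   and `votes`).
#' @export
rf_predict <- function(model, x, votes = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != model$n_features)
    stop("feature count mismatch: model expects ", model$n_features)
  n <- nrow(x)
  K <- length(model$classes)
  vote <- matrix(0L, n, K)
  rows <- seq_len(n)
  for (tr in model$trees) {
    node <- rep(tr$root, n)
    active <- rows[is.na(tr$pred[node])]
    while (length(active)) {
      nd <- node[active]
      f <- tr$feature[nd]
      xv <- x[cbind(active, f)]
      node[active] <- ifelse(xv <= tr$threshold[nd], tr$left[nd], tr$right[nd])
      active <- active[is.na(tr$pred[node[active]])]
    }
    p <- tr$pred[node]
    ix <- cbind(rows, p)
    vote[ix] <- vote[ix] + 1L
  }
  pred_idx <- max.col(vote, ties.method = "first")  # first = lowest class code
  pred <- model$classes[pred_idx]
  if (votes) list(pred = pred, votes = vote) else pred
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model> %d trees, mtry=%d, %d features, classes: %s (seed %d)\n",
              x$n_trees, x$mtry, x$n_features,
              paste(x$classes, collapse = ","), x$seed))
  invisible(x)
}
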