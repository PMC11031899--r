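## Minimal random forest for binary feature matrices (no RF package is
## available in the target environment). Bootstrap aggregation of fully grown
## CART trees with per-node feature subsampling and Gini splits; binary
## features make each candidate split a 0/1 partition.

.rfBuildTree <- function(X, y, mtry, minNode, maxDepth) {
  feature <- integer(0); left <- integer(0); right <- integer(0)
  prob <- numeric(0)
  P <- ncol(X)
  newNode <- function() {
    feature[length(feature) + 1L] <<- 0L
    left[length(left) + 1L] <<- 0L
    right[length(right) + 1L] <<- 0L
    prob[length(prob) + 1L] <<- NA_real_
    length(feature)
  }
  build <- function(idx, depth) {
    id <- newNode()
    nn <- length(idx)
    npos <- sum(y[idx])
    if (npos == 0L || npos == nn || nn < 2L * minNode || depth >= maxDepth) {
      prob[id] <<- npos / nn
      return(id)
    }
    feats <- sample.int(P, min(mtry, P))
    sub <- X[idx, feats, drop = FALSE]
    n1 <- colSums(sub)
    pos1 <- as.vector(crossprod(sub, y[idx]))
    n0 <- nn - n1; pos0 <- npos - pos1
    valid <- n1 >= minNode & n0 >= minNode
    if (!any(valid)) {
      prob[id] <<- npos / nn
      return(id)
    }
    gini <- function(pos, n) ifelse(n > 0, 2 * (pos / n) * (1 - pos / n), 0)
    impurity <- (n0 * gini(pos0, n0) + n1 * gini(pos1, n1)) / nn
    impurity[!valid] <- Inf
    parentImp <- gini(npos, nn)
    bestF <- which.min(impurity)
    if (impurity[bestF] >= parentImp - 1e-12) {
      prob[id] <<- npos / nn
      return(id)
    }
    f <- feats[bestF]
    goRight <- X[idx, f] != 0
    feature[id] <<- f
    left[id] <<- build(idx[!goRight], depth + 1L)
    right[id] <<- build(idx[goRight], depth + 1L)
    id
  }
  root <- build(seq_along(y), 0L)
  list(feature = feature, left = left, right = right, prob = prob,
       root = root)
}

.rfTreePredict <- function(tree, X) {
  out <- numeric(nrow(X))
  descend <- function(id, rows) {
    f <- tree$feature[id]
    if (f == 0L) {
      out[rows] <<- tree$prob[id]
      return(invisible(NULL))
    }
    goRight <- X[rows, f] != 0
    if (any(!goRight)) descend(tree$left[id], rows[!goRight])
    if (any(goRight)) descend(tree$right[id], rows[goRight])
  }
  if (nrow(X)) descend(tree$root, seq_len(nrow(X)))
  out
}

# fit: bootstrap + feature-subsampled Gini trees; deterministic given the
# RNG state set by the caller
.rfFit <- function(X, y, nTrees = 500L, mtry = NULL, minNode = 1L,
                   maxDepth = Inf) {
  stopifnot(nrow(X) == length(y))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  n <- nrow(X)
  trees <- vector("list", nTrees)
  for (t in seq_len(nTrees)) {
    boot <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- .rfBuildTree(X[boot, , drop = FALSE], y[boot],
                               mtry = mtry, minNode = minNode,
                               maxDepth = maxDepth)
  }
  structure(list(trees = trees, p = ncol(X)), class = "pacsenseRF")
}

.rfPredict <- function(fit, X) {
  stopifnot(ncol(X) == fit$p)
  acc <- numeric(nrow(X))
  for (tree in fit$trees) acc <- acc + .rfTreePredict(tree, X)
  acc / length(fit$trees)
}
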