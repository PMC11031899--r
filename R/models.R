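## The four classifier back-ends behind one fit/predict contract.

.defaultHyper <- function(kind) {
  h <- list(
    embedding_dim = 20L, hidden_units = 20L, aggregation = "mean",
    learning_rate = 1e-3, max_epochs = 500L, batch_size = 32L,
    early_stopping = TRUE, early_stopping_patience = 20L,
    inner_fraction = 0.1, monitor = "loss", n_restarts = 1L,
    embed_init_sd = 0.1,
    l2_penalty = 1.0, n_trees = 500L, max_depth = Inf, mtry = NULL,
    min_node = 1L)
  h
}

#' Specify a classifier
#'
#' The four model kinds of the study design: `random_forest`,
#' `logistic_regression`, `ann` (single hidden layer on the concatenated
#' binary clinical + binary variant vector) and `ann_with_ge` (the same
#' network fed with clinical features plus an aggregated learned variant
#' embedding). Defaults follow the study configuration where stated
#' (embedding dimension 20, one hidden layer of 20 nodes) and standard
#' choices elsewhere (mean aggregation, Adam with learning rate 1e-3, at
#' most 500 epochs, batch 32, early stopping on a 10\% inner split with
#' patience 20; RF 500 trees of unlimited depth; logistic regression with L2
#' penalty 1 on the sklearn scale, i.e. ridge `lambda = 1/n`).
#'
#' @param kind Model kind (see above).
#' @param ... Hyperparameter overrides by name (e.g. `aggregation = "sum"`,
#'   `n_trees = 100`).
#' @param seed Integer seed honoured by every back-end.
#' @return A [ModelSpec].
#' @export
modelSpec <- function(kind = c("random_forest", "logistic_regression",
                               "ann", "ann_with_ge"),
                      ..., seed = 1L) {
  kind <- match.arg(kind)
  hyper <- .defaultHyper(kind)
  dots <- list(...)
  bad <- setdiff(names(dots), names(hyper))
  if (length(bad))
    stop("unknown hyperparameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  hyper[names(dots)] <- dots
  if (!hyper$aggregation %in% c("mean", "sum"))
    stop("aggregation must be 'mean' or 'sum'", call. = FALSE)
  new("ModelSpec", kind = kind, hyper = hyper, seed = as.integer(seed))
}

#' Aggregate variant embeddings for one patient
#'
#' Elementwise mean (default) or sum of the embedding rows of the carried
#' variant set. The empty set maps to the zero vector; the result is
#' invariant to listing order and duplication of indices.
#'
#' @param variantIdx Integer set of 1-based vocabulary indices.
#' @param E V x d embedding matrix.
#' @param aggregation `"mean"` or `"sum"`.
#' @return Numeric vector of length `ncol(E)`.
#' @examples
#' embedAggregate(c(1, 2), rbind(c(1, 0), c(0, 1)))  # c(0.5, 0.5)
#' @export
embedAggregate <- function(variantIdx, E, aggregation = c("mean", "sum")) {
  aggregation <- match.arg(aggregation)
  variantIdx <- unique(as.integer(variantIdx))
  if (length(variantIdx) && any(variantIdx < 1L | variantIdx > nrow(E)))
    stop("variant index outside the embedding table (V = ", nrow(E), ")",
         call. = FALSE)
  if (!length(variantIdx)) return(numeric(ncol(E)))
  v <- colSums(E[variantIdx, , drop = FALSE])
  if (aggregation == "mean") v / length(variantIdx) else v
}

#' Forward pass of the embedding network
#'
#' `p = sigmoid(w2 . relu(W1' [clinical, g] + b1) + b2)` with `g` the
#' aggregated embedding of the variant set.
#'
#' @param clinical Numeric binary clinical vector (length k).
#' @param variantIdx Integer variant index set.
#' @param params An [EmbedNetParams].
#' @param aggregation `"mean"` or `"sum"`.
#' @return Probability in (0, 1).
#' @export
forwardEmbedNet <- function(clinical, variantIdx, params,
                            aggregation = c("mean", "sum")) {
  aggregation <- match.arg(aggregation)
  stopifnot(is(params, "EmbedNetParams"))
  g <- embedAggregate(variantIdx, params@E, aggregation)
  x <- c(as.numeric(clinical), g)
  if (length(x) != nrow(params@W1))
    stop("shape mismatch: input width ", length(x), " vs W1 rows ",
         nrow(params@W1), call. = FALSE)
  h <- pmax(drop(crossprod(params@W1, x)) + params@b1, 0)
  .sigmoid(sum(params@w2 * h) + params@b2)
}

.trainLabels <- function(features, trainIdx) {
  lab <- features@labels[trainIdx]
  if (any(lab == "excluded"))
    stop("training indices contain 'excluded' patients", call. = FALSE)
  as.integer(lab == "sensitive")
}

#' Train the variant-embedding network
#'
#' Minimises mean binary cross-entropy by minibatch Adam; the embedding table
#' (initialised N(0, 0.1)) is tuned jointly with the network. Embedding rows
#' of variants never seen in the training split receive zero gradient and
#' remain exactly at their initialisation. Deterministic given `spec@seed`;
#' the parameters returned are the best monitored iterate, so the final
#' monitored loss never exceeds the epoch-0 loss.
#'
#' @param features A [PacFeatureSet].
#' @param trainIdx Training row indices (labels must not be `excluded`).
#' @param spec A [ModelSpec] of kind `ann_with_ge`.
#' @return An [EmbedNetParams].
#' @export
trainEmbedNet <- function(features, trainIdx, spec = modelSpec("ann_with_ge")) {
  stopifnot(is(features, "PacFeatureSet"), spec@kind == "ann_with_ge")
  y <- .trainLabels(features, trainIdx)
  set.seed(spec@seed)
  out <- .trainNet(features@clinical[trainIdx, , drop = FALSE],
                   features@variantMatrix[trainIdx, , drop = FALSE],
                   y, embed = TRUE, hyper = spec@hyper)
  p <- out$params
  new("EmbedNetParams", E = p$E, W1 = p$W1, b1 = p$b1, w2 = p$w2, b2 = p$b2)
}

#' Fit any of the four classifiers
#'
#' Baselines consume the concatenated binary matrix `[clinical, variant]`
#' (width k + V); `ann_with_ge` consumes clinical features plus variant index
#' sets. Every back-end honours `spec@seed` (refitting with the same seed
#' reproduces the identical prediction vector).
#'
#' @param spec A [ModelSpec].
#' @param features A [PacFeatureSet].
#' @param trainIdx Training row indices (non-excluded labels).
#' @return A fitted [PacModel].
#' @export
fitClassifier <- function(spec, features, trainIdx) {
  stopifnot(is(spec, "ModelSpec"), is(features, "PacFeatureSet"))
  validObject(spec)
  y <- .trainLabels(features, trainIdx)
  if (length(unique(y)) < 2L)
    stop("training data contain a single class", call. = FALSE)
  Clin <- features@clinical[trainIdx, , drop = FALSE]
  Xfull <- cbind(features@clinical, features@variantMatrix)
  fit <- switch(spec@kind,
    logistic_regression = {
      lam <- spec@hyper$l2_penalty / length(trainIdx)
      glmnet::glmnet(Xfull[trainIdx, , drop = FALSE], y,
                     family = "binomial", alpha = 0, lambda = lam,
                     standardize = FALSE)
    },
    random_forest = {
      set.seed(spec@seed)
      .rfFit(Xfull[trainIdx, , drop = FALSE], y,
             nTrees = spec@hyper$n_trees, mtry = spec@hyper$mtry,
             minNode = spec@hyper$min_node, maxDepth = spec@hyper$max_depth)
    },
    ann = {
      set.seed(spec@seed)
      out <- .trainNet(Clin,
                       features@variantMatrix[trainIdx, , drop = FALSE],
                       y, embed = FALSE, hyper = spec@hyper)
      out$params
    },
    ann_with_ge = trainEmbedNet(features, trainIdx, spec))
  new("PacModel", spec = spec, fit = fit,
      vocabulary = features@vocabulary,
      clinicalNames = colnames(features@clinical))
}

#' Predict sensitivity probabilities
#'
#' One probability per requested patient; the model is not mutated, and a
#' feature set built on a different vocabulary or clinical layout is refused.
#'
#' @param model A fitted [PacModel].
#' @param features A [PacFeatureSet].
#' @param indices Row indices to score (default: all rows).
#' @param ... Unused.
#' @return Numeric probabilities in (0, 1).
#' @name predictProba
NULL

#' @rdname predictProba
#' @export
setMethod("predictProba", "PacModel",
          function(model, features, indices, ...) {
  stopifnot(is(features, "PacFeatureSet"))
  if (missing(indices)) indices <- seq_along(features@patientIDs)
  if (!identical(features@vocabulary@ids, model@vocabulary@ids))
    stop("feature-set vocabulary does not match the model vocabulary",
         call. = FALSE)
  if (!identical(colnames(features@clinical), model@clinicalNames))
    stop("clinical feature layout does not match the model", call. = FALSE)
  Clin <- features@clinical[indices, , drop = FALSE]
  M <- features@variantMatrix[indices, , drop = FALSE]
  switch(model@spec@kind,
    logistic_regression = {
      as.numeric(stats::predict(model@fit, cbind(Clin, M),
                                type = "response"))
    },
    random_forest = .rfPredict(model@fit, cbind(Clin, M)),
    ann = .netPredict(model@fit, Clin, M, "sum"),
    ann_with_ge = {
      p <- model@fit
      pl <- list(E = p@E, W1 = p@W1, b1 = p@b1, w2 = p@w2, b2 = p@b2)
      .netPredict(pl, Clin, M, model@spec@hyper$aggregation)
    })
})

#' Save or reload a fitted model bundle
#'
#' The bundle (one RDS file) carries the parameter arrays, the [ModelSpec]
#' and the training vocabulary, sufficient for bit-identical reload.
#'
#' @param model A [PacModel].
#' @param path File path (conventionally `.rds`).
#' @return `saveModel()` the path invisibly; `loadModel()` the [PacModel].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "PacModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "PacModel")) stop("not a pacsense model bundle")
  model
}
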