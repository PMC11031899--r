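## Single-hidden-layer network engine shared by the plain ANN (raw binary
## variant features) and the variant-embedding ANN. Written from scratch:
## the learned variant-set embedding IS the method under study here.
##
## Architecture: x = [clinical, g]  where g is either the raw binary variant
## vector (plain ANN) or the aggregated embedding  g = agg_{v in S} E[v, ]
## (mean or sum over the carried set S). Then
##   p = sigmoid( w2 . relu(W1' x + b1) + b2 ),
## trained by minibatch Adam on the mean binary cross-entropy.

.sigmoid <- function(z) 1 / (1 + exp(-z))

# aggregation operator as a row-weight matrix: Agg = Mw %*% E
.aggWeights <- function(M, aggregation) {
  if (aggregation == "mean") M / pmax(rowSums(M), 1) else M
}

.initNetParams <- function(V, k, d, h, embed, sdE = 0.1) {
  # He-style scaling for the ReLU layer; embedding rows N(0, sdE) as stated
  E <- if (embed) matrix(rnorm(V * d, 0, sdE), V, d) else NULL
  inW <- k + d
  list(E = E,
       W1 = matrix(rnorm(inW * h, 0, sqrt(2 / inW)), inW, h),
       b1 = rep(0.1, h),  # slightly positive: keeps ReLU units live at init
       w2 = rnorm(h, 0, sqrt(2 / h)),
       b2 = 0)
}

# forward pass on a batch; G = aggregated genetic block (n x d)
.netForward <- function(params, Clin, G) {
  X <- cbind(Clin, G)
  Z1 <- sweep(X %*% params$W1, 2L, params$b1, "+")
  H <- pmax(Z1, 0)
  z2 <- drop(H %*% params$w2) + params$b2
  list(p = .sigmoid(z2), X = X, Z1 = Z1, H = H)
}

.bceLoss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

# loss and analytic gradients of mean BCE w.r.t. every parameter block.
# Mw: aggregation-weight matrix (n x V), NULL for the plain ANN (G fixed).
.netLossGrad <- function(params, Clin, G, y, Mw = NULL) {
  n <- length(y)
  fw <- .netForward(params, Clin, G)
  loss <- .bceLoss(fw$p, y)
  dz2 <- (fw$p - y) / n
  gw2 <- drop(crossprod(fw$H, dz2))
  gb2 <- sum(dz2)
  dH <- outer(dz2, params$w2)
  dZ1 <- dH * (fw$Z1 > 0)
  gW1 <- crossprod(fw$X, dZ1)
  gb1 <- colSums(dZ1)
  grads <- list(W1 = gW1, b1 = gb1, w2 = gw2, b2 = gb2)
  if (!is.null(Mw)) {
    k <- ncol(Clin)
    dX <- dZ1 %*% t(params$W1)
    dG <- dX[, (k + 1):ncol(dX), drop = FALSE]
    grads$E <- crossprod(Mw, dG)
  }
  list(loss = loss, grads = grads)
}

.adamInit <- function(params) {
  zero <- function(x) if (is.null(x)) NULL else x * 0
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

.adamUpdate <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# compute the genetic block for given params (embedding or identity)
.geneticBlock <- function(params, M, Mw) {
  if (is.null(params$E)) M else Mw %*% params$E
}

# stratified inner split for early stopping: ~fraction of each class
.innerHoldout <- function(y, fraction) {
  val <- integer(0)
  for (cls in c(0L, 1L)) {
    members <- which(y == cls)
    k <- max(1L, floor(length(members) * fraction))
    val <- c(val, members[sample.int(length(members), k)])
  }
  sort(val)
}

# rank-based AUROC (positive = y == 1); used as an early-stopping monitor
.fastAUC <- function(p, y) {
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# core trainer; returns list(params, history). Deterministic given the seed
# set by the caller. Always returns the parameters with the best monitored
# value seen (the initial parameters included), so with the loss monitor the
# final training loss never exceeds the epoch-0 loss and is monotone in
# max_epochs when early stopping is off. hyper$monitor chooses the
# early-stopping criterion: "loss" (inner BCE, minimised) or "auc" (inner
# AUROC, maximised; ties broken by loss).
.trainNet <- function(Clin, M, y, embed, hyper) {
  n <- length(y)
  stopifnot(nrow(Clin) == n, nrow(M) == n)
  if (length(unique(y)) < 2L)
    stop("training data contain a single class", call. = FALSE)
  d <- if (embed) hyper$embedding_dim else ncol(M)
  agg <- if (embed) hyper$aggregation else "sum"
  Mw <- .aggWeights(M, agg)

  useES <- isTRUE(hyper$early_stopping)
  if (useES) {
    innerVal <- .innerHoldout(y, hyper$inner_fraction)
    fitIdx <- setdiff(seq_len(n), innerVal)
    if (length(unique(y[fitIdx])) < 2L || !length(innerVal)) {
      useES <- FALSE
      fitIdx <- seq_len(n)
    }
  } else {
    fitIdx <- seq_len(n)
  }

  useAUC <- useES && identical(hyper$monitor, "auc")
  # monitored value; a pair (primary, tiebreak loss), lower is better
  monitorVal <- function(p) {
    idx <- if (useES) innerVal else fitIdx
    fw <- .netForward(p, Clin[idx, , drop = FALSE],
                      .geneticBlock(p, M[idx, , drop = FALSE],
                                    Mw[idx, , drop = FALSE]))
    loss <- .bceLoss(fw$p, y[idx])
    if (useAUC) c(-.fastAUC(fw$p, y[idx]), loss) else c(loss, loss)
  }
  better <- function(a, b) {
    a[1] < b[1] - 1e-12 || (abs(a[1] - b[1]) <= 1e-12 && a[2] < b[2] - 1e-12)
  }

  oneRun <- function() {
    params <- .initNetParams(ncol(M), ncol(Clin), d, hyper$hidden_units,
                             embed, hyper$embed_init_sd)
    # reject initialisations with no live ReLU unit on the training data
    # (a dead network has identically zero gradients and can never learn)
    for (try in 1:20) {
      fw <- .netForward(params, Clin[fitIdx, , drop = FALSE],
                        .geneticBlock(params, M[fitIdx, , drop = FALSE],
                                      Mw[fitIdx, , drop = FALSE]))
      if (any(fw$Z1 > 0)) break
      params <- .initNetParams(ncol(M), ncol(Clin), d, hyper$hidden_units,
                               embed, hyper$embed_init_sd)
    }
    best <- params
    bestVal <- monitorVal(params)
    sinceBest <- 0L
    state <- .adamInit(params)
    bs <- min(hyper$batch_size, length(fitIdx))
    history <- numeric(0)
    for (epoch in seq_len(hyper$max_epochs)) {
      perm <- fitIdx[sample.int(length(fitIdx))]
      starts <- seq(1L, length(perm), by = bs)
      for (s in starts) {
        b <- perm[s:min(s + bs - 1L, length(perm))]
        Mb <- M[b, , drop = FALSE]
        Mwb <- Mw[b, , drop = FALSE]
        G <- .geneticBlock(params, Mb, Mwb)
        lg <- .netLossGrad(params, Clin[b, , drop = FALSE], G, y[b],
                           Mw = if (embed) Mwb else NULL)
        upd <- .adamUpdate(params, lg$grads, state, hyper$learning_rate)
        params <- upd$params; state <- upd$state
      }
      cur <- monitorVal(params)
      history <- c(history, cur[1])
      if (better(cur, bestVal)) {
        bestVal <- cur; best <- params; sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (useES && sinceBest >= hyper$early_stopping_patience) break
      }
    }
    list(params = best, history = history, monitor = bestVal)
  }

  out <- oneRun()
  nRestarts <- max(1L, as.integer(hyper$n_restarts %||% 1L))
  for (r in seq_len(nRestarts - 1L)) {
    alt <- oneRun()
    if (better(alt$monitor, out$monitor)) out <- alt
  }
  out$params <- lapply(out$params, function(x) {
    if (is.matrix(x)) dimnames(x) <- NULL else x <- unname(x)
    x
  })
  list(params = out$params, history = out$history,
       monitor = out$monitor, aggregation = agg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# predictions for a network fit on new rows
.netPredict <- function(params, Clin, M, aggregation) {
  Mw <- .aggWeights(M, if (is.null(params$E)) "sum" else aggregation)
  fw <- .netForward(params, Clin, .geneticBlock(params, M, Mw))
  fw$p
}
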