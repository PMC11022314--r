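#' ClassifierModel: a three-layer feed-forward taxonomic classifier
#'
#' Holds the learned weights of a 3-layer multi-layer perceptron mapping a
#' canonical k-mer frequency profile to class probabilities over taxa,
#' together with the metadata needed to apply it to raw sequences: the
#' k-mer length, the profile normalisation mode and the label map (class
#' column i corresponds to `labelMap[i]`). The first two affine layers are
#' each followed by ReLU and (during training) dropout; the output layer is
#' affine followed by softmax.
#'
#' @slot weights List `W1, b1, W2, b2, W3, b3` of numeric matrices/vectors.
#' @slot labelMap Character vector of taxon ids, one per output class, in
#'   column order (sorted at training time).
#' @slot k k-mer length of the input profiles.
#' @slot normalize Whether input profiles are frequency-normalised.
#' @slot hiddenDims Widths of the two hidden layers.
#' @slot dropout Dropout rate used during training.
#' @slot trainingLog data.frame (epoch, train_loss, val_loss).
#' @slot bestEpoch Epoch whose weights were kept (early stopping).
#' @seealso [trainClassifier()], [classifyReads()]
#' @export
setClass("ClassifierModel",
  representation(weights = "list", labelMap = "character", k = "integer",
                 normalize = "logical", hiddenDims = "integer",
                 dropout = "numeric", trainingLog = "data.frame",
                 bestEpoch = "integer"))

setValidity("ClassifierModel", function(object) {
  w <- object@weights
  need <- c("W1", "b1", "W2", "b2", "W3", "b3")
  if (!all(need %in% names(w))) return("weights must contain W1..b3")
  if (ncol(w$W3) != length(object@labelMap))
    return("output dimension must equal the number of labels")
  if (length(object@labelMap) < 1L) return("label map must be non-empty")
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must be in [0, 1)")
  TRUE
})

#' @describeIn ClassifierModel-class Display a summary.
#' @param object,x A `ClassifierModel`.
#' @export
setMethod("show", "ClassifierModel", function(object) {
  cat("ClassifierModel: ", nrow(object@weights$W1), " -> ",
      paste(object@hiddenDims, collapse = " -> "), " -> ",
      length(object@labelMap), " classes (k = ", object@k,
      ", ", if (object@normalize) "normalized" else "raw", " profiles)\n",
      sep = "")
  if (nrow(object@trainingLog))
    cat("  trained ", nrow(object@trainingLog), " epochs, best epoch ",
        object@bestEpoch, " (val loss ",
        signif(object@trainingLog$val_loss[object@bestEpoch], 5), ")\n",
        sep = "")
})

#' @describeIn ClassifierModel-class k-mer length the model expects.
#' @export
setMethod("kmerSize", "ClassifierModel", function(x) x@k)

#' @describeIn ClassifierModel-class Taxon ids in output-column order.
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' @describeIn ClassifierModel-class Label map accessor.
#' @export
setMethod("labelMap", "ClassifierModel", function(x) x@labelMap)

#' @describeIn ClassifierModel-class Per-epoch training/validation losses.
#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))

#' @describeIn ClassifierModel-class Training log accessor.
#' @export
setMethod("trainingLog", "ClassifierModel", function(x) x@trainingLog)

## Number of canonical k-mers without materialising the index: palindromes
## exist only for even k (4^(k/2) of them).
nCanonicalKmers <- function(k) {
  p <- if (k %% 2 == 0) 4^(k / 2) else 0
  (4^k - p) / 2 + p
}

## He-uniform initialisation for the ReLU stack, seeded.
mlpInit <- function(inputDim, hiddenDims, nClasses, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- c(inputDim, hiddenDims, nClasses)
  w <- list()
  for (l in 1:3) {
    fanIn <- dims[l]
    lim <- sqrt(6 / fanIn)
    w[[paste0("W", l)]] <- matrix(runif(fanIn * dims[l + 1L], -lim, lim),
                                  fanIn, dims[l + 1L])
    w[[paste0("b", l)]] <- numeric(dims[l + 1L])
  }
  w
}

rowSoftmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## Forward pass. In train mode, inverted dropout is applied after each
## hidden ReLU; masks are kept in the cache for backprop.
mlpForward <- function(weights, x, dropout = 0, trainMode = FALSE) {
  a1 <- sweep(x %*% weights$W1, 2L, weights$b1, "+")
  h1 <- pmax(a1, 0)
  m1 <- NULL
  if (trainMode && dropout > 0) {
    keep <- 1 - dropout
    m1 <- matrix((runif(length(h1)) < keep) / keep, nrow(h1), ncol(h1))
    h1 <- h1 * m1
  }
  a2 <- sweep(h1 %*% weights$W2, 2L, weights$b2, "+")
  h2 <- pmax(a2, 0)
  m2 <- NULL
  if (trainMode && dropout > 0) {
    keep <- 1 - dropout
    m2 <- matrix((runif(length(h2)) < keep) / keep, nrow(h2), ncol(h2))
    h2 <- h2 * m2
  }
  a3 <- sweep(h2 %*% weights$W3, 2L, weights$b3, "+")
  probs <- rowSoftmax(a3)
  list(probs = probs,
       cache = list(x = x, a1 = a1, h1 = h1, m1 = m1,
                    a2 = a2, h2 = h2, m2 = m2))
}

## Gradients of the mean cross-entropy w.r.t. all weights, given the
## forward cache and the one-hot targets.
mlpBackward <- function(weights, fwd, yOneHot) {
  n <- nrow(yOneHot)
  cache <- fwd$cache
  dz3 <- (fwd$probs - yOneHot) / n
  g <- list(W3 = crossprod(cache$h2, dz3), b3 = colSums(dz3))
  dh2 <- tcrossprod(dz3, weights$W3)
  if (!is.null(cache$m2)) dh2 <- dh2 * cache$m2
  dz2 <- dh2 * (cache$a2 > 0)
  g$W2 <- crossprod(cache$h1, dz2)
  g$b2 <- colSums(dz2)
  dh1 <- tcrossprod(dz2, weights$W2)
  if (!is.null(cache$m1)) dh1 <- dh1 * cache$m1
  dz1 <- dh1 * (cache$a1 > 0)
  g$W1 <- crossprod(cache$x, dz1)
  g$b1 <- colSums(dz1)
  g
}

#' Cross-entropy loss
#'
#' Mean over examples of the negative log predicted probability of the
#' true class, with the log clamped at `eps` for numerical safety. The
#' per-batch mean (rather than sum) makes the learning rate robust to the
#' batch size.
#'
#' @param y True labels: a one-hot matrix, or a factor/integer vector of
#'   class indices (expanded to one-hot against `ncol(probs)`).
#' @param probs Predicted probability matrix; rows must sum to 1.
#' @param eps Clamp for `log` (default 1e-12).
#' @return Scalar loss.
#' @examples
#' crossEntropy(c(1, 2), rbind(c(0.5, 0.5), c(0.75, 0.25)))  # ~1.0397
#' @export
crossEntropy <- function(y, probs, eps = 1e-12) {
  probs <- as.matrix(probs)
  if (!is.matrix(y)) y <- oneHot(y, ncol(probs))
  if (!all(dim(y) == dim(probs)))
    stop("shape mismatch between labels and predictions")
  -mean(rowSums(y * log(pmax(probs, eps))))
}

oneHot <- function(y, nClasses) {
  y <- as.integer(y)
  if (any(is.na(y)) || any(y < 1L) || any(y > nClasses))
    stop("labels out of range for one-hot encoding")
  m <- matrix(0, length(y), nClasses)
  m[cbind(seq_along(y), y)] <- 1
  m
}

adamStep <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(weights = weights, state = state)
}

#' Train the k-mer profile classifier
#'
#' Mini-batch Adam on the cross-entropy loss with dropout regularisation
#' and early stopping: after each epoch the validation loss is computed in
#' evaluation mode, and training stops once it has failed to improve for
#' `patience` consecutive epochs (or at `maxEpochs`); the weights of the
#' best validation epoch are restored. Fully seeded: initialisation,
#' shuffling and dropout masks all derive from `seed`.
#'
#' @param x Training profile matrix (rows = sequences, columns = canonical
#'   k-mers).
#' @param labels Factor of taxon labels for `x`; its (sorted) levels become
#'   the model's label map.
#' @param xval,valLabels Validation set in the same feature space and with
#'   the same factor levels; drives early stopping.
#' @param k k-mer length of the profiles (stored in the model).
#' @param normalize Normalisation mode of the profiles (stored).
#' @param hiddenDims Two hidden-layer widths. Default `c(1024, 512)` (the
#'   "small" preset); `c(2048, 1024)` is the doubled large preset for
#'   databases with many classes.
#' @param dropout Dropout rate on both hidden layers, in \[0, 1).
#' @param learningRate Adam learning rate.
#' @param batchSize Mini-batch size.
#' @param maxEpochs Epoch cap.
#' @param patience Epochs without validation improvement before stopping.
#' @param seed Integer seed.
#' @return A [ClassifierModel-class] with the training log attached.
#' @export
trainClassifier <- function(x, labels, xval, valLabels, k,
                            normalize = TRUE, hiddenDims = c(1024L, 512L),
                            dropout = 0.3, learningRate = 1e-3,
                            batchSize = 512L, maxEpochs = 100L,
                            patience = 5L, seed = 1L) {
  x <- as.matrix(x); xval <- as.matrix(xval)
  labels <- as.factor(labels); valLabels <- as.factor(valLabels)
  if (!identical(levels(labels), levels(valLabels)))
    stop("train and validation label maps differ")
  lmap <- levels(labels)
  if (length(lmap) < 2L)
    stop("degenerate training set: at least 2 classes required")
  if (length(hiddenDims) != 2L || any(hiddenDims < 1))
    stop("'hiddenDims' must be two positive integers")
  if (dropout < 0 || dropout >= 1) stop("'dropout' must be in [0, 1)")
  stopifnot(batchSize >= 1, patience >= 1, maxEpochs >= 1)
  if (ncol(xval) != ncol(x)) stop("train/validation feature dimension differ")

  set.seed(seed)
  nClasses <- length(lmap)
  weights <- mlpInit(ncol(x), as.integer(hiddenDims), nClasses)
  zeros <- lapply(weights, function(w) w * 0)
  state <- list(m = zeros, v = zeros, t = 0L)
  yIdx <- as.integer(labels)
  yValHot <- oneHot(as.integer(valLabels), nClasses)
  n <- nrow(x)

  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  best <- list(loss = Inf, weights = weights, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(maxEpochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = batchSize)
    epochLoss <- 0
    for (s in starts) {
      rows <- perm[s:min(s + batchSize - 1L, n)]
      xb <- x[rows, , drop = FALSE]
      yb <- oneHot(yIdx[rows], nClasses)
      fwd <- mlpForward(weights, xb, dropout = dropout, trainMode = TRUE)
      loss <- crossEntropy(yb, fwd$probs)
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      epochLoss <- epochLoss + loss * length(rows)
      grads <- mlpBackward(weights, fwd, yb)
      upd <- adamStep(weights, grads, state, lr = learningRate)
      weights <- upd$weights
      state <- upd$state
    }
    valProbs <- mlpForward(weights, xval)$probs
    valLoss <- crossEntropy(yValHot, valProbs)
    if (!is.finite(valLoss))
      stop("training diverged (non-finite validation loss) at epoch ", epoch)
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = epochLoss / n,
                                 val_loss = valLoss))
    if (valLoss < best$loss) {
      best <- list(loss = valLoss, weights = weights, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  new("ClassifierModel", weights = best$weights, labelMap = lmap,
      k = as.integer(k), normalize = isTRUE(normalize),
      hiddenDims = as.integer(hiddenDims), dropout = dropout,
      trainingLog = log, bestEpoch = best$epoch)
}

#' Class probabilities for profile rows
#'
#' Applies the trained network in evaluation mode (no dropout) to a matrix
#' of k-mer profiles.
#'
#' @param model A [ClassifierModel-class].
#' @param x Profile matrix with `nrow(model@weights$W1)` columns.
#' @return Probability matrix (rows sum to 1) with taxon ids as column
#'   names.
#' @export
predictProbs <- function(model, x) {
  stopifnot(is(model, "ClassifierModel"))
  x <- as.matrix(x)
  if (ncol(x) != nrow(model@weights$W1))
    stop("profile dimension (", ncol(x), ") does not match model input (",
         nrow(model@weights$W1), ")")
  p <- mlpForward(model@weights, x)$probs
  colnames(p) <- model@labelMap
  rownames(p) <- rownames(x)
  p
}

#' Numerical gradient verification of the network
#'
#' Compares the analytic gradients of the cross-entropy loss with central
#' finite differences on a small randomly initialised network and batch.
#' A developer/diagnostic utility; the returned maximum relative error
#' should be well below 1e-5.
#'
#' @param inputDim,hiddenDims,nClasses Network shape (keep small).
#' @param n Batch size.
#' @param seed Integer seed.
#' @param eps Finite-difference step.
#' @return Maximum relative error over all parameters, as
#'   `|num - ana| / max(|num|, |ana|, 1e-8)`.
#' @export
gradientCheck <- function(inputDim = 8, hiddenDims = c(4, 3), nClasses = 2,
                          n = 5, seed = 42, eps = 1e-6) {
  set.seed(seed)
  w <- mlpInit(inputDim, hiddenDims, nClasses)
  x <- matrix(runif(n * inputDim), n, inputDim)
  y <- oneHot(sample.int(nClasses, n, replace = TRUE), nClasses)
  fwd <- mlpForward(w, x)
  ana <- mlpBackward(w, fwd, y)
  worst <- 0
  for (nm in names(ana)) {
    wi <- w[[nm]]
    for (j in seq_along(wi)) {
      wp <- w; wp[[nm]][j] <- wp[[nm]][j] + eps
      wm <- w; wm[[nm]][j] <- wm[[nm]][j] - eps
      lp <- crossEntropy(y, mlpForward(wp, x)$probs)
      lm <- crossEntropy(y, mlpForward(wm, x)$probs)
      num <- (lp - lm) / (2 * eps)
      rel <- abs(num - ana[[nm]][j]) / max(abs(num), abs(ana[[nm]][j]), 1e-8)
      worst <- max(worst, rel)
    }
  }
  worst
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint is a directory holding the weight arrays
#' (`weights.rds`), a JSON metadata file (k, normalisation mode, label
#' map, architecture) and the training log as TSV. Loading verifies that
#' the metadata and weights agree and reproduces predictions bit-exactly.
#'
#' @param model A [ClassifierModel-class].
#' @param path Checkpoint directory (created if needed).
#' @return `saveModel` returns `path` invisibly; `loadModel` returns the
#'   restored [ClassifierModel-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "ClassifierModel"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "taxonn-checkpoint-1",
               k = model@k, normalize = model@normalize,
               label_map = model@labelMap,
               input_dim = nrow(model@weights$W1),
               hidden_dims = model@hiddenDims,
               n_classes = length(model@labelMap),
               dropout = model@dropout, best_epoch = model@bestEpoch)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model@weights, file.path(path, "weights.rds"))
  write.table(model@trainingLog, file.path(path, "training_log.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  metaPath <- file.path(path, "metadata.json")
  wPath <- file.path(path, "weights.rds")
  if (!file.exists(metaPath) || !file.exists(wPath))
    stop("corrupt checkpoint: missing metadata.json or weights.rds in ", path)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  need <- c("k", "normalize", "label_map", "input_dim", "hidden_dims",
            "n_classes", "dropout")
  if (!all(need %in% names(meta)) || length(meta$label_map) == 0)
    stop("corrupt checkpoint: incomplete metadata (label map or fields missing)")
  weights <- readRDS(wPath)
  if (nrow(weights$W1) != meta$input_dim ||
      ncol(weights$W3) != meta$n_classes ||
      meta$n_classes != length(meta$label_map))
    stop("corrupt checkpoint: weights do not match metadata dimensions")
  if (meta$input_dim != nCanonicalKmers(meta$k))
    stop("checkpoint mismatch: input dimension ", meta$input_dim,
         " is not the canonical k-mer space size for k = ", meta$k)
  logPath <- file.path(path, "training_log.tsv")
  log <- if (file.exists(logPath)) read.delim(logPath) else
    data.frame(epoch = integer(0), train_loss = numeric(0),
               val_loss = numeric(0))
  new("ClassifierModel", weights = weights,
      labelMap = as.character(meta$label_map), k = as.integer(meta$k),
      normalize = isTRUE(meta$normalize),
      hiddenDims = as.integer(meta$hidden_dims),
      dropout = as.numeric(meta$dropout), trainingLog = log,
      bestEpoch = as.integer(meta$best_epoch %||% 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
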