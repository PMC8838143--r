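#' @include network.R
NULL

#' Inverse-frequency class weights
#'
#' \code{w_k = N_total / (K * n_k)}: the weights average 1 for balanced
#' classes and up-weight minority classes in the weighted cross-entropy.
#'
#' @param trainCounts named integer vector of per-class training counts
#'   (at least two classes, all counts >= 1).
#' @return named numeric weight vector.
#' @export
classWeights <- function(trainCounts) {
  if (length(trainCounts) < 2L) stop("need counts for at least two classes")
  if (any(trainCounts < 1L)) stop("every class needs a positive count")
  n <- sum(trainCounts)
  k <- length(trainCounts)
  setNames(n / (k * as.numeric(trainCounts)), names(trainCounts))
}

#' Weighted cross-entropy loss
#'
#' \deqn{L = -\frac{1}{N} \sum_{i=1}^{N} \sum_{j=1}^{K} w_j T_{ij}
#' \log P_{ij}} with predictions clamped to \code{[1e-12, 1]} before the
#' logarithm. Nonnegative; 0 for perfect one-hot predictions (up to the
#' clamping term) and linear in the class weights.
#'
#' @param probs N x K matrix of predicted probabilities (rows on the simplex).
#' @param targets N x K one-hot matrix.
#' @param weights length-K class weight vector (default all 1).
#' @return nonnegative numeric scalar.
#' @export
weightedCrossEntropy <- function(probs, targets, weights = rep(1, ncol(probs))) {
  if (!all(dim(probs) == dim(targets)))
    stop("probs and targets must have identical dimensions")
  if (length(weights) != ncol(probs))
    stop("weights length must match the number of classes")
  p <- pmin(pmax(probs, 1e-12), 1)
  -sum(targets * log(p) * rep(weights, each = nrow(probs))) / nrow(probs)
}

#' One SGDM parameter update
#'
#' Classical momentum with an L2 term folded into the gradient:
#' \deqn{v' = \gamma v - \alpha (g + \lambda \theta), \qquad
#' \theta' = \theta + v'.} With \eqn{\gamma = 0, \lambda = 0} this reduces to
#' plain gradient descent \eqn{\theta' = \theta - \alpha g}.
#'
#' @param theta parameter array.
#' @param grad gradient array (same shape).
#' @param velocity velocity array (same shape).
#' @param config a \linkS4class{TrainConfig} supplying
#'   \code{learningRate}, \code{momentum}, \code{weightDecay}.
#' @return list with elements \code{theta} and \code{velocity}.
#' @export
sgdmStep <- function(theta, grad, velocity, config = new("TrainConfig")) {
  if (length(theta) != length(grad) || length(theta) != length(velocity))
    stop("theta, grad and velocity must have matching shapes")
  if (any(!is.finite(grad)))
    stop("non-finite gradient: training aborted")
  v <- config@momentum * velocity -
    config@learningRate * (grad + config@weightDecay * theta)
  list(theta = theta + v, velocity = v)
}

#' Early-stopping decision from a validation-loss sequence
#'
#' Given the per-epoch validation losses observed so far, returns the index
#' of the best epoch (first strict minimum; ties do not count as
#' improvement) and whether training should stop because the loss has not
#' improved for \code{patience} consecutive epochs. A network whose
#' validation loss never improves after epoch 1 therefore stops at epoch
#' \code{1 + patience}.
#'
#' @param valLosses numeric vector of validation losses, one per epoch.
#' @param patience integer epochs without improvement tolerated.
#' @return list with \code{bestEpoch} and \code{stop}.
#' @export
earlyStopStatus <- function(valLosses, patience) {
  best <- 1L
  for (e in seq_along(valLosses))
    if (valLosses[e] < valLosses[best] - 1e-12) best <- e
  list(bestEpoch = best, stop = length(valLosses) - best >= patience)
}

one_hot <- function(labels, classes) {
  m <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  m[cbind(seq_along(labels), match(labels, classes))] <- 1
  m
}

#' Train an LCNet model
#'
#' Epoch loop with seeded shuffling and mini-batch SGDM on the weighted
#' cross-entropy. When \code{config@augment} is TRUE the training images are
#' passed through \code{\link{randomAugment}} online, every epoch (records
#' flagged \code{is_duplicate} by \code{\link{oversampleBalance}} exist only
#' through their augmented views). Class weights are the inverse frequencies
#' of \code{trainLabels} over the originals. After each epoch the validation
#' loss and accuracy are measured in inference mode; training stops when the
#' validation loss has not improved for \code{earlyStopPatience} epochs or at
#' \code{maxEpochs}, and the weights of the best epoch are restored.
#'
#' @param model an \linkS4class{LCNetModel} (see \code{\link{buildNetwork}}).
#' @param trainImages named list of 128 x 128 x 3 arrays (0..255), training
#'   split only; validation/test records must never be passed here.
#' @param trainLabels character vector of labels aligned with
#'   \code{trainImages} (or with \code{trainIds} when given).
#' @param valImages,valLabels held-out validation images and labels.
#' @param config a \linkS4class{TrainConfig}.
#' @param trainIds optional data.frame from \code{\link{oversampleBalance}}
#'   (columns id, label, is_duplicate); ids index into \code{trainImages}.
#' @param augmentPolicy an \linkS4class{AugmentPolicy}.
#' @param verbose print one line per epoch.
#' @return list with elements \code{model} (best weights) and
#'   \code{history} (a \linkS4class{TrainHistory}).
#' @export
trainNetwork <- function(model, trainImages, trainLabels,
                         valImages, valLabels,
                         config = new("TrainConfig"),
                         trainIds = NULL,
                         augmentPolicy = new("AugmentPolicy"),
                         verbose = FALSE) {
  stopifnot(is(model, "LCNetModel"), is(config, "TrainConfig"))
  if (!length(trainImages) || !length(valImages))
    stop("training and validation sets must be non-empty")
  classes <- class_names(model@config@nClasses)
  if (is.null(trainIds)) {
    if (is.null(names(trainImages)))
      names(trainImages) <- paste0("img", seq_along(trainImages))
    trainIds <- data.frame(id = names(trainImages),
                           label = trainLabels,
                           is_duplicate = FALSE, stringsAsFactors = FALSE)
  }
  if (length(intersect(trainIds$id, names(valImages))) > 0L)
    stop("train and validation record sets must be disjoint")
  w <- classWeights(table(trainIds$label[!trainIds$is_duplicate]))[classes]
  s <- model@config@inputSize

  xval <- as_input_batch(valImages, model@config)
  tval <- one_hot(valLabels, classes)

  local_rng(config@seed)
  params <- model@params
  vel <- rapply(params, function(a) a * 0, how = "replace")
  n <- nrow(trainIds)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_accuracy = numeric())
  best <- list(loss = Inf, epoch = 0L, params = params)

  for (epoch in seq_len(config@maxEpochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_n <- 0L
    for (start in seq(1L, n, by = config@batchSize)) {
      ix <- ord[start:min(start + config@batchSize - 1L, n)]
      B <- length(ix)
      xb <- array(0, c(s, s, model@config@inputChannels, B))
      for (j in seq_len(B)) {
        im <- trainImages[[trainIds$id[ix[j]]]]
        if (config@augment) im <- randomAugment(im, augmentPolicy)
        xb[, , , j] <- im / 255
      }
      tb <- one_hot(trainIds$label[ix], classes)
      model@params <- params
      fwd <- lcnet_forward(model, xb, training = TRUE, cache = TRUE)
      ep_loss <- ep_loss + B * weightedCrossEntropy(fwd$probs, tb, w)
      ep_n <- ep_n + B
      # d(loss)/d(logits) of softmax + weighted CE
      wrow <- rowSums(tb * rep(w, each = B))
      dlogits <- (fwd$probs - tb) * wrow / B
      grads <- lcnet_backward(model, fwd, dlogits)
      for (id in names(grads)) {
        for (nm in names(grads[[id]])) {
          up <- sgdmStep(params[[id]][[nm]], grads[[id]][[nm]],
                         vel[[id]][[nm]], config)
          params[[id]][[nm]] <- up$theta
          vel[[id]][[nm]] <- up$velocity
        }
      }
      # running BN moments (momentum 0.1), tracked outside the optimizer
      for (id in names(params)) {
        if (!is.null(params[[id]]$rmean)) {
          mom <- get(id, envir = fwd$aux)
          params[[id]]$rmean <- (1 - BN_MOMENTUM) * params[[id]]$rmean +
            BN_MOMENTUM * mom$mean
          params[[id]]$rvar <- (1 - BN_MOMENTUM) * params[[id]]$rvar +
            BN_MOMENTUM * mom$var
        }
      }
    }
    model@params <- params
    vp <- predict_batched(model, xval, config@batchSize)
    val_loss <- weightedCrossEntropy(vp, tval, w)
    val_acc <- mean(classes[max.col(vp, ties.method = "last")] == valLabels)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / ep_n,
                                   val_loss = val_loss,
                                   val_accuracy = val_acc))
    if (verbose)
      message(sprintf("epoch %d: train loss %.4f, val loss %.4f, val acc %.3f",
                      epoch, ep_loss / ep_n, val_loss, val_acc))
    if (val_loss < best$loss - 1e-12)
      best <- list(loss = val_loss, epoch = epoch, params = params)
    es <- earlyStopStatus(hist$val_loss, config@earlyStopPatience)
    if (es$stop) break
  }
  model@params <- best$params
  list(model = model,
       history = new("TrainHistory", epochs = hist,
                     stoppedEpoch = as.integer(max(hist$epoch)),
                     bestEpoch = as.integer(best$epoch)))
}

predict_batched <- function(model, x, batchSize) {
  B <- dim(x)[4]
  out <- matrix(NA_real_, B, model@config@nClasses)
  for (st in seq(1L, B, by = batchSize)) {
    ix <- st:min(st + batchSize - 1L, B)
    out[ix, ] <- lcnet_forward(model, x[, , , ix, drop = FALSE])$probs
  }
  out
}

setMethod("show", "TrainHistory", function(object) {
  cat(sprintf("TrainHistory: %d epoch(s), best epoch %d\n",
              object@stoppedEpoch, object@bestEpoch))
  print(utils::tail(object@epochs, 5))
  invisible(object)
})

#' Write a training history CSV
#'
#' @param history a \linkS4class{TrainHistory}.
#' @param path output CSV path (columns epoch, train_loss, val_loss,
#'   val_accuracy).
#' @return \code{path}, invisibly.
#' @export
writeHistory <- function(history, path) {
  write.csv(history@epochs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
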