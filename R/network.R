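#' @include architecture.R
NULL

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Instantiate an LCNet model
#'
#' Allocates and initializes all learnable parameters of the canonical graph.
#' Convolution and fully connected weights use variance-scaling fan-in normal
#' initialization with the LeakyReLU gain \code{sqrt(2 / (1 + slope^2))};
#' biases start at 0, batch-normalization scales at 1 and offsets at 0.
#' Initialization is deterministic for a fixed seed.
#'
#' @param config an \linkS4class{LCNetConfig}.
#' @param seed integer initialization seed.
#' @return an \linkS4class{LCNetModel}.
#' @export
buildNetwork <- function(config = lcnetConfig(), seed = 1L) {
  stopifnot(is(config, "LCNetConfig"))
  g <- lcnet_graph(config)
  local_rng(seed)
  gain <- sqrt(2 / (1 + config@leakySlope^2))
  params <- list()
  for (n in g$nodes) {
    if (n$op == "conv") {
      fan_in <- n$k * n$k * n$cin
      w <- array(rnorm(n$k * n$k * n$cin * n$cout, sd = gain / sqrt(fan_in)),
                 c(n$k, n$k, n$cin, n$cout))
      params[[n$id]] <- list(w = w, b = numeric(n$cout))
    } else if (n$op == "bn") {
      params[[n$id]] <- list(gamma = rep(1, n$cout), beta = numeric(n$cout),
                             rmean = numeric(n$cout), rvar = rep(1, n$cout))
    } else if (n$op == "fc") {
      w <- matrix(rnorm(n$cin * n$cout, sd = gain / sqrt(n$cin)),
                  n$cin, n$cout)
      params[[n$id]] <- list(w = w, b = numeric(n$cout))
    }
  }
  new("LCNetModel", config = config, graph = g$nodes, params = params,
      seed = as.integer(seed))
}

# Forward pass over a (H, W, C, B) batch.
# Returns logits (B x K) and probs; with cache = TRUE also every activation
# and the batch BN moments needed for backprop.
lcnet_forward <- function(model, x, training = FALSE, cache = FALSE) {
  cfg <- model@config
  d <- dim(x)
  if (length(d) != 4L || d[1] != cfg@inputSize || d[2] != cfg@inputSize ||
      d[3] != cfg@inputChannels)
    stop(sprintf("expected input of spatial size %dx%dx%d, got %s",
                 cfg@inputSize, cfg@inputSize, cfg@inputChannels,
                 paste(d[1:3], collapse = "x")))
  acts <- new.env(parent = emptyenv())
  aux <- new.env(parent = emptyenv())
  assign("in", x, envir = acts)
  for (n in model@graph) {
    if (n$op == "input") next
    inp <- lapply(n$inputs, get, envir = acts)
    y <- switch(n$op,
      conv = {
        p <- model@params[[n$id]]
        cpp_conv_fwd(inp[[1]], p$w, p$b, n$stride, n$pad)
      },
      bn = {
        p <- model@params[[n$id]]
        r <- cpp_bn_fwd(inp[[1]], p$gamma, p$beta, p$rmean, p$rvar,
                        BN_EPS, training)
        if (cache) assign(n$id, list(mean = r$mean, var = r$var), envir = aux)
        r$y
      },
      lrelu = cpp_lrelu_fwd(inp[[1]], cfg@leakySlope),
      maxpool2 = {
        r <- cpp_maxpool2_fwd(inp[[1]])
        if (cache) assign(n$id, r$idx, envir = aux)
        r$y
      },
      avgpool2 = cpp_avgpool2_fwd(inp[[1]]),
      concat = cpp_concat_channels(inp),
      gap = {
        a <- inp[[1]]
        da <- dim(a)
        t(colMeans(matrix(a, da[1] * da[2], da[3] * da[4])) |>
            matrix(da[3], da[4]))      # B x C
      },
      fc = {
        p <- model@params[[n$id]]
        sweep(inp[[1]] %*% p$w, 2L, p$b, "+")
      },
      stop("unknown op ", n$op))
    assign(n$id, y, envir = acts)
  }
  logits <- get("fc", envir = acts)
  probs <- softmax_rows(logits)
  list(logits = logits, probs = probs,
       acts = if (cache) acts, aux = if (cache) aux)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Backward pass: dlogits is B x K; returns named list of gradients per
# parameterized node (conv/fc: w, b; bn: gamma, beta).
lcnet_backward <- function(model, fwd, dlogits) {
  cfg <- model@config
  acts <- fwd$acts
  aux <- fwd$aux
  grads <- list()
  dact <- new.env(parent = emptyenv())
  assign("fc", dlogits, envir = dact)
  push <- function(id, g) {
    if (exists(id, envir = dact, inherits = FALSE))
      assign(id, get(id, envir = dact) + g, envir = dact)
    else assign(id, g, envir = dact)
  }
  for (n in rev(model@graph)) {
    if (n$op == "input") next
    if (!exists(n$id, envir = dact, inherits = FALSE)) next
    dy <- get(n$id, envir = dact)
    switch(n$op,
      conv = {
        p <- model@params[[n$id]]
        x <- get(n$inputs, envir = acts)
        r <- cpp_conv_bwd(x, p$w, dy, n$stride, n$pad)
        grads[[n$id]] <- list(w = r$dw, b = r$db)
        push(n$inputs, r$dx)
      },
      bn = {
        p <- model@params[[n$id]]
        x <- get(n$inputs, envir = acts)
        mom <- get(n$id, envir = aux)
        r <- cpp_bn_bwd(x, p$gamma, mom$mean, mom$var, BN_EPS, dy)
        grads[[n$id]] <- list(gamma = r$dgamma, beta = r$dbeta)
        push(n$inputs, r$dx)
      },
      lrelu = {
        x <- get(n$inputs, envir = acts)
        push(n$inputs, cpp_lrelu_bwd(x, dy, cfg@leakySlope))
      },
      maxpool2 = {
        x <- get(n$inputs, envir = acts)
        push(n$inputs, cpp_maxpool2_bwd(get(n$id, envir = aux), dy, dim(x)))
      },
      avgpool2 = {
        x <- get(n$inputs, envir = acts)
        push(n$inputs, cpp_avgpool2_bwd(dy, dim(x)))
      },
      concat = {
        off <- 0L
        for (src in n$inputs) {
          nc <- dim(get(src, envir = acts))[3]
          push(src, cpp_slice_channels(dy, off, nc))
          off <- off + nc
        }
      },
      gap = {
        x <- get(n$inputs, envir = acts)
        dxa <- dim(x)
        # dy is B x C; spread evenly over H*W
        g <- aperm(array(t(dy) / (dxa[1] * dxa[2]),
                         c(dxa[3], dxa[4], dxa[1], dxa[2])), c(3L, 4L, 1L, 2L))
        push(n$inputs, g)
      },
      fc = {
        p <- model@params[[n$id]]
        x <- get(n$inputs, envir = acts)   # B x Cin
        grads[[n$id]] <- list(w = t(x) %*% dy, b = colSums(dy))
        push(n$inputs, dy %*% t(p$w))
      })
  }
  grads
}

#' Class probabilities for a set of images
#'
#' Runs the network in inference mode (batch normalization uses running
#' moments) over mini-batches.
#'
#' @param model an \linkS4class{LCNetModel}.
#' @param images list of H x W x 3 arrays on the 0..255 scale, or a
#'   (H, W, 3, B) array already scaled to [0, 1].
#' @param batchSize mini-batch size for the forward passes.
#' @return numeric matrix, one row per image, columns \code{MEL}, \code{BEN}
#'   (and further classes if configured); rows sum to 1.
#' @export
predictProb <- function(model, images, batchSize = 32L) {
  x <- as_input_batch(images, model@config)
  B <- dim(x)[4]
  out <- matrix(NA_real_, B, model@config@nClasses)
  for (s in seq(1L, B, by = batchSize)) {
    ix <- s:min(s + batchSize - 1L, B)
    out[ix, ] <- lcnet_forward(model, x[, , , ix, drop = FALSE])$probs
  }
  colnames(out) <- class_names(model@config@nClasses)
  out
}

#' Predicted labels from class probabilities
#'
#' Argmax over the softmax row; exact ties are broken toward \code{BEN}
#' (the conservative call for a melanoma screen is handled upstream by
#' thresholding scores, not by the tie-break).
#'
#' @param probs matrix from \code{\link{predictProb}}.
#' @return character vector of labels.
#' @export
predictLabel <- function(probs) {
  stopifnot(ncol(probs) >= 2L)
  apply(probs, 1L, function(p) {
    if (p[1] > max(p[-1])) colnames(probs)[1] else
      colnames(probs)[-1][which.max(p[-1])]
  })
}

class_names <- function(k) {
  if (k == 2L) LABEL_LEVELS else c(LABEL_LEVELS, paste0("C", 3:k))
}

# Accept a list of 0..255 arrays or a ready (H,W,C,B) [0,1] batch.
as_input_batch <- function(images, config) {
  if (is.array(images) && length(dim(images)) == 4L) return(images)
  stopifnot(is.list(images), length(images) >= 1L)
  s <- config@inputSize
  x <- array(0, c(s, s, config@inputChannels, length(images)))
  for (i in seq_along(images)) {
    im <- images[[i]]
    if (!identical(dim(im)[1:2], c(s, s)))
      stop(sprintf("expected %dx%d images; preprocess first", s, s))
    x[, , , i] <- im / 255
  }
  x
}

setMethod("show", "LCNetModel", function(object) {
  s <- networkStats(object)
  cat(sprintf("LCNetModel (seed %d): %d conv layers, %d kernels, %s parameters\n",
              object@seed, s@nConvLayers, s@nKernels,
              format(s@nLearnableParams, big.mark = ",")))
  invisible(object)
})
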