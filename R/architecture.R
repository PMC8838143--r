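#' @include augment.R
NULL

conv_spec <- function(nKernels, kernelSize, stride = 1L, padding = "same") {
  stopifnot(kernelSize %in% c(1L, 3L), stride %in% c(1L, 2L), nKernels >= 1L)
  list(nKernels = as.integer(nKernels), kernelSize = as.integer(kernelSize),
       stride = as.integer(stride), padding = padding)
}

block_spec <- function(id, convs, pool = "none") {
  list(id = as.integer(id), convs = convs, pool = pool)
}

#' Canonical LCNet configuration
#'
#' Builds the canonical architecture: a stem (8 kernels of 3x3, stride 2,
#' then 2x2 max pooling), a junction concatenating block 1 (16@1x1 then
#' 32@3x3), block 2 (32@3x3) and the pooled stem output, three 1x1 reduction
#' blocks (36, 32, 64 kernels) each followed by 2x2 average pooling, and
#' three groups of two-branch units repeated 2, 4 and 2 times. A unit applies
#' its two blocks in parallel to the same input and concatenates their
#' feature maps: a bottleneck branch (r@1x1 then m@3x3) and a direct branch
#' (m@3x3), with (r, m) = (32, 64), (64, 128), (128, 256) per group. The
#' head is global average pooling over 512 channels into a fully connected
#' softmax layer. Every convolution is followed by batch normalization and
#' LeakyReLU with slope 0.3.
#'
#' @param nClasses integer number of output classes (default 2: MEL, BEN).
#' @return an immutable \linkS4class{LCNetConfig}.
#' @export
lcnetConfig <- function(nClasses = 2L) {
  nClasses <- as.integer(nClasses)
  if (is.na(nClasses) || nClasses < 2L) stop("nClasses must be >= 2")
  blocks <- list(
    block_spec(1L, list(conv_spec(16L, 1L), conv_spec(32L, 3L))),
    block_spec(2L, list(conv_spec(32L, 3L))),
    block_spec(3L, list(conv_spec(36L, 1L)), pool = "avg2x2"),
    block_spec(4L, list(conv_spec(32L, 1L), conv_spec(64L, 3L))),
    block_spec(5L, list(conv_spec(64L, 3L))),
    block_spec(6L, list(conv_spec(32L, 1L)), pool = "avg2x2"),
    block_spec(7L, list(conv_spec(64L, 1L), conv_spec(128L, 3L))),
    block_spec(8L, list(conv_spec(128L, 3L))),
    block_spec(9L, list(conv_spec(64L, 1L)), pool = "avg2x2"),
    block_spec(10L, list(conv_spec(128L, 1L), conv_spec(256L, 3L))),
    block_spec(11L, list(conv_spec(256L, 3L)))
  )
  new("LCNetConfig", inputSize = 128L, inputChannels = 3L,
      nClasses = nClasses, leakySlope = 0.3, repeats = c(2L, 4L, 2L),
      blocks = blocks)
}

#' LeakyReLU activation
#'
#' \code{x} for \code{x >= 0}, \code{slope * x} otherwise; monotone and
#' continuous at 0.
#'
#' @param x numeric vector or array.
#' @param slope negative-branch slope, default 0.3.
#' @return same shape as \code{x}.
#' @export
leakyReLU <- function(x, slope = 0.3) {
  stopifnot(all(is.finite(x)))
  ifelse(x >= 0, x, slope * x)
}

# Ordered computation graph for a config. Nodes are lists with fields
#   id, op (input/conv/bn/lrelu/maxpool2/avgpool2/concat/gap/fc), inputs
#   (character ids), plus op-specific fields (k, stride, pad, cin, cout).
# Spatial sizes and channel widths are tracked at build time so every
# concatenation is checked to join maps of identical spatial size.
lcnet_graph <- function(config) {
  nodes <- list()
  ch <- integer()   # channels per node id
  sp <- integer()   # spatial edge per node id
  add <- function(id, op, inputs, out_channels, out_spatial, ...) {
    nodes[[id]] <<- list(id = id, op = op, inputs = inputs, ...)
    ch[id] <<- as.integer(out_channels)
    sp[id] <<- as.integer(out_spatial)
    id
  }
  # conv + BN + LeakyReLU triple
  cbl <- function(prefix, input, spec) {
    k <- spec$kernelSize
    pad <- if (spec$padding == "same") (k - 1L) %/% 2L else 0L
    s_in <- sp[input]
    s_out <- (s_in + 2L * pad - k) %/% spec$stride + 1L
    cid <- add(paste0(prefix, ".conv"), "conv", input, spec$nKernels, s_out,
               k = k, stride = spec$stride, pad = pad,
               cin = ch[input], cout = spec$nKernels)
    bid <- add(paste0(prefix, ".bn"), "bn", cid, spec$nKernels, s_out,
               cout = spec$nKernels)
    add(paste0(prefix, ".act"), "lrelu", bid, spec$nKernels, s_out)
  }
  run_block <- function(prefix, input, blk) {
    cur <- input
    for (i in seq_along(blk$convs))
      cur <- cbl(sprintf("%s.c%d", prefix, i), cur, blk$convs[[i]])
    if (blk$pool == "avg2x2")
      cur <- add(paste0(prefix, ".pool"), "avgpool2", cur, ch[cur],
                 sp[cur] %/% 2L)
    cur
  }
  concat <- function(id, inputs) {
    if (length(unique(sp[inputs])) != 1L)
      stop("concatenation inputs differ in spatial size")
    add(id, "concat", inputs, sum(ch[inputs]), sp[unique(inputs)][1])
  }
  blk <- function(i) config@blocks[[i]]

  add("in", "input", character(), config@inputChannels, config@inputSize)
  stem <- cbl("stem", "in", conv_spec(8L, 3L, stride = 2L))
  pooled <- add("stem.pool", "maxpool2", stem, ch[stem], sp[stem] %/% 2L)
  b1 <- run_block("b1", pooled, blk(1))
  b2 <- run_block("b2", pooled, blk(2))
  cur <- concat("junction", c(b1, b2, pooled))
  cur <- run_block("b3", cur, blk(3))
  groups <- list(c(4L, 5L), c(7L, 8L), c(10L, 11L))
  reducers <- c(6L, 9L, NA)
  for (g in seq_len(3L)) {
    for (r in seq_len(config@repeats[g])) {
      p <- sprintf("g%d.u%d", g, r)
      br1 <- run_block(paste0(p, ".a"), cur, blk(groups[[g]][1]))
      br2 <- run_block(paste0(p, ".b"), cur, blk(groups[[g]][2]))
      cur <- concat(paste0(p, ".cat"), c(br1, br2))
    }
    if (!is.na(reducers[g]))
      cur <- run_block(sprintf("b%d", reducers[g]), cur, blk(reducers[g]))
  }
  cur <- add("gap", "gap", cur, ch[cur], 1L)
  add("fc", "fc", cur, config@nClasses, 1L,
      cin = unname(ch[cur]), cout = config@nClasses)
  list(nodes = nodes, channels = ch, spatial = sp)
}

#' @rdname networkStats
#' @export
setMethod("networkStats", "LCNetConfig", function(x) {
  g <- lcnet_graph(x)
  convs <- Filter(function(n) n$op == "conv", g$nodes)
  n_conv <- length(convs)
  n_kern <- sum(vapply(convs, function(n) n$cout, integer(1)))
  conv_par <- sum(vapply(convs, function(n)
    n$k * n$k * n$cin * n$cout + n$cout, numeric(1)))
  bn_par <- 2 * n_kern
  fc <- g$nodes[["fc"]]
  fc_par <- fc$cin * fc$cout + fc$cout
  new("NetworkStats", nConvLayers = n_conv, nKernels = as.integer(n_kern),
      nLearnableParams = as.numeric(unname(conv_par + bn_par + fc_par)))
})

#' @rdname networkStats
#' @export
setMethod("networkStats", "LCNetModel", function(x) networkStats(x@config))

setMethod("show", "NetworkStats", function(object) {
  cat(sprintf("NetworkStats: %d conv layers, %d kernels, %s learnable parameters\n",
              object@nConvLayers, object@nKernels,
              format(object@nLearnableParams, big.mark = ",")))
  invisible(object)
})

setMethod("show", "LCNetConfig", function(object) {
  s <- networkStats(object)
  cat(sprintf(paste0("LCNetConfig: %dx%dx%d input, %d classes, ",
                     "11 blocks with repeats (%s)\n"),
              object@inputSize, object@inputSize, object@inputChannels,
              object@nClasses, paste(object@repeats, collapse = ", ")))
  cat(sprintf("  %d conv layers, %d kernels, %s parameters\n",
              s@nConvLayers, s@nKernels,
              format(s@nLearnableParams, big.mark = ",")))
  invisible(object)
})
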