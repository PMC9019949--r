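#' Network architecture configuration
#'
#' Hyperparameters of the quality-regression network: four convolutional
#' blocks (2D convolution, batch normalization, leaky rectifier), the first
#' two carrying squeeze-and-excitation (SE) channel attention, a global max
#' pool over each of the final channels, and four dense blocks reducing the
#' pooled feature vector to the single predicted GDT-TS score. The final
#' activation is a plain rectifier (predictions are non-negative); every
#' other non-SE activation is the leaky rectifier.
#'
#' @param conv_channels output channels of the four conv blocks; the last one
#'   (default 256) must equal `dense_sizes[1]`.
#' @param kernel_size odd convolution kernel size (stride 1, zero padding
#'   preserving H x W).
#' @param se_ratio squeeze-and-excitation bottleneck ratio (default 16); must
#'   divide the channel count of every block listed in `se_block_positions`.
#' @param se_block_positions conv blocks carrying an SE block (default the
#'   first two), applied after the block's activation.
#' @param dense_sizes widths of the four dense blocks, ending in 1.
#' @param negative_slope leaky-rectifier slope for negative inputs.
#' @param pool_positions conv blocks whose activation is followed by a 2x2
#'   (ceil mode) max pool. Downsampling keeps CPU training tractable; set to
#'   `integer(0)` for a fully resolution-preserving network. The global max
#'   pool makes the output shape independent of this choice. In a block that
#'   has both, the SE gate acts on the pooled features (per-channel positive
#'   gains commute with max pooling).
#' @param bn_eps,bn_momentum batch-normalization stabilizer and running-moment
#'   update rate.
#' @param seed integer seed for kaiming weight initialization.
#' @return a validated list of class `dmqa_network_config`.
#' @export
network_config <- function(conv_channels = c(32L, 64L, 128L, 256L),
                           kernel_size = 3L,
                           se_ratio = 16L,
                           se_block_positions = c(1L, 2L),
                           dense_sizes = c(256L, 64L, 16L, 1L),
                           negative_slope = 0.01,
                           pool_positions = c(1L, 2L, 3L),
                           bn_eps = 1e-5,
                           bn_momentum = 0.1,
                           seed = 1L) {
  cfg <- list(conv_channels = as.integer(conv_channels),
              kernel_size = as.integer(kernel_size),
              se_ratio = as.integer(se_ratio),
              se_block_positions = as.integer(se_block_positions),
              dense_sizes = as.integer(dense_sizes),
              negative_slope = negative_slope,
              pool_positions = as.integer(pool_positions),
              bn_eps = bn_eps, bn_momentum = bn_momentum,
              seed = as.integer(seed))
  if (length(cfg$conv_channels) != 4 || any(cfg$conv_channels < 1))
    stop("conv_channels must be 4 positive channel counts")
  if (length(cfg$dense_sizes) != 4 || cfg$dense_sizes[4] != 1)
    stop("dense_sizes must be 4 widths ending in 1")
  if (cfg$dense_sizes[1] != cfg$conv_channels[4])
    stop("dense_sizes[1] must equal the last conv channel count")
  if (cfg$kernel_size < 1 || cfg$kernel_size %% 2 == 0)
    stop("kernel_size must be a positive odd integer")
  if (!all(cfg$se_block_positions %in% 1:4))
    stop("se_block_positions must be within 1..4")
  if (!all(cfg$pool_positions %in% 1:4))
    stop("pool_positions must be within 1..4")
  if (cfg$se_ratio < 1)
    stop("se_ratio must be a positive integer")
  bad <- cfg$se_block_positions[
    cfg$conv_channels[cfg$se_block_positions] %% cfg$se_ratio != 0]
  if (length(bad) > 0)
    stop(sprintf(
      "config error: se_ratio %d does not divide the channel count of block %s",
      cfg$se_ratio, paste(bad, collapse = ", ")))
  if (negative_slope < 0 || negative_slope >= 1)
    stop("negative_slope must be in [0, 1)")
  class(cfg) <- "dmqa_network_config"
  cfg
}

lrelu <- function(x, a) {
  neg <- x < 0
  x[neg] <- a * x[neg]
  x
}

# gradient of the leaky rectifier w.r.t. its pre-activation z (slope 1 at 0)
lrelu_bwd <- function(z, dy, a) {
  neg <- z < 0
  dy[neg] <- a * dy[neg]
  dy
}

kaiming <- function(nout, nin, fan_in, gain) {
  matrix(stats::rnorm(nout * nin, sd = gain / sqrt(fan_in)), nout, nin)
}

#' Build the quality-regression network
#'
#' Allocates all weights under kaiming initialization with the config seed.
#' Convolution weights are stored as `(C_out, k*k*C_in)` matrices matching
#' the internal im2col layout; batch-normalization running moments start at
#' mean 0, variance 1.
#'
#' @param config a [network_config()].
#' @return an object of class `dmqa_net` with elements `config`, `params`
#'   (named list of weight arrays) and `buffers` (running BN moments).
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "dmqa_network_config"))
  gain <- sqrt(2 / (1 + config$negative_slope^2))
  k <- config$kernel_size
  params <- list()
  buffers <- list()
  with_seed(config$seed, {
    cin <- 1L
    for (i in 1:4) {
      cout <- config$conv_channels[i]
      K <- k * k * cin
      params[[paste0("conv", i, ".w")]] <- kaiming(cout, K, K, gain)
      params[[paste0("conv", i, ".b")]] <- numeric(cout)
      params[[paste0("bn", i, ".gamma")]] <- rep(1, cout)
      params[[paste0("bn", i, ".beta")]] <- numeric(cout)
      buffers[[paste0("bn", i, ".rmean")]] <- numeric(cout)
      buffers[[paste0("bn", i, ".rvar")]] <- rep(1, cout)
      if (i %in% config$se_block_positions) {
        cmid <- cout %/% config$se_ratio
        params[[paste0("se", i, ".w1")]] <- kaiming(cmid, cout, cout, gain)
        params[[paste0("se", i, ".b1")]] <- numeric(cmid)
        params[[paste0("se", i, ".w2")]] <- kaiming(cout, cmid, cmid, 1)
        params[[paste0("se", i, ".b2")]] <- numeric(cout)
      }
      cin <- cout
    }
    # dense block j maps ins[j] -> dense_sizes[j]; the configured widths are
    # per-block output sizes, so c(256, 64, 16, 1) gives 256->256->64->16->1
    ins <- c(config$conv_channels[4], config$dense_sizes[-4])
    for (j in 1:4) {
      g <- if (j == 4) sqrt(2) else gain
      params[[paste0("dense", j, ".w")]] <-
        kaiming(config$dense_sizes[j], ins[j], ins[j], g)
      params[[paste0("dense", j, ".b")]] <- numeric(config$dense_sizes[j])
    }
    # start the output inside the score range: a rectified scalar head whose
    # pre-activation is negative for every input has zero gradient and never
    # recovers, so the final bias starts at the GDT-TS midpoint
    params[["dense4.b"]][] <- 0.5
  })
  structure(list(config = config, params = params, buffers = buffers),
            class = "dmqa_net")
}

#' @export
print.dmqa_net <- function(x, ...) {
  cat(sprintf(
    "<dmqa network> conv %s (SE at %s, pool after %s), dense %s, %d parameters\n",
    paste(x$config$conv_channels, collapse = "-"),
    paste(x$config$se_block_positions, collapse = ","),
    paste(x$config$pool_positions, collapse = ","),
    paste(x$config$dense_sizes, collapse = "-"),
    count_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param net a `dmqa_net`.
#' @return integer parameter count (independent of input size L).
#' @export
count_params <- function(net) {
  sum(vapply(net$params, length, numeric(1)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass. x is a (L*L, 1, b) array of difference maps. Returns
# list(out = 1 x b predictions, cache for backward when keep_cache,
# buffers = updated running BN moments when training).
nn_forward <- function(net, x, training = FALSE, se_override = NULL,
                       keep_cache = FALSE) {
  cfg <- net$config
  p <- net$params
  buf <- net$buffers
  stopifnot(is.array(x), length(dim(x)) == 3, dim(x)[2] == 1)
  H <- as.integer(round(sqrt(dim(x)[1])))
  if (H * H != dim(x)[1]) stop("input maps must be square")
  slope <- cfg$negative_slope
  h <- x
  blocks <- vector("list", 4)
  for (i in 1:4) {
    blk <- list(H = H, x_in = if (keep_cache) h else NULL)
    z <- cpp_conv_fwd(h, H, H, p[[paste0("conv", i, ".w")]],
                      p[[paste0("conv", i, ".b")]], cfg$kernel_size)
    if (!keep_cache) h <- NULL
    bn <- cpp_bn_act_fwd(z, p[[paste0("bn", i, ".gamma")]],
                         p[[paste0("bn", i, ".beta")]],
                         buf[[paste0("bn", i, ".rmean")]],
                         buf[[paste0("bn", i, ".rvar")]],
                         cfg$bn_eps, cfg$bn_momentum, slope, training)
    if (training) {
      buf[[paste0("bn", i, ".rmean")]] <- as.numeric(bn$rmean)
      buf[[paste0("bn", i, ".rvar")]] <- as.numeric(bn$rvar)
    }
    y <- bn$y
    if (keep_cache) {
      blk$z <- z
      blk$mu <- as.numeric(bn$mu)
      blk$invsd <- as.numeric(bn$invsd)
    }
    # pooling precedes the SE gate: the per-channel excitation weights are
    # positive scalars, which commute with max pooling, so gating the pooled
    # features computes the same composition at a quarter of the cost
    if (i %in% cfg$pool_positions && H > 1) {
      mp <- cpp_maxpool_fwd(y, H, H)
      if (keep_cache) {
        blk$pool_idx <- mp$idx
        blk$pool_P <- dim(y)[1]
      }
      blk$pooled <- TRUE
      y <- mp$y
      H <- (H + 1L) %/% 2L
    } else blk$pooled <- FALSE
    if (i %in% cfg$se_block_positions) {
      P <- dim(y)[1]; C <- dim(y)[2]; b <- dim(y)[3]
      sq <- colMeans(matrix(y, P, C * b))
      dim(sq) <- c(C, b)
      z1 <- p[[paste0("se", i, ".w1")]] %*% sq + p[[paste0("se", i, ".b1")]]
      h1 <- lrelu(z1, slope)
      z2 <- p[[paste0("se", i, ".w2")]] %*% h1 + p[[paste0("se", i, ".b2")]]
      e <- sigmoid(z2)
      if (!is.null(se_override)) e[] <- se_override
      if (keep_cache) blk$se <- list(x = y, sq = sq, z1 = z1, h1 = h1, e = e)
      y <- cpp_scale_channels_fwd(y, e)
    }
    blocks[[i]] <- blk
    h <- y
  }
  gp <- cpp_gmaxpool_fwd(h)
  f <- gp$y  # C x b
  dense <- vector("list", 4)
  for (j in 1:4) {
    zd <- p[[paste0("dense", j, ".w")]] %*% f + p[[paste0("dense", j, ".b")]]
    if (keep_cache) dense[[j]] <- list(x = f, z = zd)
    f <- if (j < 4) lrelu(zd, slope) else pmax(zd, 0)
  }
  cache <- if (keep_cache)
    list(blocks = blocks, g_idx = gp$idx, g_P = dim(h)[1], dense = dense)
  else NULL
  list(out = f, cache = cache, buffers = if (training) buf else net$buffers)
}

# Backward pass; dout is the 1 x b loss gradient at the output. Returns the
# named gradient list aligned with net$params. With se_override set, the
# excitation path is constant, so its parameter gradients are zero.
nn_backward <- function(net, cache, dout, se_override = NULL) {
  cfg <- net$config
  p <- net$params
  slope <- cfg$negative_slope
  grads <- lapply(p, function(w) {
    g <- w
    g[] <- 0
    g
  })
  f <- dout
  for (j in 4:1) {
    dj <- cache$dense[[j]]
    dz <- if (j == 4) f * (dj$z > 0) else lrelu_bwd(dj$z, f, slope)
    grads[[paste0("dense", j, ".w")]] <- dz %*% t(dj$x)
    grads[[paste0("dense", j, ".b")]] <- rowSums(dz)
    f <- t(p[[paste0("dense", j, ".w")]]) %*% dz
  }
  dh <- cpp_gmaxpool_bwd(cache$g_idx, cache$g_P, f)
  for (i in 4:1) {
    blk <- cache$blocks[[i]]
    if (i %in% cfg$se_block_positions) {
      sc <- blk$se
      sb <- cpp_scale_channels_bwd(sc$x, sc$e, dh)
      dx <- sb$dx
      if (is.null(se_override)) {
        ds <- sb$ds
        dz2 <- ds * sc$e * (1 - sc$e)
        grads[[paste0("se", i, ".w2")]] <- dz2 %*% t(sc$h1)
        grads[[paste0("se", i, ".b2")]] <- rowSums(dz2)
        dh1 <- t(p[[paste0("se", i, ".w2")]]) %*% dz2
        dz1 <- lrelu_bwd(sc$z1, dh1, slope)
        grads[[paste0("se", i, ".w1")]] <- dz1 %*% t(sc$sq)
        grads[[paste0("se", i, ".b1")]] <- rowSums(dz1)
        dsq <- t(p[[paste0("se", i, ".w1")]]) %*% dz1  # C x b
        P <- dim(sc$x)[1]
        dx <- dx + array(rep(as.vector(dsq) / P, each = P), dim = dim(dx))
      }
      dh <- dx
    }
    if (blk$pooled) dh <- cpp_maxpool_bwd(blk$pool_idx, blk$pool_P, dh)
    bb <- cpp_bn_act_bwd(blk$z, p[[paste0("bn", i, ".gamma")]],
                         p[[paste0("bn", i, ".beta")]],
                         blk$mu, blk$invsd, slope, dh)
    grads[[paste0("bn", i, ".gamma")]] <- as.numeric(bb$dgamma)
    grads[[paste0("bn", i, ".beta")]] <- as.numeric(bb$dbeta)
    cb <- cpp_conv_bwd(blk$x_in, blk$H, blk$H, p[[paste0("conv", i, ".w")]],
                       cfg$kernel_size, bb$dx)
    grads[[paste0("conv", i, ".w")]] <- cb$dw
    grads[[paste0("conv", i, ".b")]] <- as.numeric(cb$db)
    dh <- cb$dx
  }
  grads
}

# assemble a (L*L, 1, n) input tensor from records of one common length
records_tensor <- function(records) {
  L <- records[[1]]$length
  n <- length(records)
  x <- array(0, dim = c(L * L, 1L, n))
  for (i in seq_len(n)) {
    if (records[[i]]$length != L)
      stop("all records in a batch must share the same length L")
    x[, 1L, i] <- as.vector(records[[i]]$diff$values)
  }
  x
}

#' Apply the SE-clamped or plain forward pass of a network
#'
#' Evaluation-mode forward pass on a batch of difference maps.
#'
#' @param net a `dmqa_net`.
#' @param x `(L*L, 1, b)` array, or an L x L matrix for a single map.
#' @param se_override optional constant forced onto every SE excitation
#'   weight (1 disables the gating, 0 zeroes the gated channels); `NULL`
#'   (default) uses the learned attention.
#' @return numeric vector of b non-negative predicted scores.
#' @export
forward_scores <- function(net, x, se_override = NULL) {
  if (is.matrix(x)) x <- array(x, dim = c(length(x), 1L, 1L))
  as.numeric(nn_forward(net, x, training = FALSE,
                        se_override = se_override)$out)
}

#' Remove the SE blocks from a network
#'
#' Returns the no-attention variant sharing all convolutional, normalization
#' and dense weights — the ablation comparator: with excitation clamped to 1
#' the SE network computes exactly this network's function.
#'
#' @param net a `dmqa_net`.
#' @return a `dmqa_net` without SE blocks.
#' @export
strip_se_blocks <- function(net) {
  cfg <- net$config
  drop <- grep("^se[0-9]+\\.", names(net$params))
  if (length(drop) > 0) net$params <- net$params[-drop]
  net$config$se_block_positions <- integer(0)
  net
}

#' Predict model quality for a set of featurized records
#'
#' Batched inference: records are grouped by length internally (results are
#' independent of the grouping) and returned in input order.
#'
#' @param net a trained (or initialized) `dmqa_net`.
#' @param records non-empty list of [model_record()] objects.
#' @param batch_size maximum inference batch size.
#' @param clamp if `TRUE`, clip predictions into \[0,1\] for reporting. Off by
#'   default: the final rectifier only guarantees non-negativity and ranking
#'   is unaffected by the clamp.
#' @return `data.frame` with columns `target_id`, `model_id`,
#'   `predicted_gdtts`, one row per record, in input order.
#' @export
predict_quality <- function(net, records, batch_size = 16L, clamp = FALSE) {
  stopifnot(inherits(net, "dmqa_net"), length(records) > 0)
  lens <- vapply(records, `[[`, numeric(1), "length")
  pred <- numeric(length(records))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    for (start in seq(1, length(idx), by = batch_size)) {
      chunk <- idx[start:min(start + batch_size - 1, length(idx))]
      x <- records_tensor(records[chunk])
      pred[chunk] <- as.numeric(nn_forward(net, x, training = FALSE)$out)
    }
  }
  if (clamp) pred <- pmin(pmax(pred, 0), 1)
  data.frame(
    target_id = vapply(records, `[[`, character(1), "target_id"),
    model_id = vapply(records, `[[`, character(1), "model_id"),
    predicted_gdtts = pred,
    stringsAsFactors = FALSE)
}

#' Save / load a self-describing network checkpoint
#'
#' The checkpoint carries the weights, the full [network_config()], and the
#' featurization convention (threshold and representative atom) so that
#' inference can refuse feature stores built under a different convention.
#'
#' @param net a `dmqa_net`.
#' @param path checkpoint file (`.rds`).
#' @param threshold,atom featurization convention the network was trained on.
#' @param history optional training history `data.frame`.
#' @return `path` (save) or the restored object (load).
#' @export
save_checkpoint <- function(net, path, threshold = 16, atom = "cb",
                            history = NULL) {
  saveRDS(list(params = net$params, buffers = net$buffers,
               config = net$config, threshold = threshold, atom = atom,
               history = history, version = 1L), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint not found: '%s'", path))
  ck <- readRDS(path)
  if (is.null(ck$params) || is.null(ck$config))
    stop(sprintf("'%s' is not a dmqa checkpoint", path))
  net <- structure(list(config = ck$config, params = ck$params,
                        buffers = ck$buffers), class = "dmqa_net")
  list(net = net, threshold = ck$threshold, atom = ck$atom,
       history = ck$history)
}
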