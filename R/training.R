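#' Smooth L1 loss and its derivative
#'
#' The regression loss on the residual `x = predicted - true GDT-TS`:
#' `0.5 * x^2` for `|x| < 1` and `|x| - 0.5` otherwise. It behaves like a
#' squared loss near zero (differentiable at 0) and like an absolute loss in
#' the tails, so it is less sensitive to outliers; both branches meet at
#' `|x| = 1` with value 0.5. The derivative is `x` on `(-1, 1)` and the
#' constant -1 / +1 for `x <= -1` / `x >= 1` (the closed-interval convention
#' at the boundary, where the two branches agree in value).
#'
#' @param x numeric vector of residuals (must be finite).
#' @return `smooth_l1`: loss values; `smooth_l1_derivative`: gradients.
#' @export
smooth_l1 <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("domain error: smooth_l1 requires finite numeric residuals")
  ax <- abs(x)
  ifelse(ax < 1, 0.5 * x^2, ax - 0.5)
}

#' @rdname smooth_l1
#' @export
smooth_l1_derivative <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("domain error: smooth_l1_derivative requires finite numeric residuals")
  pmax(pmin(x, 1), -1)
}

#' Training configuration
#'
#' @param learning_rate constant Adam learning rate (default 5e-5).
#' @param adam_beta1,adam_beta2 Adam moment decay rates (0.9, 0.999).
#' @param batch_size records per length-homogeneous batch (default 16).
#' @param epochs number of training epochs.
#' @param split_fraction per-batch share assigned to training (default 0.8).
#' @param seed integer seed governing batching, splitting and batch-order
#'   reshuffling.
#' @param keep_best if `TRUE` (default) the returned network carries the
#'   parameters of the epoch with the lowest validation loss.
#' @return validated list of class `dmqa_train_config`.
#' @export
train_config <- function(learning_rate = 5e-5, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, batch_size = 16L,
                         epochs = 60L, split_fraction = 0.8, seed = 1L,
                         keep_best = TRUE) {
  cfg <- list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
              adam_beta2 = adam_beta2, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), split_fraction = split_fraction,
              seed = as.integer(seed), keep_best = isTRUE(keep_best))
  if (!is_number(learning_rate) || learning_rate < 0)
    stop("learning_rate must be a non-negative number")
  if (cfg$batch_size < 1) stop("batch_size must be >= 1")
  if (cfg$epochs < 0) stop("epochs must be >= 0")
  if (!is_number(split_fraction) || split_fraction <= 0 ||
      split_fraction >= 1)
    stop("split_fraction must lie strictly between 0 and 1")
  class(cfg) <- "dmqa_train_config"
  cfg
}

#' Group records into length-homogeneous batches
#'
#' Every batch contains records of exactly one sequence length L (so maps can
#' be stacked into one tensor), holds at most `batch_size` records, and every
#' record appears exactly once. Order within lengths and among batches is a
#' deterministic function of `seed`.
#'
#' @param records list of [model_record()] objects.
#' @param batch_size maximum batch size b.
#' @param seed integer seed.
#' @return list of batches, each a list of records; empty input gives an
#'   empty list.
#' @export
make_length_batches <- function(records, batch_size = 16L, seed = 1L) {
  stopifnot(batch_size >= 1)
  if (length(records) == 0) return(list())
  lens <- vapply(records, `[[`, numeric(1), "length")
  batches <- list()
  with_seed(seed, {
    for (L in sort(unique(lens))) {
      idx <- which(lens == L)
      idx <- idx[sample.int(length(idx))]
      starts <- seq(1, length(idx), by = batch_size)
      for (s in starts) {
        chunk <- idx[s:min(s + batch_size - 1, length(idx))]
        batches[[length(batches) + 1L]] <- records[chunk]
      }
    }
    batches <- batches[sample.int(length(batches))]
  })
  batches
}

#' Split batches into training and validation records
#'
#' From each batch, `round(split_fraction * size)` records (at least 1 when
#' the batch has >= 2 records) are drawn at random into the training set and
#' the rest into validation; a single-record batch goes to training. The
#' union of the two sets is exactly the input multiset.
#'
#' @param batches list of batches from [make_length_batches()].
#' @param split_fraction training share per batch (default 0.8).
#' @param seed integer seed.
#' @return `list(train = ..., validation = ...)` of record lists.
#' @export
split_batches <- function(batches, split_fraction = 0.8, seed = 1L) {
  stopifnot(split_fraction > 0, split_fraction < 1)
  train <- list()
  val <- list()
  with_seed(seed, {
    for (batch in batches) {
      n <- length(batch)
      if (n == 1) {
        train <- c(train, batch)
        next
      }
      k <- max(1L, min(n, round(split_fraction * n)))
      take <- sample.int(n, k)
      train <- c(train, batch[take])
      val <- c(val, batch[-take])
    }
  })
  list(train = train, validation = val)
}

adam_init <- function(params) {
  list(m = lapply(params, function(w) { w[] <- 0; w }),
       v = lapply(params, function(w) { w[] <- 0; w }),
       t = 0L)
}

adam_step <- function(opt, params, grads, lr, beta1, beta2, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(opt = opt, params = params)
}

batch_labels <- function(batch) {
  y <- vapply(batch, `[[`, numeric(1), "true_gdtts")
  if (anyNA(y)) {
    bad <- batch[[which(is.na(y))[1]]]
    stop(sprintf("record %s/%s has no true GDT-TS label",
                 bad$target_id, bad$model_id))
  }
  y
}

# mean smooth-L1 loss of a record set under the current network (eval mode)
eval_loss <- function(net, records, batch_size = 16L) {
  if (length(records) == 0) return(NA_real_)
  preds <- predict_quality(net, records, batch_size = batch_size)
  y <- batch_labels(records)
  mean(smooth_l1(preds$predicted_gdtts - y))
}

#' Train the network
#'
#' Minimizes the mean smooth L1 loss over length-homogeneous batches with
#' Adam (constant learning rate). Batch order (not batch contents) is
#' reshuffled every epoch under the seed. The history records, per epoch, the
#' mean training loss over the optimization batches and the evaluation-mode
#' validation loss; row `epoch = 0` holds the pre-training evaluation-mode
#' losses. With `keep_best` the returned network carries the parameters of
#' the epoch with the lowest validation loss.
#'
#' @param net a `dmqa_net` from [build_network()].
#' @param train_records non-empty list of labeled [model_record()]s.
#' @param val_records validation records; may be empty (a warning is logged
#'   and the history carries training loss only).
#' @param config a [train_config()].
#' @param verbose log per-epoch losses.
#' @return `list(net = trained network, history = data.frame(epoch,
#'   train_loss, val_loss))`.
#' @export
train_network <- function(net, train_records, val_records = list(),
                          config = train_config(), verbose = FALSE) {
  stopifnot(inherits(net, "dmqa_net"), inherits(config, "dmqa_train_config"))
  if (length(train_records) == 0) stop("training set is empty")
  has_val <- length(val_records) > 0
  if (!has_val)
    dmqa_log("validation set empty; history carries train loss only",
             level = "WARN", verbose = verbose)
  batches <- make_length_batches(train_records, config$batch_size,
                                 seed = config$seed)
  opt <- adam_init(net$params)
  history <- data.frame(epoch = 0L,
                        train_loss = eval_loss(net, train_records,
                                               config$batch_size),
                        val_loss = if (has_val)
                          eval_loss(net, val_records, config$batch_size)
                        else NA_real_)
  best <- list(val = history$val_loss[1], params = net$params,
               buffers = net$buffers, epoch = 0L)
  n_train <- length(train_records)
  # batch contents are fixed across epochs; build each input tensor once
  tensors <- lapply(batches, records_tensor)
  labels <- lapply(batches, batch_labels)
  # dead-head safeguard: a rectified scalar output that is zero for every
  # training input has zero gradient everywhere and can never recover.
  # Before optimizing, raise the output bias (deterministically) until at
  # least one training-mode prediction is positive.
  for (attempt in seq_len(40)) {
    alive <- FALSE
    for (x in tensors) {
      if (any(nn_forward(net, x, training = TRUE)$out > 0)) {
        alive <- TRUE
        break
      }
    }
    if (alive) break
    net$params[["dense4.b"]] <- net$params[["dense4.b"]] + 0.5
    dmqa_log(sprintf(
      "output head dead at initialization; output bias raised to %.2f",
      net$params[["dense4.b"]][1]), level = "WARN", verbose = verbose)
  }
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(config$seed + epoch, sample.int(length(batches)))
    tot <- 0
    for (bi in ord) {
      nb <- length(batches[[bi]])
      x <- tensors[[bi]]
      y <- labels[[bi]]
      fw <- nn_forward(net, x, training = TRUE, keep_cache = TRUE)
      net$buffers <- fw$buffers
      res <- as.numeric(fw$out) - y
      tot <- tot + sum(smooth_l1(res))
      dout <- matrix(smooth_l1_derivative(res) / nb, nrow = 1)
      grads <- nn_backward(net, fw$cache, dout)
      upd <- adam_step(opt, net$params, grads, config$learning_rate,
                       config$adam_beta1, config$adam_beta2)
      opt <- upd$opt
      net$params <- upd$params
    }
    vl <- if (has_val) eval_loss(net, val_records, config$batch_size)
          else NA_real_
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = tot / n_train,
                                         val_loss = vl))
    if (has_val && !is.na(vl) && (is.na(best$val) || vl < best$val)) {
      best <- list(val = vl, params = net$params, buffers = net$buffers,
                   epoch = epoch)
    }
    if (verbose)
      dmqa_log(sprintf("epoch %d: train %.5f val %s", epoch, tot / n_train,
                       ifelse(is.na(vl), "NA", sprintf("%.5f", vl))),
               verbose = TRUE)
  }
  if (config$keep_best && has_val && !is.na(best$val)) {
    net$params <- best$params
    net$buffers <- best$buffers
    attr(net, "best_epoch") <- best$epoch
  }
  list(net = net, history = history)
}
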