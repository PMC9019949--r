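test_that("smooth L1 loss matches its closed form and bounds", {
  expect_identical(smooth_l1(0), 0)
  expect_identical(smooth_l1(0.5), 0.125)
  expect_identical(smooth_l1(-3), 2.5)
  # continuity at the branch point: both branches give 0.5
  expect_identical(smooth_l1(1), 0.5)
  expect_identical(smooth_l1(-1), 0.5)
  expect_equal(smooth_l1(1 - 1e-12), 0.5, tolerance = 1e-9)

  x <- seq(-6, 6, length.out = 2001)
  l <- smooth_l1(x)
  expect_true(all(l <= abs(x) + 1e-15))
  inner <- abs(x) < 1
  expect_identical(l[inner], 0.5 * x[inner]^2)
  expect_identical(l[!inner], abs(x[!inner]) - 0.5)

  expect_error(smooth_l1(Inf), "domain")
  expect_error(smooth_l1(NA_real_), "domain")
})

test_that("smooth L1 derivative follows the piecewise form", {
  expect_identical(smooth_l1_derivative(0.3), 0.3)
  expect_identical(smooth_l1_derivative(7), 1)
  expect_identical(smooth_l1_derivative(-2), -1)
  # closed-interval convention at the boundary
  expect_identical(smooth_l1_derivative(1), 1)
  expect_identical(smooth_l1_derivative(-1), -1)

  # central finite differences at +-0.5 and +-2
  h <- 1e-6
  for (x0 in c(-2, -0.5, 0.5, 2)) {
    num <- (smooth_l1(x0 + h) - smooth_l1(x0 - h)) / (2 * h)
    expect_equal(smooth_l1_derivative(x0), num, tolerance = 1e-6)
  }
  expect_error(smooth_l1_derivative(NaN), "domain")
})

test_that("length batching partitions records into same-L batches", {
  recs <- c(random_records(35, lengths = 50, seed = 1),
            random_records(10, lengths = 80, seed = 2))
  # fix ids to be unique across the two draws
  for (i in seq_along(recs)) recs[[i]]$model_id <- sprintf("u%03d", i)
  batches <- make_length_batches(recs, batch_size = 16, seed = 3)
  sizes <- vapply(batches, length, numeric(1))
  ls <- vapply(batches, function(b) b[[1]]$length, numeric(1))
  expect_identical(sort(sizes[ls == 50]), c(3, 16, 16))
  expect_identical(sizes[ls == 80], 10)
  for (b in batches) {
    expect_identical(length(unique(vapply(b, `[[`, numeric(1), "length"))),
                     1L)
  }
  # union of batches is exactly the input multiset
  got <- sort(unlist(lapply(batches, function(b)
    vapply(b, `[[`, character(1), "model_id"))))
  expect_identical(got, sort(sprintf("u%03d", 1:45)))

  # same L, count == batch size: exactly one batch
  one <- make_length_batches(random_records(16, lengths = 30, seed = 4),
                             batch_size = 16, seed = 1)
  expect_identical(length(one), 1L)
  expect_identical(make_length_batches(list(), 16, 1), list())

  # deterministic under seed
  b1 <- make_length_batches(recs, 16, seed = 9)
  b2 <- make_length_batches(recs, 16, seed = 9)
  expect_identical(lapply(b1, function(b)
    vapply(b, `[[`, character(1), "model_id")),
    lapply(b2, function(b) vapply(b, `[[`, character(1), "model_id")))
})

test_that("per-batch split honors the fraction and conserves records", {
  recs <- random_records(10, lengths = 40, seed = 5)
  batches <- make_length_batches(recs, batch_size = 10, seed = 1)
  sp <- split_batches(batches, split_fraction = 0.8, seed = 2)
  expect_identical(length(sp$train), 8L)
  expect_identical(length(sp$validation), 2L)

  # single-record batch goes to training
  sp1 <- split_batches(list(recs[1]), 0.8, seed = 1)
  expect_identical(length(sp1$train), 1L)
  expect_identical(length(sp1$validation), 0L)

  # two runs with the same seed give identical splits
  sp2 <- split_batches(batches, 0.8, seed = 2)
  expect_identical(vapply(sp$train, `[[`, character(1), "model_id"),
                   vapply(sp2$train, `[[`, character(1), "model_id"))
})

test_that("history epoch zero equals the direct mean smooth L1 loss", {
  net <- build_network(tiny_net_config(seed = 3))
  recs <- random_records(6, lengths = c(9, 12), seed = 8)
  fit <- train_network(net, recs, recs[1:3],
                       train_config(epochs = 0, batch_size = 4, seed = 1))
  preds <- predict_quality(net, recs, batch_size = 4)
  truth <- vapply(recs, `[[`, numeric(1), "true_gdtts")
  expect_equal(fit$history$train_loss[1],
               mean(smooth_l1(preds$predicted_gdtts - truth)),
               tolerance = 1e-12)
  expect_identical(fit$history$epoch[1], 0L)
})

test_that("a zero learning rate is a null update", {
  net <- build_network(tiny_net_config(seed = 5))
  recs <- random_records(5, lengths = 10, seed = 12)
  fit <- train_network(net, recs, list(),
                       train_config(epochs = 1, learning_rate = 0,
                                    batch_size = 4, seed = 1,
                                    keep_best = FALSE))
  expect_identical(fit$net$params, net$params)
})

test_that("training reduces the loss on learnable synthetic data", {
  # labels are a deterministic function of the difference map
  set.seed(44)
  recs <- lapply(1:24, function(i) {
    L <- 12L
    u <- matrix(0, L, L)
    u[upper.tri(u)] <- rnorm(sum(upper.tri(u)), sd = runif(1, 0.1, 3))
    q <- max(0, min(1, 1 - mean(abs(u[upper.tri(u)])) / 3))
    model_record(sprintf("T%d", (i %% 4) + 1), sprintf("m%02d", i),
                 structure(list(values = u, length = L),
                           class = "dmqa_diffmap"), q)
  })
  net <- build_network(tiny_net_config(seed = 2))
  # precondition: the rectified head must start alive in training mode
  x0 <- dmqa:::records_tensor(recs[1:8])
  expect_true(any(dmqa:::nn_forward(net, x0, training = TRUE)$out > 0))
  fit <- train_network(net, recs, list(),
                       train_config(epochs = 200, batch_size = 8,
                                    learning_rate = 1e-3, seed = 2,
                                    keep_best = FALSE))
  hist <- fit$history
  expect_lt(tail(hist$train_loss, 1), hist$train_loss[1])
  # the optimized loss also beats the epoch-1 loss decisively
  expect_lt(tail(hist$train_loss, 1), 0.5 * hist$train_loss[2] + 1e-8)
})

test_that("training without validation warns and records NA val loss", {
  net <- build_network(tiny_net_config(seed = 15))
  recs <- random_records(4, lengths = 9, seed = 2)
  expect_message(
    fit <- train_network(net, recs, list(),
                         train_config(epochs = 1, batch_size = 4, seed = 1),
                         verbose = TRUE),
    "validation set empty")
  expect_true(all(is.na(fit$history$val_loss)))
})
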