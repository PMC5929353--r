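# Architecture, forward/backward passes, decisions, loss, batching,
# schedule, SGD and training behavior.

test_that("shape_chain reproduces the published stage sizes", {
  arch <- cnn_architecture()
  chain <- shape_chain(arch)
  expect_identical(chain$conv_edge, c(360L, 90L, 23L, 6L))
  expect_identical(chain$pool_edge, c(180L, 45L, 11L, 3L))
  expect_identical(chain$channels, c(4L, 8L, 16L, 32L))
  expect_identical(arch$n_features, 288L)       # 32 * 3 * 3
  expect_identical(chain$channels[2], 8L)       # stage 2: 8 x 45 x 45
  expect_identical(chain$pool_edge[2], 45L)
  expect_error(cnn_architecture(input_size = 4),
               "architecture error")
})

test_that("forward pass satisfies the SoftMax contracts", {
  arch <- quick_arch()
  w <- init_weights(arch, seed = 2)
  # zero weights everywhere -> uniform classification vectors
  w0 <- w
  for (i in seq_along(w0$stages)) {
    w0$stages[[i]]$W[] <- 0
    w0$stages[[i]]$beta[] <- 0
  }
  w0$fc$W[] <- 0; w0$fc$b[] <- 0
  X <- matrix(rnorm(arch$input_size^2 * 3), ncol = 3)
  fwd0 <- cnn_forward(w0, X, mode = "eval")
  expect_equal(fwd0$probs, matrix(1 / 3, 3, 3), tolerance = 1e-12)

  # probabilities sum to 1 and are shift invariant in the logits
  fwd <- cnn_forward(w, X, mode = "train")
  expect_equal(colSums(fwd$probs), rep(1, 3), tolerance = 1e-6)
  sm <- braggscreen:::softmax_cols
  z <- matrix(rnorm(30), 3, 10)
  expect_equal(sm(z), sm(z + rep(rnorm(10), each = 3)), tolerance = 1e-6)

  # eval mode is deterministic and batch-composition independent
  e1 <- cnn_forward(w, X, mode = "eval")$probs
  e2 <- cnn_forward(w, X[, c(2, 1, 3)], mode = "eval")$probs
  expect_equal(e1[, c(2, 1, 3)], e2, tolerance = 1e-12)
  expect_error(cnn_forward(w, matrix(0, 10, 2)), "edge")
})

test_that("convolution and pooling match naive oracles", {
  # one-stage network, eval mode with unit running stats and identity BN:
  # output = maxpool(conv(x)) for nonnegative activations
  set.seed(31)
  for (rep in 1:5) {
    arch <- cnn_architecture(input_size = 16, channels = 2L)
    w <- init_weights(arch, seed = rep)
    w$stages[[1]]$W <- abs(w$stages[[1]]$W)  # keep activations >= 0
    x <- matrix(abs(rnorm(256)), 16, 16)
    fwd <- cnn_forward(w, x, mode = "eval")
    bn_scale <- 1 / sqrt(1 + braggscreen:::BN_EPS)  # unit running variance
    for (ch in 1:2) {
      kern <- matrix(w$stages[[1]]$W[ch, ], 3, 3)
      ref <- naive_maxpool(naive_conv(x, kern, stride = 2), 2)  # 8 -> 4x4
      got <- matrix(fwd$features[(ch - 1) * 16 + 1:16, 1], 4, 4)
      expect_equal(got, ref * bn_scale, tolerance = 1e-9)
    }
  }
  # multi-channel second-stage convolution against the naive oracle,
  # via the gather plan itself
  arch2 <- cnn_architecture(input_size = 12, channels = c(2L, 3L))
  plan <- braggscreen:::build_plan(arch2)
  st <- plan$stages[[2]]
  xin <- array(rnorm(st$n^2 * st$Cin), c(st$n, st$n, st$Cin))
  Xcol <- matrix(as.numeric(xin), ncol = 1)
  Xpad <- matrix(0, st$Lpad, 1)
  Xpad[st$interior, ] <- Xcol
  P <- Xpad[st$IDX, , drop = FALSE]
  dim(P) <- c(st$k2cin, st$Eo^2)
  W2 <- matrix(rnorm(3 * st$k2cin), 3, st$k2cin)
  O <- W2 %*% P
  for (ch in 1:3) {
    ref <- naive_conv(xin, array(W2[ch, ], c(3, 3, st$Cin)), stride = 2)
    expect_equal(matrix(O[ch, ], st$Eo, st$Eo), ref, tolerance = 1e-9)
  }
})

test_that("decide_label aggregates Hit+Maybe and breaks ties as stated", {
  d <- decide_label(c(0.6, 0.3, 0.1))
  expect_identical(d$binary, "Hit-like")
  expect_identical(d$three_class, "Hit")
  expect_identical(decide_label(c(0, 0, 1))$binary, "Miss")
  expect_identical(decide_label(c(0.2, 0.25, 0.55))$binary, "Miss")
  expect_identical(decide_label(c(0.2, 0.25, 0.55))$three_class, "Miss")
  # exact tie retains the frame (fail-open veto)
  expect_identical(decide_label(c(0.25, 0.25, 0.5))$binary, "Hit-like")
  # argmax ties break Hit > Maybe > Miss
  expect_identical(decide_label(c(0.4, 0.4, 0.2))$three_class, "Hit")
})

test_that("cross_entropy_loss matches closed forms", {
  expect_equal(cross_entropy_loss(matrix(c(1, 0, 0), 3, 1), "Hit"), 0,
               tolerance = 1e-9)
  u <- matrix(1 / 3, 3, 4)
  expect_equal(cross_entropy_loss(u, c("Hit", "Maybe", "Miss", "Hit")),
               log(3), tolerance = 1e-9)
  p <- matrix(c(0.5, 0.3, 0.2, 0.25, 0.5, 0.25), 3, 2)
  expect_equal(cross_entropy_loss(p, c(1, 3)), (log(2) + log(4)) / 2,
               tolerance = 1e-9)
  expect_error(cross_entropy_loss(matrix(0, 3, 0), integer(0)), "empty")
  # probability floor keeps the loss finite
  expect_true(is.finite(cross_entropy_loss(matrix(c(0, 0, 1), 3, 1),
                                           "Hit")))
})

test_that("balanced batches keep per-class counts within one", {
  tab <- random_annotations(300, seed = 41)
  set.seed(42)
  batches <- make_balanced_batches(tab, batch_size = 64, n_batches = 200)
  lab <- setNames(as.character(tab$label), tab$frame_id)
  for (b in batches) {
    counts <- table(factor(lab[b], levels = c("Hit", "Maybe", "Miss")))
    expect_lte(max(counts) - min(counts), 1)
    expect_identical(sum(counts), 64L)
  }
  # batch of 3 -> exactly one of each class
  set.seed(43)
  b3 <- make_balanced_batches(tab, batch_size = 3, n_batches = 5)
  for (b in b3) expect_setequal(unname(lab[b]), c("Hit", "Maybe", "Miss"))
  # scarce classes are resampled with replacement
  scarce <- annotation_table(sprintf("f%02d", 1:12),
                             rep(c("Hit", "Maybe", "Miss"), c(5, 2, 5)))
  set.seed(44)
  bs <- make_balanced_batches(scarce, batch_size = 30, n_batches = 3)
  for (b in bs) expect_identical(length(b), 30L)
  # a class entirely absent is an error
  bad <- annotation_table(c("a", "b"), c("Hit", "Miss"))
  expect_error(make_balanced_batches(bad, 3, 1), "missing")
})

test_that("lr_schedule decays exponentially between the stated endpoints", {
  cfg <- train_config()
  expect_equal(lr_schedule(cfg, 0), 0.1)
  expect_equal(lr_schedule(cfg, 119), 1e-4, tolerance = 1e-12)
  etas <- lr_schedule(cfg, 0:119)
  expect_true(all(diff(etas) < 0))
  mid <- sqrt(0.1 * 1e-4)   # geometric midpoint at e = 59.5
  expect_gt(lr_schedule(cfg, 59), mid)
  expect_lt(lr_schedule(cfg, 60), mid)
  expect_error(lr_schedule(cfg, 120), "out of range")
  expect_error(lr_schedule(cfg, -1), "out of range")
})

test_that("sgd_step updates with w - eta * g and rejects bad gradients", {
  arch <- quick_arch(input = 44L, channels = c(2L, 2L, 2L))
  w <- init_weights(arch, seed = 1)
  zero_grads <- list(
    stages = lapply(w$stages, function(s)
      list(dW = 0 * s$W, dgamma = 0 * s$gamma, dbeta = 0 * s$beta)),
    fc = list(dW = 0 * w$fc$W, db = 0 * w$fc$b))
  # eta = 0 (or zero gradient) leaves the weights unchanged
  expect_identical(sgd_step(w, zero_grads, 0.5)$weights, w)
  g1 <- zero_grads
  g1$fc$dW[1, 1] <- 2
  stepped <- sgd_step(w, g1, 0.1)$weights
  expect_equal(stepped$fc$W[1, 1], w$fc$W[1, 1] - 0.2)
  # toy quadratic (b - 3)^2 through repeated steps converges
  wq <- w
  for (i in 1:200) {
    g <- zero_grads
    g$fc$db <- 2 * (wq$fc$b - 3)
    wq <- sgd_step(wq, g, 0.1)$weights
  }
  expect_lt(max(abs(wq$fc$b - 3)), 1e-6)
  gbad <- zero_grads
  gbad$fc$dW[1, 1] <- NaN
  expect_error(sgd_step(w, gbad, 0.1), "non-finite gradient")
})

test_that("analytic gradients match central finite differences", {
  arch <- quick_arch(input = 44L, channels = c(2L, 3L, 4L))
  w <- init_weights(arch, seed = 7)
  set.seed(8)
  X <- matrix(rnorm(44 * 44 * 5), ncol = 5)
  tg <- c(1L, 2L, 3L, 1L, 2L)
  loss_at <- function(wts) {
    cross_entropy_loss(cnn_forward(wts, X, mode = "train")$probs, tg)
  }
  fwd <- cnn_forward(w, X, mode = "train", keep_cache = TRUE)
  gr <- cnn_backward(w, fwd, targets = tg)
  eps <- 1e-5
  check <- function(get, set, analytic) {
    wp <- set(w, get(w) + eps); wm <- set(w, get(w) - eps)
    fd <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
    expect_equal(analytic, fd, tolerance = 1e-4)
  }
  # a sample of parameters from every layer type
  check(function(w) w$fc$W[2, 3],
        function(w, v) { w$fc$W[2, 3] <- v; w }, gr$fc$dW[2, 3])
  check(function(w) w$fc$b[1],
        function(w, v) { w$fc$b[1] <- v; w }, gr$fc$db[1])
  for (st in 1:3) {
    check(function(w) w$stages[[st]]$W[1, 2],
          function(w, v) { w$stages[[st]]$W[1, 2] <- v; w },
          gr$stages[[st]]$dW[1, 2])
    check(function(w) w$stages[[st]]$gamma[1],
          function(w, v) { w$stages[[st]]$gamma[1] <- v; w },
          gr$stages[[st]]$dgamma[1])
    check(function(w) w$stages[[st]]$beta[2],
          function(w, v) { w$stages[[st]]$beta[2] <- v; w },
          gr$stages[[st]]$dbeta[2])
  }
})

test_that("training learns easy synthetic data and is deterministic", {
  ds <- easy_dataset(240, seed = 51)
  pp <- preprocess_stack(ds$stack, bin = 1, crop_size = 44,
                         contrast = "lcn")
  parts <- split_dataset(ds$annotations,
                         split_spec(c(0.7, 0, 0.3), seed = 1))
  sel <- function(p) {
    ix <- match(p$frame_id, pp$frame_ids)
    list(x = pp$inputs[, ix, drop = FALSE], y = p$label)
  }
  tr <- sel(parts$train); te <- sel(parts$test)
  arch <- quick_arch(input = 44L, channels = c(4L, 8L, 16L))
  cfg <- train_config(batch_size = 32, batches_per_epoch = 24,
                      epochs = 16, seed = 3)
  fit <- train_cnn(tr$x, tr$y, arch, cfg)
  expect_identical(nrow(fit$history), 16L)
  expect_gte(tail(fit$history$train_acc, 1), 0.95)
  # learning-curve sanity: early median loss above late median loss
  expect_gt(median(fit$history$train_loss[1:5]),
            median(fit$history$train_loss[12:16]))
  # held-out binary accuracy on the easy task
  pred <- predict_cnn(fit$weights, te$x, frame_ids = parts$test$frame_id)
  expect_gte(success_rate(te$y, pred$binary), 0.9)

  # same seed twice -> identical histories and weights
  fit2 <- train_cnn(tr$x, tr$y, arch, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$weights, fit2$weights)

  # prediction is order independent and duplicates agree
  perm <- sample(ncol(te$x))
  p1 <- predict_cnn(fit$weights, te$x)
  p2 <- predict_cnn(fit$weights, te$x[, perm, drop = FALSE])
  expect_equal(p1$p_hit[perm], p2$p_hit, tolerance = 1e-12)
  dup <- predict_cnn(fit$weights, te$x[, c(1, 1), drop = FALSE])
  expect_identical(dup$p_hit[1], dup$p_hit[2])

  # weight containers round-trip
  path <- tempfile(fileext = ".bin")
  save_weights(fit$weights, path)
  expect_identical(load_weights(path), fit$weights)
  expect_error(train_cnn(tr$x, rep("Miss", ncol(tr$x)), arch, cfg),
               "missing")
})
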