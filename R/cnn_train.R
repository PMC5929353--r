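# Training loop: class-balanced mini-batches, exponentially decaying
# learning rate, plain stochastic gradient descent on the batch-mean
# cross-entropy.

#' Training configuration
#'
#' Defaults follow the published protocol: 64-image mini-batches, 100
#' batches per epoch, 120 epochs, learning rate decaying exponentially from
#' 0.1 to 0.0001, balanced batches.
#'
#' @param batch_size images per mini-batch.
#' @param batches_per_epoch batches per epoch; `NULL` derives one pass over
#'   the training set (`ceiling(n / batch_size)`), the natural choice for
#'   scaled-down runs.
#' @param epochs number of epochs.
#' @param lr_start,lr_end initial and final learning rate
#'   (`lr_end < lr_start`).
#' @param seed integer seed controlling initialization and batch sampling.
#' @param balanced_batches draw mini-batches with approximately equal
#'   per-class counts (within 1), resampling scarce classes with
#'   replacement.
#' @param momentum,weight_decay optional SGD extras, both 0 by default
#'   (plain vanilla updates).
#' @param augment `NULL` (off) or a named list of [augment_image()]
#'   arguments (e.g. `list(flips = TRUE, max_shift = 3)`) applied
#'   on-the-fly to every training image; enlarging the effective training
#'   set this way reduces overfitting on small annotated sets.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, batches_per_epoch = 100L,
                         epochs = 120L, lr_start = 0.1, lr_end = 1e-4,
                         seed = 1L, balanced_batches = TRUE,
                         momentum = 0, weight_decay = 0, augment = NULL) {
  abort_if(batch_size < 1 || epochs < 1, "batch_size and epochs must be >= 1")
  abort_if(!(lr_end < lr_start) || lr_end <= 0,
           "need 0 < lr_end < lr_start")
  structure(list(batch_size = as.integer(batch_size),
                 batches_per_epoch =
                   if (is.null(batches_per_epoch)) NULL
                   else as.integer(batches_per_epoch),
                 epochs = as.integer(epochs), lr_start = lr_start,
                 lr_end = lr_end, seed = as.integer(seed),
                 balanced_batches = isTRUE(balanced_batches),
                 momentum = momentum, weight_decay = weight_decay,
                 augment = augment),
            class = "train_config")
}

#' Exponentially decaying learning rate
#'
#' `eta(e) = lr_start * (lr_end / lr_start)^(e / (epochs - 1))` for 0-based
#' epoch `e`; equals `lr_start` at the first epoch and `lr_end` at the
#' last, strictly decreasing in between.
#'
#' @param config a [train_config()].
#' @param epoch 0-based epoch index, `0 <= epoch < epochs`.
#' @return the learning rate.
#' @export
lr_schedule <- function(config, epoch) {
  abort_if(any(epoch < 0) || any(epoch >= config$epochs),
           "epoch out of range")
  if (config$epochs == 1) return(config$lr_start)
  config$lr_start *
    (config$lr_end / config$lr_start)^(epoch / (config$epochs - 1))
}

# Internal: balanced batch of indices given a label code vector.
#' @noRd
balanced_batch_indices <- function(class_rows, batch_size) {
  k <- length(class_rows)
  base <- batch_size %/% k
  rem <- batch_size %% k
  extra <- if (rem > 0) sample.int(k, rem) else integer(0)
  unlist(lapply(seq_len(k), function(ci) {
    m <- base + (ci %in% extra)
    rows <- class_rows[[ci]]
    if (m == 0) return(integer(0))
    sample(rows, m, replace = m > length(rows))
  }), use.names = FALSE)
}

#' Class-balanced mini-batches
#'
#' Emits batches of frame ids in which per-class counts differ by at most
#' one, so that the majority class cannot dominate the gradient. Classes
#' with fewer frames than their quota are resampled with replacement.
#' Deterministic given the ambient RNG state.
#'
#' @param table an [annotation_table()]; every class must be present.
#' @param batch_size images per batch.
#' @param n_batches number of batches to emit.
#' @return list of character vectors of frame ids.
#' @export
make_balanced_batches <- function(table, batch_size = 64L, n_batches = 1L) {
  abort_if(!inherits(table, "annotation_table"),
           "table must be an annotation_table")
  present <- table(table$label) > 0
  abort_if(!all(present),
           "balanced batches need every class present; missing: %s",
           paste(names(present)[!present], collapse = ", "))
  class_rows <- lapply(CLASS_LEVELS, function(cl) which(table$label == cl))
  lapply(seq_len(n_batches), function(b) {
    table$frame_id[balanced_batch_indices(class_rows, batch_size)]
  })
}

#' One stochastic gradient descent step
#'
#' `w <- w - eta * g` for every learnable parameter, where `g` is the mean
#' over the batch of the per-example loss gradients (as produced by
#' [cnn_backward()]). Optional classical momentum and weight decay are
#' supported but default to zero.
#'
#' @param weights a `cnn_weights` object.
#' @param grads gradient list from [cnn_backward()].
#' @param eta learning rate.
#' @param state optional momentum state (velocity) from a previous step.
#' @param momentum,weight_decay SGD extras.
#' @return list with updated `weights` and `state`.
#' @export
sgd_step <- function(weights, grads, eta, state = NULL, momentum = 0,
                     weight_decay = 0) {
  upd <- function(w, g, key) {
    if (any(!is.finite(g))) {
      stop(sprintf("training error: non-finite gradient in %s", key),
           call. = FALSE)
    }
    if (weight_decay > 0) g <- g + weight_decay * w
    if (momentum > 0) {
      v <- state[[key]]
      if (is.null(v)) v <- 0 * g
      v <- momentum * v - eta * g
      state[[key]] <<- v
      w + v
    } else {
      w - eta * g
    }
  }
  if (is.null(state)) state <- list()
  for (i in seq_along(weights$stages)) {
    weights$stages[[i]]$W <-
      upd(weights$stages[[i]]$W, grads$stages[[i]]$dW, paste0("W", i))
    weights$stages[[i]]$gamma <-
      upd(weights$stages[[i]]$gamma, grads$stages[[i]]$dgamma,
          paste0("g", i))
    weights$stages[[i]]$beta <-
      upd(weights$stages[[i]]$beta, grads$stages[[i]]$dbeta, paste0("b", i))
  }
  weights$fc$W <- upd(weights$fc$W, grads$fc$dW, "fcW")
  weights$fc$b <- upd(weights$fc$b, grads$fc$db, "fcb")
  list(weights = weights, state = state)
}

#' @noRd
eval_in_chunks <- function(weights, inputs, chunk = 128L) {
  n <- ncol(inputs)
  probs <- matrix(0, weights$arch$n_classes, n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    probs[, s:e] <- cnn_forward(weights, inputs[, s:e, drop = FALSE],
                                mode = "eval")$probs
  }
  probs
}

#' Train the classifier
#'
#' Runs `epochs x batches_per_epoch` class-balanced mini-batches of plain
#' SGD on the batch-mean cross-entropy, with the learning rate following
#' [lr_schedule()]. Per-epoch training loss/accuracy (running over the
#' epoch's batches) and validation loss/accuracy (eval mode; never used for
#' updates) are recorded. Deterministic given `config$seed`.
#'
#' @param inputs `edge^2 x n` matrix of preprocessed images (see
#'   [preprocess_stack()]).
#' @param labels labels aligned with the columns of `inputs`.
#' @param arch a [cnn_architecture()] whose `input_size` matches the inputs.
#' @param config a [train_config()].
#' @param val_inputs,val_labels optional held-out set monitored per epoch.
#' @param verbose print one line per epoch.
#' @return list with `weights` (trained `cnn_weights`) and `history`
#'   (data.frame: epoch, lr, train_loss, train_acc, val_loss, val_acc).
#' @export
train_cnn <- function(inputs, labels, arch, config = train_config(),
                      val_inputs = NULL, val_labels = NULL,
                      verbose = FALSE) {
  abort_if(!inherits(arch, "cnn_architecture"),
           "arch must be a cnn_architecture")
  abort_if(nrow(inputs) != arch$input_size^2,
           "inputs do not match arch$input_size")
  labels <- canonical_labels(labels)
  targets <- as.integer(labels)
  if (config$balanced_batches) {
    missing_cl <- CLASS_LEVELS[tabulate(targets, 3) == 0]
    abort_if(length(missing_cl) > 0,
             "balanced training needs every class present; missing: %s",
             paste(missing_cl, collapse = ", "))
  }
  n <- ncol(inputs)
  nb <- if (is.null(config$batches_per_epoch)) {
    as.integer(ceiling(n / config$batch_size))
  } else {
    config$batches_per_epoch
  }
  class_rows <- lapply(1:3, function(ci) which(targets == ci))
  weights <- init_weights(arch, seed = config$seed)
  state <- NULL
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), train_acc = numeric(0),
                        val_loss = numeric(0), val_acc = numeric(0))
  val_targets <- if (!is.null(val_labels))
    as.integer(canonical_labels(val_labels)) else NULL

  with_seed(derive_seed(config$seed, 1L), {
    for (epoch in seq_len(config$epochs) - 1L) {
      eta <- lr_schedule(config, epoch)
      ep_loss <- 0; ep_correct <- 0; ep_n <- 0
      for (b in seq_len(nb)) {
        ix <- if (config$balanced_batches) {
          balanced_batch_indices(class_rows, config$batch_size)
        } else {
          sample.int(n, config$batch_size, replace = config$batch_size > n)
        }
        batch_x <- inputs[, ix, drop = FALSE]
        if (!is.null(config$augment)) {
          edge <- arch$input_size
          for (j in seq_len(ncol(batch_x))) {
            batch_x[, j] <- as.numeric(do.call(
              augment_image,
              c(list(image = matrix(batch_x[, j], edge, edge)),
                config$augment)))
          }
        }
        fwd <- cnn_forward(weights, batch_x, mode = "train",
                           keep_cache = TRUE)
        weights <- fwd$weights  # running BN statistics
        loss <- cross_entropy_loss(fwd$probs, targets[ix])
        abort_if(!is.finite(loss),
                 "training error: non-finite loss at epoch %d batch %d (lr %.4g)",
                 epoch, b, eta)
        grads <- cnn_backward(weights, fwd, targets = targets[ix])
        stepped <- sgd_step(weights, grads, eta, state = state,
                            momentum = config$momentum,
                            weight_decay = config$weight_decay)
        weights <- stepped$weights
        state <- stepped$state
        pred <- apply(fwd$probs, 2, which.max)
        ep_loss <- ep_loss + loss * length(ix)
        ep_correct <- ep_correct + sum(pred == targets[ix])
        ep_n <- ep_n + length(ix)
      }
      row <- data.frame(epoch = epoch, lr = eta,
                        train_loss = ep_loss / ep_n,
                        train_acc = ep_correct / ep_n,
                        val_loss = NA_real_, val_acc = NA_real_)
      if (!is.null(val_inputs)) {
        vp <- eval_in_chunks(weights, val_inputs)
        row$val_loss <- cross_entropy_loss(vp, val_targets)
        row$val_acc <- mean(apply(vp, 2, which.max) == val_targets)
      }
      history <- rbind(history, row)
      if (verbose) {
        message(sprintf(
          "epoch %3d  lr %.5f  train loss %.4f acc %.3f  val acc %s",
          epoch, eta, row$train_loss, row$train_acc,
          ifelse(is.na(row$val_acc), "-", sprintf("%.3f", row$val_acc))))
      }
    }
  })
  list(weights = weights, history = history)
}

#' Classify a stack (or input matrix)
#'
#' Eval-mode forward pass plus [decide_label()] per frame; results are
#' independent of batching and frame order.
#'
#' @param weights trained `cnn_weights`.
#' @param inputs `edge^2 x n` input matrix, or the list returned by
#'   [preprocess_stack()].
#' @param frame_ids optional ids (taken from `inputs` when it is a
#'   `preprocess_stack()` result).
#' @return data.frame with columns `frame_id`, `p_hit`, `p_maybe`,
#'   `p_miss`, `binary`, `three_class`.
#' @export
predict_cnn <- function(weights, inputs, frame_ids = NULL) {
  if (is.list(inputs) && !is.null(inputs$inputs)) {
    if (is.null(frame_ids)) frame_ids <- inputs$frame_ids
    inputs <- inputs$inputs
  }
  abort_if(nrow(inputs) != weights$arch$input_size^2,
           "inputs do not match arch$input_size")
  if (is.null(frame_ids)) frame_ids <- paste0("f", seq_len(ncol(inputs)))
  probs <- eval_in_chunks(weights, inputs)
  dec <- decide_label(probs)
  data.frame(frame_id = frame_ids, p_hit = probs[1, ],
             p_maybe = probs[2, ], p_miss = probs[3, ],
             binary = dec$binary, three_class = dec$three_class,
             stringsAsFactors = FALSE)
}
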