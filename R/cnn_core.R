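# Forward and reverse passes of the classifier, vectorized over the batch:
# every convolution is an im2col gather followed by one GEMM, batch norm and
# ReLU are row-recycled vector ops, and max pooling selects among the p^2
# pool-corner column sets. The reverse pass is hand-derived reverse-mode
# differentiation of the same graph (gradients with respect to all weights
# and, when requested, the input pixels).

#' @noRd
as_input_matrix <- function(input, edge) {
  if (is.matrix(input) && nrow(input) == edge && ncol(input) == edge) {
    dim(input) <- c(edge * edge, 1L)
    return(input)
  }
  if (is.array(input) && length(dim(input)) == 3) {
    abort_if(dim(input)[1] != edge || dim(input)[2] != edge,
             "input edge does not match the architecture input_size")
    return(matrix(input, edge * edge, dim(input)[3]))
  }
  abort_if(!is.matrix(input) || nrow(input) != edge * edge,
           "input must be edge^2 x batch (or edge x edge x batch)")
  input
}

#' SoftMax over the columns of a logit matrix
#' @noRd
softmax_cols <- function(logits) {
  mx <- apply(logits, 2, max)
  e <- exp(logits - rep(mx, each = nrow(logits)))
  e / rep(colSums(e), each = nrow(logits))
}

#' Run the network forward
#'
#' Maps a batch of preprocessed square images to feature vectors, logits and
#' SoftMax classification vectors over (Hit, Maybe, Miss). In `train` mode,
#' batch normalization uses the batch statistics (and updates the running
#' statistics in the returned weights); in `eval` mode it uses the stored
#' running statistics, so evaluation is deterministic and batch-order
#' independent.
#'
#' @param weights a `cnn_weights` object (see [init_weights()]).
#' @param input `edge^2 x batch` matrix (or `edge x edge x batch` array, or
#'   a single `edge x edge` matrix).
#' @param mode `"eval"` or `"train"`.
#' @param keep_cache retain the intermediate activations needed by
#'   [cnn_backward()].
#' @return list with `features` (`n_features x batch`), `logits`
#'   (`n_classes x batch`), `probs` (SoftMax columns, each summing to 1),
#'   `weights` (with updated running statistics in train mode) and,
#'   if requested, `cache`.
#' @export
cnn_forward <- function(weights, input, mode = c("eval", "train"),
                        keep_cache = FALSE) {
  mode <- match.arg(mode)
  abort_if(!inherits(weights, "cnn_weights"),
           "weights must be a cnn_weights object")
  arch <- weights$arch
  plan <- build_plan(arch)
  X <- as_input_matrix(input, arch$input_size)
  B <- ncol(X)
  cache <- if (keep_cache) vector("list", length(plan$stages)) else NULL

  for (i in seq_along(plan$stages)) {
    st <- plan$stages[[i]]
    wgt <- weights$stages[[i]]
    Xpad <- matrix(0, st$Lpad, B)
    Xpad[st$interior, ] <- X
    P <- Xpad[st$IDX, , drop = FALSE]
    dim(P) <- c(st$k2cin, st$Eo^2 * B)
    O <- wgt$W %*% P
    if (mode == "train") {
      m <- rowMeans(O)
      cent <- O - m
      v <- rowMeans(cent^2)
      istd <- 1 / sqrt(v + BN_EPS)
      xhat <- cent * istd
      weights$stages[[i]]$run_mean <-
        (1 - BN_MOMENTUM) * wgt$run_mean + BN_MOMENTUM * m
      weights$stages[[i]]$run_var <-
        (1 - BN_MOMENTUM) * wgt$run_var + BN_MOMENTUM * v
    } else {
      istd <- 1 / sqrt(wgt$run_var + BN_EPS)
      xhat <- (O - wgt$run_mean) * istd
    }
    A <- wgt$gamma * xhat + wgt$beta
    relu_mask <- A > 0
    A[!relu_mask] <- 0
    # max pool over the p^2 corner column sets
    coloff <- rep((0:(B - 1)) * st$Eo^2, each = st$Ep^2)
    cols <- lapply(st$corners, function(q) rep(q, times = B) + coloff)
    parts <- lapply(cols, function(cl) A[, cl, drop = FALSE])
    Pl <- do.call(pmax, parts)
    if (keep_cache) {
      sel <- vector("list", length(parts))
      taken <- matrix(FALSE, nrow(Pl), ncol(Pl))
      for (j in seq_along(parts)) {
        sj <- (parts[[j]] == Pl) & !taken
        taken <- taken | sj
        sel[[j]] <- sj
      }
      cache[[i]] <- list(P = P, xhat = xhat, istd = istd,
                         relu_mask = relu_mask, cols = cols, sel = sel,
                         B = B)
    }
    arr <- array(Pl, c(st$Cout, st$Ep^2, B))
    X <- matrix(aperm(arr, c(2, 1, 3)), st$Ep^2 * st$Cout, B)
  }

  feat <- X
  logits <- weights$fc$W %*% feat + weights$fc$b
  probs <- softmax_cols(logits)
  out <- list(features = feat, logits = logits, probs = probs,
              weights = weights)
  if (keep_cache) {
    out$cache <- list(stages = cache, features = feat, mode = mode)
  }
  out
}

#' Reverse pass: gradients of the mean cross-entropy loss
#'
#' Backpropagates `dlogits` (by default `(probs - onehot) / batch`, the
#' gradient of the batch-mean cross-entropy with respect to the logits)
#' through the fully connected layer and every filter stage of a cached
#' forward pass.
#'
#' @param weights the `cnn_weights` used in the forward pass.
#' @param fwd result of `cnn_forward(..., keep_cache = TRUE)`.
#' @param targets integer class indices (1 = Hit, 2 = Maybe, 3 = Miss), one
#'   per batch column; ignored when `dlogits` is supplied.
#' @param dlogits optional explicit logit gradient (`n_classes x batch`).
#' @param want_input_grad also return the gradient with respect to the
#'   input pixels (needed for saliency maps).
#' @return list with `stages` (per-stage `dW`, `dgamma`, `dbeta`), `fc`
#'   (`dW`, `db`) and optionally `dinput` (`edge^2 x batch`).
#' @export
cnn_backward <- function(weights, fwd, targets = NULL, dlogits = NULL,
                         want_input_grad = FALSE) {
  abort_if(is.null(fwd$cache), "forward pass must keep_cache = TRUE")
  arch <- weights$arch
  plan <- build_plan(arch)
  probs <- fwd$probs
  B <- ncol(probs)
  if (is.null(dlogits)) {
    abort_if(is.null(targets), "need targets or dlogits")
    onehot <- matrix(0, nrow(probs), B)
    onehot[cbind(as.integer(targets), seq_len(B))] <- 1
    dlogits <- (probs - onehot) / B
  }
  feat <- fwd$cache$features
  grads <- list(fc = list(dW = dlogits %*% t(feat), db = rowSums(dlogits)),
                stages = vector("list", length(plan$stages)))
  dX <- t(weights$fc$W) %*% dlogits
  train_mode <- identical(fwd$cache$mode, "train")

  for (i in rev(seq_along(plan$stages))) {
    st <- plan$stages[[i]]
    wgt <- weights$stages[[i]]
    cc <- fwd$cache$stages[[i]]
    # un-rearrange (Ep^2 * Cout, B) -> (Cout, Ep^2 * B)
    arr <- array(dX, c(st$Ep^2, st$Cout, B))
    dPl <- matrix(aperm(arr, c(2, 1, 3)), st$Cout, st$Ep^2 * B)
    # pool backward: route to the selected corner
    dA <- matrix(0, st$Cout, st$Eo^2 * B)
    for (j in seq_along(cc$cols)) {
      dA[, cc$cols[[j]]] <- dPl * cc$sel[[j]]
    }
    dA[!cc$relu_mask] <- 0
    # batch-norm backward
    dgamma <- rowSums(dA * cc$xhat)
    dbeta <- rowSums(dA)
    dxhat <- dA * wgt$gamma
    dO <- if (train_mode) {
      cc$istd * (dxhat - rowMeans(dxhat) -
                   cc$xhat * rowMeans(dxhat * cc$xhat))
    } else {
      dxhat * cc$istd
    }
    dW <- dO %*% t(cc$P)
    grads$stages[[i]] <- list(dW = dW, dgamma = dgamma, dbeta = dbeta)
    if (i > 1 || want_input_grad) {
      dP <- t(wgt$W) %*% dO
      dim(dP) <- c(st$k2cin * st$Eo^2, B)
      rs <- rowsum(dP, st$IDX)
      dXpad <- matrix(0, st$Lpad, B)
      dXpad[st$u_idx, ] <- rs
      dX <- dXpad[st$interior, , drop = FALSE]
    }
  }
  if (want_input_grad) grads$dinput <- dX
  grads
}

#' Mean cross-entropy loss
#'
#' `L = -(1/N) * sum_i log p_{t_i}` over a batch, with the predicted
#' probability of the target class floored at 1e-12 before the logarithm.
#'
#' @param probs `n_classes x batch` matrix of classification vectors (or a
#'   single vector).
#' @param targets target classes: labels (`Hit`/`Maybe`/`Miss`) or integer
#'   indices 1..3.
#' @return nonnegative scalar loss.
#' @export
cross_entropy_loss <- function(probs, targets) {
  if (is.vector(probs)) probs <- matrix(probs, ncol = 1)
  abort_if(ncol(probs) == 0, "empty batch")
  idx <- if (is.numeric(targets)) as.integer(targets) else
    as.integer(canonical_labels(targets))
  abort_if(length(idx) != ncol(probs), "targets must match the batch")
  p <- pmax(probs[cbind(idx, seq_len(ncol(probs)))], 1e-12)
  -mean(log(p))
}

#' Turn a classification vector into hard decisions
#'
#' Binary decision: the frame is retained (`Hit-like`) iff
#' `p_hit + p_maybe >= p_miss` — ties retain the frame, since a veto tool
#' must fail open. Three-class decision: argmax with ties broken in the
#' order Hit > Maybe > Miss.
#'
#' @param y length-3 classification vector `(p_hit, p_maybe, p_miss)` or a
#'   `3 x batch` matrix of them.
#' @return list with `binary` (`"Hit-like"`/`"Miss"`) and `three_class`
#'   (`"Hit"`/`"Maybe"`/`"Miss"`), vectors of length batch.
#' @export
decide_label <- function(y) {
  if (is.vector(y)) y <- matrix(y, ncol = 1)
  abort_if(nrow(y) != 3, "classification vectors have three components")
  binary <- ifelse(y[1, ] + y[2, ] >= y[3, ], "Hit-like", "Miss")
  three <- CLASS_LEVELS[apply(y, 2, which.max)]
  list(binary = binary, three_class = three)
}
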