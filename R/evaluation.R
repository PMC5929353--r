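# Classifier evaluation: confusion matrices, screening success rate,
# confidence histograms, input-gradient saliency maps, and the
# cross-dataset / data-size / preprocessing-ablation experiment drivers.

# Collapse Hit/Maybe/Miss (or Hit-like) labels to the binary screening
# decision.
#' @noRd
binary_collapse <- function(x) {
  x <- as.character(x)
  ifelse(x %in% c("Hit", "Maybe", "Hit-like"), "Hit-like", "Miss")
}

#' Confusion matrix between ground truth and predictions
#'
#' Rows are ground-truth classes, columns predicted classes; `row_percent`
#' normalizes each truth row to 100. In binary mode, Hit and Maybe are
#' grouped (on both axes) before counting, matching the screening use-case
#' where either class retains the frame. Truth classes with no frames are
#' omitted rather than reported as NaN rows.
#'
#' @param truth,predictions aligned label vectors (`Hit`/`Maybe`/`Miss`;
#'   predictions may also use `Hit-like`).
#' @param binary collapse to Hit-or-Maybe vs Miss.
#' @return object of class `screen_confusion`: list with `labels`,
#'   `counts`, `row_percent`.
#' @export
confusion_matrix <- function(truth, predictions, binary = FALSE) {
  abort_if(length(truth) != length(predictions),
           "validation error: truth and predictions must align")
  abort_if(length(truth) == 0, "empty input")
  if (binary) {
    lev <- c("Hit-like", "Miss")
    t_lab <- factor(binary_collapse(truth), levels = lev)
    p_lab <- factor(binary_collapse(predictions), levels = lev)
  } else {
    lev <- CLASS_LEVELS
    t_lab <- canonical_labels(truth)
    p_lab <- canonical_labels(predictions)
  }
  counts <- table(truth = t_lab, predicted = p_lab)
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  row_percent <- 100 * counts / rowSums(counts)
  structure(list(labels = lev, counts = unclass(counts),
                 row_percent = unclass(row_percent)),
            class = "screen_confusion")
}

#' @export
print.screen_confusion <- function(x, ...) {
  cat("confusion matrix (row %):\n")
  print(round(x$row_percent, 1))
  invisible(x)
}

#' Screening success rate
#'
#' Fraction of frames whose binary decision (Hit-or-Maybe vs Miss) agrees
#' with the binary ground truth. Strict three-class agreement is available
#' via `mode = "three_class"`.
#'
#' @param truth,predictions aligned label vectors.
#' @param mode `"binary"` (default) or `"three_class"`.
#' @return fraction in `[0, 1]`.
#' @export
success_rate <- function(truth, predictions,
                         mode = c("binary", "three_class")) {
  mode <- match.arg(mode)
  abort_if(length(truth) == 0, "empty input")
  abort_if(length(truth) != length(predictions),
           "truth and predictions must align")
  if (mode == "binary") {
    mean(binary_collapse(truth) == binary_collapse(predictions))
  } else {
    mean(as.character(canonical_labels(truth)) ==
           as.character(canonical_labels(predictions)))
  }
}

#' Confidence of correct classifications
#'
#' For frames correctly classified as Miss, collects the predicted `p_miss`;
#' for frames correctly retained (binary Hit-or-Maybe), collects the
#' aggregated `p_hit + p_maybe`. Correctness is judged on the binary
#' decision.
#'
#' @param predictions data.frame from [predict_cnn()] (columns `p_hit`,
#'   `p_maybe`, `p_miss`, `binary`).
#' @param truth ground-truth labels aligned with `predictions`.
#' @return list with `miss` and `hitlike` probability vectors, their means
#'   (`mean_miss`, `mean_hitlike`) and counts.
#' @export
confidence_histogram <- function(predictions, truth) {
  abort_if(nrow(predictions) != length(truth),
           "truth and predictions must align")
  t_bin <- binary_collapse(truth)
  p_bin <- binary_collapse(predictions$binary)
  correct <- t_bin == p_bin
  miss_vals <- predictions$p_miss[correct & p_bin == "Miss"]
  hit_vals <- (predictions$p_hit + predictions$p_maybe)[
    correct & p_bin == "Hit-like"]
  list(miss = miss_vals, hitlike = hit_vals,
       mean_miss = if (length(miss_vals)) mean(miss_vals) else NA_real_,
       mean_hitlike = if (length(hit_vals)) mean(hit_vals) else NA_real_,
       n_miss = length(miss_vals), n_hitlike = length(hit_vals))
}

#' Input-gradient saliency map
#'
#' Gradient of the per-frame cross-entropy loss with respect to the input
#' pixels, obtained by reverse-mode differentiation through the trained
#' network (eval mode). The returned mask flags pixels whose gradient
#' magnitude deviates from the mean by more than three standard deviations
#' — the pixels the network is most sensitive to, which for a trained
#' network concentrate around Bragg spot regions.
#'
#' @param weights trained `cnn_weights`.
#' @param input preprocessed `edge x edge` image (or `edge^2` vector).
#' @param truth_label the frame's ground-truth label.
#' @return object of class `saliency_map`: list with `gradient_magnitude`
#'   (matrix), `mu`, `sigma`, `mask` (logical matrix).
#' @export
saliency_map <- function(weights, input, truth_label) {
  edge <- weights$arch$input_size
  if (is.vector(input)) input <- matrix(input, edge, edge)
  fwd <- cnn_forward(weights, input, mode = "eval", keep_cache = TRUE)
  tgt <- as.integer(canonical_labels(as.character(truth_label)))
  grads <- cnn_backward(weights, fwd, targets = tgt,
                        want_input_grad = TRUE)
  g <- matrix(abs(grads$dinput[, 1]), edge, edge)
  abort_if(any(!is.finite(g)), "numeric error: non-finite input gradient")
  mu <- mean(g)
  sigma <- sqrt(mean((g - mu)^2))
  mask <- g > mu + 3 * sigma | g < mu - 3 * sigma
  structure(list(gradient_magnitude = g, mu = mu, sigma = sigma,
                 mask = mask),
            class = "saliency_map")
}

# ---- experiment drivers ---------------------------------------------------

# Generate, preprocess and split one profile's dataset; returns train /
# validation / test input matrices with labels.
#' @noRd
profile_dataset <- function(profile, n, seed, preprocess = list(),
                            mixture = NULL) {
  if (is.character(profile)) profile <- builtin_profile(profile)
  if (is.null(mixture)) mixture <- demo_scene_mixture()
  ds <- generate_dataset(n, mixture, profile, seed = seed)
  pp_args <- modifyList(list(bin = 1L, crop_size = NULL, contrast = "lcn"),
                        preprocess)
  pp <- do.call(preprocess_stack, c(list(stack = ds$stack), pp_args))
  parts <- split_dataset(ds$annotations,
                         split_spec(seed = derive_seed(seed, 2L)))
  sel <- function(part) {
    ix <- match(part$frame_id, pp$frame_ids)
    list(inputs = pp$inputs[, ix, drop = FALSE], labels = part$label,
         ids = part$frame_id)
  }
  list(train = sel(parts$train), validation = sel(parts$validation),
       test = sel(parts$test), edge = pp$edge, annotations = ds$annotations)
}

#' Cross-dataset training and testing
#'
#' Trains one classifier per training profile (optionally plus one pooled
#' model over all profiles) and evaluates each on every profile's held-out
#' test split, producing the matrix of screening success rates whose
#' diagonal measures within-distribution performance and whose off-diagonal
#' entries measure transfer between detector types. Repeated over `seeds`;
#' the mean matrix and per-seed results are returned.
#'
#' @param profiles list (length >= 2) of [detector_profile()]s or builtin
#'   profile names.
#' @param n_per_profile frames generated per profile.
#' @param arch a [cnn_architecture()] matching the preprocessed size.
#' @param config a [train_config()].
#' @param seeds integer vector of experiment seeds (default 3 seeds, since
#'   single stochastic training runs are not comparable).
#' @param preprocess named list of [preprocess_stack()] arguments.
#' @param include_pooled also train on the union of all profiles' training
#'   splits (reported as row `"pooled"`).
#' @return list with `mean` (train x test success-rate matrix, percent) and
#'   `per_seed` (list of matrices).
#' @export
cross_dataset_experiment <- function(profiles, n_per_profile, arch, config,
                                     seeds = 1:3, preprocess = list(),
                                     include_pooled = FALSE) {
  abort_if(length(profiles) < 2, "need at least two profiles")
  prof_names <- names(profiles)
  if (is.null(prof_names)) {
    prof_names <- vapply(profiles, function(p)
      if (is.character(p)) p else p$name, character(1))
  }
  per_seed <- lapply(seeds, function(seed) {
    data_by_prof <- lapply(seq_along(profiles), function(i) {
      profile_dataset(profiles[[i]], n_per_profile,
                      seed = derive_seed(seed, i), preprocess = preprocess)
    })
    names(data_by_prof) <- prof_names
    for (d in data_by_prof) {
      abort_if(length(unique(d$train$labels)) < 2,
               "profile produced a single-class training set")
    }
    train_sets <- lapply(data_by_prof, function(d) d$train)
    if (include_pooled) {
      train_sets$pooled <- list(
        inputs = do.call(cbind, lapply(data_by_prof,
                                       function(d) d$train$inputs)),
        labels = factor(unlist(lapply(data_by_prof, function(d)
          as.character(d$train$labels))), levels = CLASS_LEVELS))
    }
    cfg <- config
    cfg$seed <- derive_seed(seed, 99L)
    mat <- matrix(NA_real_, length(train_sets), length(data_by_prof),
                  dimnames = list(names(train_sets), prof_names))
    for (tr in names(train_sets)) {
      fit <- train_cnn(train_sets[[tr]]$inputs, train_sets[[tr]]$labels,
                       arch, cfg)
      for (te in prof_names) {
        pred <- predict_cnn(fit$weights, data_by_prof[[te]]$test$inputs)
        mat[tr, te] <- 100 * success_rate(data_by_prof[[te]]$test$labels,
                                          pred$three_class)
      }
    }
    mat
  })
  list(mean = Reduce(`+`, per_seed) / length(per_seed),
       per_seed = per_seed, seeds = seeds)
}

#' Preprocessing ablation
#'
#' Trains the identical protocol under different contrast stages (`none`,
#' `linear`, `lcn`) on one profile and reports the test screening success
#' rate per mode. If training diverges in a mode (which can happen without
#' contrast adjustment), that mode is evaluated with its initial weights
#' and flagged.
#'
#' @param profile a [detector_profile()] or builtin name.
#' @param n frames to generate.
#' @param arch,config as in [cross_dataset_experiment()].
#' @param modes contrast modes to compare.
#' @param seeds experiment seeds.
#' @param preprocess extra [preprocess_stack()] arguments (the contrast
#'   argument is overridden per mode).
#' @return data.frame with columns `mode`, `success_mean`, `success_min`,
#'   `success_max` (percent), `diverged` (any seed).
#' @export
ablation_experiment <- function(profile, n, arch, config,
                                modes = c("none", "linear", "lcn"),
                                seeds = 1:3, preprocess = list()) {
  res <- lapply(modes, function(mode) {
    rates <- numeric(0)
    diverged <- FALSE
    for (seed in seeds) {
      pp <- modifyList(preprocess, list(contrast = mode))
      d <- profile_dataset(profile, n, seed = derive_seed(seed, 7L),
                           preprocess = pp)
      cfg <- config
      cfg$seed <- derive_seed(seed, 99L)
      fit <- tryCatch(
        train_cnn(d$train$inputs, d$train$labels, arch, cfg),
        error = function(e) {
          diverged <<- TRUE
          list(weights = init_weights(arch, seed = cfg$seed))
        })
      pred <- predict_cnn(fit$weights, d$test$inputs)
      rates <- c(rates, 100 * success_rate(d$test$labels,
                                           pred$three_class))
    }
    data.frame(mode = mode, success_mean = mean(rates),
               success_min = min(rates), success_max = max(rates),
               diverged = diverged, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
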