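#' Classification model specification
#'
#' A feature extractor (tiled convolution + TICA pooling, or raw flattened
#' windows) followed by a single dense softmax layer over the two impairment
#' classes. Class order is fixed as `(alcohol, marijuana)`; marijuana (the
#' minority class in typical cohorts) is the positive class of the binary
#' F1 score.
#'
#' @param weights a `tiled_weights` (pretrained or random); ignored for
#'   `input_mode = "raw"`.
#' @param input_side GAF image side the model will consume.
#' @param stride convolution grid stride (default: non-overlapping,
#'   `weights$rf_s`).
#' @param pooling_radius neighborhood radius of the TICA pooling topology.
#' @param epsilon square-root smoothing of the pooled activation.
#' @param feature_lr_scale learning-rate multiplier for the convolutional
#'   bank relative to the head (backbone fine-tuning at a fraction of the
#'   head rate; pooled-energy gradients are much larger than head
#'   gradients, so 1 would destroy the pretrained filters).
#' @param freeze_features if `TRUE`, only the dense head is trained.
#' @param input_mode `"tica"` (GAF images through the tiled network) or
#'   `"raw"` (flattened raw windows through the dense head only; the GAF
#'   ablation hook).
#' @param raw_dim input length for `input_mode = "raw"`.
#' @return object of class `gait_model`.
#' @export
model_spec <- function(weights = NULL, input_side = 64L, stride = NULL,
                       pooling_radius = 1L, epsilon = 1e-8,
                       feature_lr_scale = 0.01,
                       freeze_features = FALSE,
                       input_mode = c("tica", "raw"), raw_dim = NULL) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "tica") {
    stopifnot(inherits(weights, "tiled_weights"))
    stride <- stride %||% weights$rf_s
    st <- tiled_structure(c(input_side, input_side, weights$channels),
                          weights$rf_s, weights$tile_k, weights$n_maps,
                          stride)
    V <- pooling_topology(st, pooling_radius)
    n_feat <- nrow(V)
  } else {
    stopifnot(!is.null(raw_dim))
    st <- NULL; V <- NULL; n_feat <- raw_dim
  }
  structure(list(weights = weights, structure = st, V = V,
                 stride = stride, epsilon = epsilon,
                 feature_lr_scale = feature_lr_scale,
                 freeze_features = freeze_features,
                 input_mode = input_mode, n_feat = n_feat,
                 classes = c("alcohol", "marijuana"),
                 head = list(Wh = matrix(0, n_feat, 2), bh = c(0, 0))),
            class = "gait_model")
}

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf("<gait_model> mode=%s features=%d classes=(%s)%s\n",
              x$input_mode, x$n_feat, paste(x$classes, collapse = ", "),
              if (x$freeze_features) " [features frozen]" else ""))
  invisible(x)
}

# ---- dataset splitting -------------------------------------------------------

#' Train/test split
#'
#' `subject_wise` (default): test subjects are sampled per class so that no
#' subject id contributes samples to both partitions (prevents identity
#' leakage). `record_wise`: stratified per-class sampling of individual
#' samples. Both are deterministic under `seed` and fail if any class ends
#' up absent from either partition.
#'
#' @param gs a `gaf_set` (or any list with `labels` and `subject_ids`).
#' @param strategy `"subject_wise"` or `"record_wise"`.
#' @param test_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` (both `gaf_set`) and the index
#'   vectors `train_idx`, `test_idx`.
#' @export
split_dataset <- function(gs, strategy = c("subject_wise", "record_wise"),
                          test_fraction = 0.3, seed = 1L) {
  strategy <- match.arg(strategy)
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must be strictly between 0 and 1")
  labs <- gs$labels
  test_idx <- withr::with_seed(as.integer(seed), {
    if (strategy == "subject_wise") {
      ti <- integer(0)
      for (lab in unique(labs)) {
        subj <- unique(gs$subject_ids[labs == lab])
        n_test <- min(length(subj) - 1L,
                      max(1L, round(test_fraction * length(subj))))
        if (n_test < 1L)
          stop("class ", lab, " has too few subjects to split")
        ts <- sample(subj, n_test)
        ti <- c(ti, which(gs$subject_ids %in% ts & labs == lab))
      }
      sort(ti)
    } else {
      ti <- integer(0)
      for (lab in unique(labs)) {
        ids <- which(labs == lab)
        n_test <- min(length(ids) - 1L,
                      max(1L, round(test_fraction * length(ids))))
        ti <- c(ti, sample(ids, n_test))
      }
      sort(ti)
    }
  })
  train_idx <- setdiff(seq_along(labs), test_idx)
  for (lab in unique(labs)) {
    if (!any(labs[train_idx] == lab) || !any(labs[test_idx] == lab))
      stop("class ", lab, " absent from one partition; adjust ",
           "test_fraction or provide more subjects")
  }
  list(train = gaf_subset(gs, train_idx), test = gaf_subset(gs, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

# ---- forward / backward ------------------------------------------------------

# Features of a gaf_set under a model: list(feat [N x n_feat], raw, pm, Z)
# so the backward pass can reuse the forward intermediates. `feat` is the
# standardized feature (identity until the model carries frozen
# standardization statistics, set once at the start of training).
.model_features <- function(model, gs, pm = NULL) {
  if (model$input_mode == "raw") {
    X <- do.call(rbind, lapply(gs$images, as.vector))
    return(list(feat = .standardize(model, X), raw = X, pm = NULL,
                Z = NULL))
  }
  st <- model$structure
  patches <- do.call(rbind, lapply(gs$images, as.vector))
  PM <- pm %||% .build_pm(patches, st)
  Z <- .simple_responses(NULL, model$weights, st, pm = PM)
  P2 <- Z^2 %*% t(model$V)
  raw <- sqrt(model$epsilon + P2)
  list(feat = .standardize(model, raw), raw = raw, pm = PM, Z = Z)
}

.standardize <- function(model, raw) {
  if (is.null(model$feat_mu)) return(raw)
  sweep(sweep(raw, 2, model$feat_mu), 2, model$feat_sd, "/")
}

.softmax <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Train the classifier by mini-batch gradient descent
#'
#' Minimizes the softmax cross-entropy with plain mini-batch gradient
#' descent at a fixed learning rate. Gradients propagate through the dense
#' head, the epsilon-smoothed TICA pooling, and the tiled convolution (the
#' gradients of tied filter copies sum into their shared bank). With
#' `freeze_features` only the head is updated. Deterministic per seed.
#'
#' @param model a [model_spec()].
#' @param train_set a `gaf_set` containing both classes.
#' @param epochs,lr,batch_size optimizer settings.
#' @param seed integer seed (mini-batch shuffling).
#' @param verbose print per-epoch loss lines.
#' @return the trained `gait_model`, with `loss_history` (mean per-epoch
#'   cross-entropy) attached.
#' @export
train_classifier <- function(model, train_set, epochs = 100L, lr = 0.01,
                             batch_size = 16L, seed = 1L,
                             verbose = FALSE) {
  labs <- train_set$labels
  if (length(labs) == 0L) stop("empty train set")
  if (length(unique(labs)) < 2L)
    stop("train set must contain both classes")
  y <- match(labs, model$classes)
  if (anyNA(y)) stop("labels outside model classes: ",
                     paste(setdiff(labs, model$classes), collapse = ", "))
  N <- length(y)
  Y <- matrix(0, N, 2); Y[cbind(seq_len(N), y)] <- 1
  fwd <- .model_features(model, train_set)
  if (is.null(model$feat_mu)) {
    # freeze feature standardization from the initial training features:
    # keeps logits and bank gradients O(1) regardless of pooled-energy scale
    model$feat_mu <- colMeans(fwd$raw)
    model$feat_sd <- pmax(apply(fwd$raw, 2, stats::sd), 1e-6)
    fwd$feat <- .standardize(model, fwd$raw)
  }
  st <- model$structure
  loss_hist <- numeric(epochs)
  withr::with_seed(as.integer(seed), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      losses <- numeric(0)
      for (b0 in seq(1L, N, by = batch_size)) {
        bi <- ord[b0:min(b0 + batch_size - 1L, N)]
        B <- length(bi)
        if (model$input_mode == "tica" && !model$freeze_features) {
          # recompute features for the batch under current banks
          rows <- as.vector(vapply(bi, function(t)
            (t - 1L) * st$n_pos + seq_len(st$n_pos),
            integer(st$n_pos)))
          PMb <- fwd$pm[rows, , drop = FALSE]
          Zb <- .simple_responses(NULL, model$weights, st, pm = PMb)
          P2 <- Zb^2 %*% t(model$V)
          raw <- sqrt(model$epsilon + P2)
          feat <- .standardize(model, raw)
        } else {
          feat <- fwd$feat[bi, , drop = FALSE]
          Zb <- NULL; PMb <- NULL
        }
        logits <- feat %*% model$head$Wh +
          matrix(model$head$bh, B, 2, byrow = TRUE)
        probs <- .softmax(logits)
        losses <- c(losses,
                    -mean(log(pmax(probs[cbind(seq_len(B), y[bi])],
                                   1e-12))))
        dlogits <- (probs - Y[bi, , drop = FALSE]) / B
        dWh <- crossprod(feat, dlogits)
        dbh <- colSums(dlogits)
        if (lr > 0) {
          if (model$input_mode == "tica" && !model$freeze_features) {
            dfeat <- dlogits %*% t(model$head$Wh)
            draw <- sweep(dfeat, 2, model$feat_sd, "/")
            dP2 <- draw * (0.5 / raw)      # raw = sqrt(eps + P2) > 0
            dZ <- 2 * Zb * (dP2 %*% model$V)
            G <- .bank_grad_from_dZ(dZ, PMb, st, dim(model$weights$banks))
            model$weights$banks <- model$weights$banks -
              lr * model$feature_lr_scale * G
            # banks changed: cached full-set features are stale, but only
            # the per-batch recomputation above consumes them
          }
          model$head$Wh <- model$head$Wh - lr * dWh
          model$head$bh <- model$head$bh - lr * dbh
        }
      }
      loss_hist[ep] <- mean(losses)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f", ep, loss_hist[ep]))
    }
  })
  model$loss_history <- loss_hist
  model
}

# bank gradient (sum over tied copies) given dZ [B, n_units] and the
# batch design matrix PMb [B*n_pos, ssc]
.bank_grad_from_dZ <- function(dZ, PMb, st, bank_dim) {
  B <- nrow(dZ)
  G <- array(0, bank_dim)
  class_rep <- rep(st$class_id, times = B)
  k <- st$tile_k
  for (l in seq_len(st$n_maps)) {
    dZl <- dZ[, (l - 1L) * st$n_pos + seq_len(st$n_pos), drop = FALSE]
    v <- as.vector(t(dZl))
    for (c in seq_len(st$n_classes)) {
      rows <- which(class_rep == c)
      if (length(rows) == 0L) next
      cu <- (c - 1L) %/% k + 1L; cv <- (c - 1L) %% k + 1L
      G[l, cu, cv, ] <- crossprod(PMb[rows, , drop = FALSE], v[rows])
    }
  }
  G
}

#' Class probabilities for a gaf_set
#'
#' @param model a trained `gait_model`.
#' @param gs a `gaf_set`.
#' @return `[N, 2]` matrix of class probabilities, columns in
#'   `model$classes` order.
#' @export
predict_proba <- function(model, gs) {
  feat <- .model_features(model, gs)$feat
  logits <- feat %*% model$head$Wh +
    matrix(model$head$bh, nrow(feat), 2, byrow = TRUE)
  .softmax(logits)
}

#' Rank-statistic ROC AUC
#'
#' Probability that a random positive scores above a random negative, with
#' ties credited 0.5 (Mann-Whitney statistic).
#'
#' @param scores numeric scores (higher = more positive).
#' @param positive logical vector, TRUE for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: one class absent")
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a trained model
#'
#' Computes accuracy, binary F1 with marijuana as the positive class,
#' macro F1, rank-statistic ROC AUC from the marijuana-class probability,
#' and the 2x2 confusion table. If the test set contains a single class the
#' AUC is reported as `NA` with a warning.
#'
#' @param model a trained `gait_model`.
#' @param test_set a nonempty `gaf_set`.
#' @return object of class `eval_report` with fields `accuracy`, `f1`,
#'   `f1_macro`, `roc_auc`, `confusion`, `n_test`.
#' @export
evaluate_classifier <- function(model, test_set) {
  if (length(test_set$labels) == 0L) stop("empty test set")
  probs <- predict_proba(model, test_set)
  pred <- model$classes[max.col(probs, ties.method = "first")]
  truth <- test_set$labels
  n <- length(truth)
  conf <- table(factor(truth, levels = model$classes),
                factor(pred, levels = model$classes))
  acc <- sum(diag(conf)) / n
  f1_of <- function(pos) {
    tp <- sum(truth == pos & pred == pos)
    fp <- sum(truth != pos & pred == pos)
    fn <- sum(truth == pos & pred != pos)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  f1 <- f1_of("marijuana")
  f1_macro <- mean(vapply(model$classes, f1_of, numeric(1)))
  auc <- if (length(unique(truth)) < 2L) {
    warning("single-class test set: ROC AUC undefined, reported as NA")
    NA_real_
  } else roc_auc(probs[, 2], truth == "marijuana")
  structure(list(accuracy = acc, f1 = f1, f1_macro = f1_macro,
                 roc_auc = auc, confusion = conf, n_test = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> n=%d  accuracy=%.4f  F1=%.4f  ",
                     "macroF1=%.4f  AUC=%s\n"),
              x$n_test, x$accuracy, x$f1, x$f1_macro,
              if (is.na(x$roc_auc)) "NA" else sprintf("%.4f", x$roc_auc)))
  print(x$confusion)
  invisible(x)
}

#' Build a raw-window sample set (GAF ablation hook)
#'
#' Packs the resampled triaxial cycle windows themselves (no angular
#' encoding) into the same container the trainer consumes, so a raw-input
#' dense model can be compared against the GAF pathway.
#'
#' @param cs a `cycle_set`.
#' @return a `gaf_set`-shaped object whose `images` are 3 x n windows.
#' @export
window_set <- function(cs) {
  cycles <- if (inherits(cs, "cycle_set")) cs$cycles else cs
  structure(list(images = lapply(cycles, function(c) c$window),
                 labels = vapply(cycles, function(c) c$label, character(1)),
                 subject_ids = vapply(cycles, function(c) c$subject_id,
                                      character(1)),
                 cycle_ids = vapply(cycles, function(c) c$cycle_id,
                                    character(1)),
                 side = NA_integer_),
            class = "gaf_set")
}
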