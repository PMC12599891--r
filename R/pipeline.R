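#' Default pipeline run configuration
#'
#' A nested per-stage configuration for [run_pipeline()], sized as a
#' desk-scale demonstration (64x64 GAF images, stride-level segmentation,
#' short bouts). Every stage seed is derived deterministically from the
#' global `seed`, so one integer reproduces the whole run.
#'
#' @param seed global seed.
#' @param out_dir artifact directory (default: a fresh temporary directory).
#' @return nested configuration list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("gaitica_")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    sim = list(class_mix = c(sober = 8, alcohol = 8, marijuana = 8),
               bouts_per_subject = 1L, duration_s = 12, fs = 50),
    preprocess = list(lowpass_cutoff_hz = 10, filter_order = 4L,
                      hampel_window = 11L, hampel_nsigma = 3,
                      min_cycle_s = 0.9, max_cycle_s = 2.0,
                      ncc_threshold = 0.6, resample_len = 64L),
    encode = list(paa_len = NULL, method = "gasf"),
    pretrain = list(enabled = TRUE, filter_label = "sober",
                    n_patches = 200L, patch_side = 16L,
                    n_maps = 3L, tile_k = 2L, rf_s = 8L,
                    patch_stride = 4L, max_outer = 60L, tol = 1e-4,
                    epsilon = 1e-8),
    train = list(epochs = 80L, lr = 0.05, batch_size = 16L,
                 stride = NULL, pooling_radius = 1L,
                 freeze_features = FALSE,
                 strategy = "subject_wise", test_fraction = 0.3),
    verbosity = 1L
  ), class = "run_config")
}

.stage_log <- function(cfg, stage, ...) {
  if ((cfg$verbosity %||% 1L) > 0L)
    message(sprintf("[%s] %s", stage, sprintf(...)))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full pipeline: simulate, preprocess, encode, pretrain, train,
#' evaluate
#'
#' Executes all stages in order on synthetic data (or, if
#' `config$input_dir` is set, on recording CSVs read from disk), writes
#' every intermediate artifact under `config$out_dir`, and returns the
#' evaluation report. Identical config and seed produce an identical
#' report.
#'
#' @param config a [default_run_config()]-style nested list.
#' @return list with `report` (an `eval_report`), `train_accuracy`, and
#'   `paths` (named artifact paths).
#' @export
run_pipeline <- function(config = default_run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  seed <- config$seed

  recs <- .stage("simulate", {
    if (!is.null(config$input_dir)) {
      read_recordings_csv(config$input_dir)
    } else {
      r <- do.call(generate_dataset,
                   c(config$sim, list(seed = derive_seed(seed, "simulate"))))
      paths$recordings <- file.path(config$out_dir, "recordings")
      write_recordings_csv(r, paths$recordings)
      r
    }
  })
  .stage_log(config, "simulate", "%d recordings", length(recs))

  cs <- .stage("preprocess", {
    sc <- do.call(segmentation_config, config$preprocess)
    out <- preprocess_dataset(recs, sc)
    paths$cycles <- file.path(config$out_dir, "cycles.rds")
    saveRDS(out, paths$cycles)
    utils::write.csv(cycle_report(out),
                     file.path(config$out_dir, "cycles.csv"),
                     row.names = FALSE)
    out
  })
  .stage_log(config, "preprocess", "%d validated cycles",
             length(cs$cycles))

  gs <- .stage("encode", {
    out <- encode_cycles(cs, paa_len = config$encode$paa_len,
                         method = config$encode$method)
    paths$gaf <- file.path(config$out_dir, "gaf.rds")
    saveRDS(out, paths$gaf)
    out
  })
  .stage_log(config, "encode", "%d GAF images, side %d",
             length(gs$images), gs$side)

  pc <- config$pretrain
  weights <- .stage("pretrain", {
    if (isTRUE(pc$enabled)) {
      sober <- gaf_subset(gs, gs$labels == pc$filter_label)
      if (length(sober$images) == 0L)
        stop("no '", pc$filter_label, "' images available for pretraining")
      patches <- sample_gaf_patches(sober, pc$n_patches, pc$patch_side,
                                    seed = derive_seed(seed, "patches"))
      C <- dim(gs$images[[1]])[3]
      st <- tiled_structure(c(pc$patch_side, pc$patch_side, C),
                            pc$rf_s, pc$tile_k, pc$n_maps,
                            stride = pc$patch_stride)
      fit <- pretrain_tica(
        patches, W0 = NULL, V = NULL,
        config = tica_config(epsilon = pc$epsilon,
                             max_outer = pc$max_outer, tol = pc$tol,
                             seed = derive_seed(seed, "pretrain")),
        st = st, verify = FALSE)
      paths$weights <- file.path(config$out_dir, "weights.rds")
      saveRDS(fit, paths$weights)
      .stage_log(config, "pretrain",
                 "objective %.2f -> %.2f in %d outer iterations",
                 fit$trace[1], fit$trace[length(fit$trace)], fit$n_outer)
      fit$weights
    } else {
      C <- dim(gs$images[[1]])[3]
      init_tiled_weights(pc$n_maps, pc$tile_k, pc$rf_s, C,
                         seed = derive_seed(seed, "init"))
    }
  })

  tc <- config$train
  impaired <- gaf_subset(gs, gs$labels %in% c("alcohol", "marijuana"))
  res <- .stage("train", {
    sp <- split_dataset(impaired, tc$strategy, tc$test_fraction,
                        seed = derive_seed(seed, "split"))
    model <- model_spec(weights, input_side = gs$side,
                        stride = tc$stride,
                        pooling_radius = tc$pooling_radius,
                        freeze_features = tc$freeze_features)
    model <- train_classifier(model, sp$train, epochs = tc$epochs,
                              lr = tc$lr, batch_size = tc$batch_size,
                              seed = derive_seed(seed, "train"))
    paths$model <- file.path(config$out_dir, "model.rds")
    saveRDS(model, paths$model)
    train_rep <- evaluate_classifier(model, sp$train)
    list(model = model, split = sp, train_accuracy = train_rep$accuracy)
  })
  .stage_log(config, "train", "final loss %.4f, train accuracy %.3f",
             utils::tail(res$model$loss_history, 1), res$train_accuracy)

  report <- .stage("evaluate", {
    rep <- evaluate_classifier(res$model, res$split$test)
    paths$report <- file.path(config$out_dir, "report.json")
    jsonlite::write_json(
      list(accuracy = rep$accuracy, f1 = rep$f1, f1_macro = rep$f1_macro,
           roc_auc = rep$roc_auc, n_test = rep$n_test,
           train_accuracy = res$train_accuracy,
           confusion = as.data.frame(rep$confusion), seed = seed),
      paths$report, auto_unbox = TRUE, digits = NA)
    rep
  })
  .stage_log(config, "evaluate",
             "accuracy %.3f  F1 %.3f  AUC %.3f on %d test cycles",
             report$accuracy, report$f1, report$roc_auc, report$n_test)

  list(report = report, train_accuracy = res$train_accuracy,
       paths = paths)
}

#' End-to-end synthetic benchmark
#'
#' Convenience wrapper used by the acceptance tests: generates a synthetic
#' cohort with the default (or overridden) class presets, runs the full
#' pipeline in memory, and returns the headline metrics.
#'
#' @param seed global seed.
#' @param n_alcohol,n_marijuana,n_sober subject counts.
#' @param duration_s bout length (s).
#' @param bouts_per_subject bouts per subject.
#' @param presets class parameter presets (default [class_presets()]).
#' @param pretrain run unsupervised TICA pretraining on the sober images.
#' @param epochs,lr supervised optimizer settings.
#' @param max_outer pretraining outer-iteration budget.
#' @param freeze_features train the head only (isolates the effect of the
#'   pretrained filter bank in ablation comparisons).
#' @param test_fraction subject-wise held-out fraction.
#' @return list with `accuracy`, `auc`, `f1`, `train_accuracy`, `n_test`,
#'   `n_cycles`.
#' @export
run_synthetic_benchmark <- function(seed = 1L, n_alcohol = 15L,
                                    n_marijuana = 15L, n_sober = 20L,
                                    duration_s = 12, bouts_per_subject = 1L,
                                    presets = class_presets(),
                                    pretrain = TRUE, epochs = 80L,
                                    lr = 0.05, max_outer = 60L,
                                    freeze_features = FALSE,
                                    test_fraction = 0.3) {
  cfg <- default_run_config(seed = seed)
  cfg$sim$class_mix <- c(sober = if (pretrain) n_sober else 0,
                         alcohol = n_alcohol, marijuana = n_marijuana)
  cfg$sim$duration_s <- duration_s
  cfg$sim$bouts_per_subject <- bouts_per_subject
  cfg$sim$params_by_class <- presets
  cfg$pretrain$enabled <- pretrain
  cfg$pretrain$max_outer <- max_outer
  cfg$train$epochs <- epochs
  cfg$train$lr <- lr
  cfg$train$freeze_features <- freeze_features
  cfg$train$test_fraction <- test_fraction
  cfg$verbosity <- 0L
  res <- run_pipeline(cfg)
  unlink(cfg$out_dir, recursive = TRUE)
  list(accuracy = res$report$accuracy, auc = res$report$roc_auc,
       f1 = res$report$f1, train_accuracy = res$train_accuracy,
       n_test = res$report$n_test)
}
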