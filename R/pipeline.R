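## One-command orchestration: synthesize (or ingest) a corpus, extract the
## 15-feature matrix, split 70/15/15, train the MLP, and report confusion
## matrices and metrics for all three splits. All randomness flows from one
## master seed, so a rerun with the same configuration reproduces the report
## bit for bit.

#' Experiment configuration
#'
#' @param corpus_dir Optional directory of labeled WAV files (files named
#'   `healthy_*.wav` / `unhealthy_*.wav`). When `NULL` (default) a synthetic
#'   corpus is generated.
#' @param n_healthy,n_unhealthy Synthetic corpus class counts (default 35/77).
#' @param frame_s,hop_s Segmentation parameters (default 2.5 s / 1.25 s).
#' @param mfcc An [mfcc_config()].
#' @param hidden Hidden-layer widths of the classifier (default `c(30, 20)`).
#' @param training A [training_config()].
#' @param fractions Train/validation/test fractions (default 0.70/0.15/0.15).
#' @param seed Master seed; corpus, split and weight initialization all
#'   derive from it.
#' @param out_dir Optional output directory for artifacts (features.csv,
#'   model.json, report.json, manifest.csv).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(corpus_dir = NULL, n_healthy = 35,
                              n_unhealthy = 77, frame_s = 2.5, hop_s = 1.25,
                              mfcc = mfcc_config(), hidden = c(30, 20),
                              training = training_config(),
                              fractions = c(0.70, 0.15, 0.15), seed = 42,
                              out_dir = NULL) {
  structure(list(corpus_dir = corpus_dir, n_healthy = n_healthy,
                 n_unhealthy = n_unhealthy, frame_s = frame_s, hop_s = hop_s,
                 mfcc = mfcc, hidden = as.integer(hidden),
                 training = training, fractions = fractions,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Any key absent from the file keeps its [experiment_config()] default;
#' nested keys `mfcc:` and `training:` override fields of [mfcc_config()] and
#' [training_config()].
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("corpus_dir", "n_healthy", "n_unhealthy",
                                  "frame_s", "hop_s", "hidden", "fractions",
                                  "seed", "out_dir"))]
  if (!is.null(y$mfcc)) args$mfcc <- do.call(mfcc_config, y$mfcc)
  if (!is.null(y$training)) args$training <- do.call(training_config, y$training)
  do.call(experiment_config, args)
}

.read_corpus_dir <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.wav$", full.names = TRUE))
  if (length(paths) == 0) stop("no WAV files in ", dir, call. = FALSE)
  lapply(paths, function(p) {
    id <- sub("\\.wav$", "", basename(p))
    label <- if (grepl("unhealthy", id)) "unhealthy"
             else if (grepl("healthy", id)) "healthy"
             else stop("cannot infer label from file name '", basename(p),
                       "'", call. = FALSE)
    rec <- read_wav(p, id = id, label = label)
    if (rec$rate != canonical_rate()) {
      rec <- resample_recording(rec, canonical_rate())
    }
    rec
  })
}

#' Run the full classification experiment
#'
#' Stages, in order: corpus (synthetic or from `corpus_dir`), feature
#' extraction, stratified 70/15/15 split, MLP training with early stopping,
#' and evaluation on all three splits. A failing stage aborts with the stage
#' name in the error.
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress per-stage progress messages (default TRUE).
#' @return Invisibly, a list: `report` (seed, split sizes and ids, confusion
#'   counts and metrics per split, epochs run, final train/val MSE),
#'   `model`, `history`, `features`, `splits`, and the corpus `manifest`
#'   (synthetic corpora only).
#' @export
run_experiment <- function(config = experiment_config(), quiet = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("experiment stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("stage corpus")
  manifest <- NULL
  recordings <- stage("corpus", {
    if (is.null(config$corpus_dir)) {
      corpus <- generate_corpus(config$n_healthy, config$n_unhealthy,
                                seed = config$seed)
      manifest <- corpus$manifest
      corpus$recordings
    } else {
      .read_corpus_dir(config$corpus_dir)
    }
  })

  say("stage features (", length(recordings), " recordings)")
  features <- stage("features",
    build_feature_matrix(recordings, frame_s = config$frame_s,
                         hop_s = config$hop_s, config = config$mfcc))

  say("stage split")
  splits <- stage("split",
    split_dataset(features, fractions = config$fractions,
                  seed = config$seed + 1L))

  say("stage train")
  fit <- stage("train", {
    model <- init_mlp(c(length(feature_names()), config$hidden, 1L),
                      seed = config$seed + 2L)
    train_mlp(model,
              as.matrix(splits$train[, feature_names()]),
              splits$train$label,
              as.matrix(splits$val[, feature_names()]),
              splits$val$label,
              config$training)
  })

  say("stage evaluate")
  evals <- stage("evaluate",
    lapply(splits, function(s) evaluate_model(fit$model, s)))

  hist <- fit$history
  report <- list(
    seed = config$seed,
    architecture = paste(c(length(feature_names()), config$hidden, 1L),
                         collapse = "-"),
    n_recordings = length(recordings),
    epochs_run = nrow(hist),
    final_train_mse = if (nrow(hist)) hist$train_mse[nrow(hist)] else NA_real_,
    best_val_mse = if (nrow(hist) && !all(is.na(hist$val_mse)))
      min(hist$val_mse, na.rm = TRUE) else NA_real_,
    splits = lapply(names(splits), function(nm) {
      list(name = nm, n = nrow(splits[[nm]]), ids = splits[[nm]]$id,
           confusion = unclass(evals[[nm]]$confusion),
           metrics = unclass(evals[[nm]]$metrics))
    })
  )
  names(report$splits) <- names(splits)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_csv(features, file.path(config$out_dir, "features.csv"))
    save_model(fit$model, file.path(config$out_dir, "model.json"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(manifest)) {
      utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                       row.names = FALSE)
    }
  }
  invisible(list(report = report, model = fit$model, history = hist,
                 features = features, splits = splits, manifest = manifest))
}
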