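## Evaluation: 70/15/15 dataset splitting, confusion-matrix construction with
## unhealthy as the positive class, percentage metrics, and the
## architecture-search harness that compares candidate hidden-layer layouts.

#' Split a feature table into train / validation / test sets
#'
#' Validation and test sizes are `round(n * fraction)` with the remainder
#' assigned to training. With `stratify = TRUE` (default) the same rule is
#' applied within each label class, so class balance is preserved and the
#' membership is invariant to input row order for a fixed seed (rows are
#' keyed by sorted id before the seeded shuffle).
#'
#' @param table Data.frame with an `id` column (unique) and, for stratified
#'   splits, a `label` column.
#' @param fractions Length-3 numeric summing to 1; default `c(0.70, 0.15, 0.15)`.
#' @param seed Integer seed for the shuffle.
#' @param stratify Stratify by `label` (default TRUE).
#' @return List of data.frames `train`, `val`, `test` — disjoint and
#'   exhaustive.
#' @export
split_dataset <- function(table, fractions = c(0.70, 0.15, 0.15), seed = 1,
                          stratify = TRUE) {
  if (abs(sum(fractions) - 1) > 1e-9 || length(fractions) != 3L) {
    stop("fractions must be three values summing to 1", call. = FALSE)
  }
  n <- nrow(table)
  if (n < 3L) stop("need at least 3 rows to split", call. = FALSE)
  if (anyDuplicated(table$id)) stop("duplicate ids in table", call. = FALSE)

  assign_one <- function(ids, rng_seed) {
    ids <- sort(ids)
    k <- length(ids)
    n_val <- round(k * fractions[2L])
    n_test <- round(k * fractions[3L])
    perm <- with_seed(rng_seed, sample(ids))
    list(val = perm[seq_len(n_val)],
         test = perm[n_val + seq_len(n_test)],
         train = perm[setdiff(seq_len(k), seq_len(n_val + n_test))])
  }

  if (stratify && !is.null(table$label)) {
    classes <- sort(unique(table$label))
    parts <- list(train = character(0), val = character(0),
                  test = character(0))
    for (i in seq_along(classes)) {
      ids <- table$id[table$label == classes[i]]
      p <- assign_one(ids, seed + i)
      parts$train <- c(parts$train, p$train)
      parts$val <- c(parts$val, p$val)
      parts$test <- c(parts$test, p$test)
    }
  } else {
    parts <- assign_one(table$id, seed)
  }
  out <- lapply(parts[c("train", "val", "test")], function(ids) {
    sub <- table[match(ids, table$id), , drop = FALSE]
    rownames(sub) <- NULL
    sub
  })
  if (!is.null(table$label)) {
    for (nm in names(out)) {
      missing_cls <- setdiff(unique(table$label), unique(out[[nm]]$label))
      if (length(missing_cls) > 0) {
        warning("class ", paste(missing_cls, collapse = ", "),
                " absent from the ", nm, " split", call. = FALSE)
      }
    }
  }
  out
}

#' Confusion matrix with unhealthy as the positive class
#'
#' @param truth,predicted Character vectors of `"healthy"` / `"unhealthy"`,
#'   equal length.
#' @return A `confusion_matrix` with counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  ok <- c("healthy", "unhealthy")
  bad <- setdiff(unique(c(truth, predicted)), ok)
  if (length(bad) > 0) {
    stop("unknown label value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(tp = sum(truth == "unhealthy" & predicted == "unhealthy"),
         fp = sum(truth == "healthy" & predicted == "unhealthy"),
         tn = sum(truth == "healthy" & predicted == "healthy"),
         fn = sum(truth == "unhealthy" & predicted == "healthy")),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(truth = c("unhealthy", "healthy"),
                              predicted = c("unhealthy", "healthy")))
  cat("<confusion_matrix> positive class: unhealthy\n")
  print(m)
  invisible(x)
}

#' Classification metrics in percent
#'
#' Accuracy, sensitivity (true-positive rate among unhealthy), specificity
#' (true-negative rate among healthy), false-negative rate and false-positive
#' rate, each as a percentage. A ratio with a zero denominator is reported as
#' `NA` with a warning. `sensitivity + fnr = 100` and
#' `specificity + fpr = 100` whenever defined.
#'
#' @param cm A [confusion()] matrix with at least one counted sample.
#' @return A `classification_metrics` list: `accuracy`, `sensitivity`,
#'   `specificity`, `fnr`, `fpr` (percent).
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  if (total == 0) stop("confusion matrix counts no samples", call. = FALSE)
  pct <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NA_real_)
    }
    100 * num / den
  }
  structure(
    list(accuracy = 100 * (cm$tp + cm$tn) / total,
         sensitivity = pct(cm$tp, cm$tp + cm$fn, "sensitivity"),
         specificity = pct(cm$tn, cm$tn + cm$fp, "specificity"),
         fnr = pct(cm$fn, cm$tp + cm$fn, "false-negative rate"),
         fpr = pct(cm$fp, cm$tn + cm$fp, "false-positive rate")),
    class = "classification_metrics"
  )
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.2f%% (~%d%%), sensitivity %.2f%%, specificity %.2f%%, fnr %.2f%%, fpr %.2f%%\n",
    x$accuracy, round(x$accuracy), x$sensitivity, x$specificity, x$fnr,
    x$fpr))
  invisible(x)
}

#' Evaluate a trained model on a feature table
#'
#' @param model A trained `mlp_model`.
#' @param table Feature table with `label` and the 15 feature columns.
#' @return List with `confusion` and `metrics`.
#' @export
evaluate_model <- function(model, table) {
  x <- as.matrix(table[, feature_names(), drop = FALSE])
  pred <- predict_mlp(model, x)
  cm <- confusion(table$label, pred$label)
  list(confusion = cm, metrics = classification_metrics(cm))
}

#' Architecture search over hidden-layer layouts
#'
#' Trains one model per candidate hidden-layer layout with an identical seed
#' and training configuration, and reports validation accuracy, validation
#' MSE and parameter count per candidate. The row with the highest validation
#' accuracy is marked selected, ties resolved toward fewer parameters. A
#' candidate whose training diverges is recorded as a failed row and the
#' search continues.
#'
#' @param candidates List of integer vectors of hidden-layer widths, e.g.
#'   `list(10, c(20, 10), c(30, 20))`.
#' @param train,val Feature tables (as from [build_feature_matrix()]).
#' @param config A [training_config()].
#' @param seed Seed for every candidate's weight initialization.
#' @return Data.frame: `architecture`, `n_params`, `val_accuracy`, `val_mse`,
#'   `failed`, `selected`.
#' @export
architecture_search <- function(candidates, train, val,
                                config = training_config(), seed = 1) {
  if (length(candidates) < 1L) stop("need at least one candidate", call. = FALSE)
  p <- length(feature_names())
  x_train <- as.matrix(train[, feature_names(), drop = FALSE])
  x_val <- as.matrix(val[, feature_names(), drop = FALSE])
  y_train <- encode_labels(train$label)
  y_val <- encode_labels(val$label)

  rows <- lapply(candidates, function(hidden) {
    sizes <- c(p, as.integer(hidden), 1L)
    arch <- paste(hidden, collapse = "/")
    model <- init_mlp(sizes, seed = seed)
    res <- tryCatch({
      fit <- train_mlp(model, x_train, y_train, x_val, y_val, config)
      out <- forward_mlp(fit$model, t(.standardize(x_val,
                                                   fit$model$standardizer)))$a
      scores <- as.numeric(out[[length(out)]])
      val_mse <- mse_loss(y_val, scores)
      acc <- 100 * mean(decode_scores(scores) ==
                          ifelse(y_val == 2, "unhealthy", "healthy"))
      data.frame(architecture = arch, n_params = n_params(model),
                 val_accuracy = acc, val_mse = val_mse, failed = FALSE)
    }, error = function(e) {
      data.frame(architecture = arch, n_params = n_params(model),
                 val_accuracy = NA_real_, val_mse = NA_real_, failed = TRUE)
    })
    res
  })
  report <- do.call(rbind, rows)
  report$selected <- FALSE
  ok <- which(!report$failed)
  if (length(ok) > 0) {
    best <- ok[order(-report$val_accuracy[ok], report$n_params[ok])][1L]
    report$selected[best] <- TRUE
  }
  report
}
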