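fake_table <- function(n_healthy, n_unhealthy) {
  n <- n_healthy + n_unhealthy
  tab <- as.data.frame(matrix(rnorm(n * 15), n, 15))
  names(tab) <- feature_names()
  cbind(data.frame(id = sprintf("s%03d", seq_len(n)),
                   label = rep(c("healthy", "unhealthy"),
                               c(n_healthy, n_unhealthy)),
                   stringsAsFactors = FALSE),
        tab)
}

test_that("a 112-recording table splits 78/17/17, stratified and reproducible", {
  set.seed(1)
  tab <- fake_table(35, 77)
  sp <- split_dataset(tab, seed = 5)
  expect_equal(vapply(sp, nrow, numeric(1)),
               c(train = 78, val = 17, test = 17))
  # the stratified split preserves the 35/77 balance
  expect_equal(sum(sp$val$label == "healthy"), 5)
  expect_equal(sum(sp$test$label == "unhealthy"), 12)

  sp2 <- split_dataset(tab, seed = 5)
  expect_identical(lapply(sp, `[[`, "id"), lapply(sp2, `[[`, "id"))

  ids <- unlist(lapply(sp, `[[`, "id"))
  expect_setequal(ids, tab$id)
  expect_equal(anyDuplicated(ids), 0)

  shuffled <- tab[sample(nrow(tab)), ]
  sp3 <- split_dataset(shuffled, seed = 5)
  expect_setequal(sp3$test$id, sp$test$id)

  expect_error(split_dataset(tab, fractions = c(0.5, 0.2, 0.2)), "summing")
  w <- capture_warnings(split_dataset(fake_table(9, 1), seed = 1))
  expect_true(any(grepl("absent", w)))
})

test_that("confusion counts treat unhealthy as the positive class", {
  truth <- rep(c("healthy", "unhealthy"), c(4, 6))
  cm <- confusion(truth, truth)
  expect_equal(c(cm$tn, cm$tp, cm$fp, cm$fn), c(4, 6, 0, 0))

  # training-set narrative: 22 healthy and 55 unhealthy correct, 1 healthy
  # misclassified as unhealthy
  truth <- rep(c("healthy", "unhealthy"), c(23, 55))
  pred <- c(rep("healthy", 22), "unhealthy", rep("unhealthy", 55))
  cm <- confusion(truth, pred)
  expect_equal(c(cm$tn, cm$tp, cm$fp, cm$fn), c(22, 55, 1, 0))

  flipped <- ifelse(pred == "healthy", "unhealthy", "healthy")
  cmf <- confusion(truth, flipped)
  expect_equal(c(cmf$tp, cmf$fn, cmf$tn, cmf$fp),
               c(cm$fn, cm$tp, cm$fp, cm$tn))

  expect_error(confusion(truth, pred[-1]), "equal length")
  expect_error(confusion(c("healthy", "sick"), c("healthy", "healthy")),
               "unknown label")
})

test_that("metrics reproduce the printed worked example and handle zero denominators", {
  cm <- structure(list(tp = 11, fp = 0, tn = 5, fn = 1),
                  class = "confusion_matrix")
  m <- classification_metrics(cm)
  expect_equal(m$sensitivity, 100 * 11 / 12)   # prints as 91.67
  expect_equal(round(m$sensitivity, 2), 91.67)
  expect_equal(round(m$fnr, 2), 8.33)
  expect_equal(m$specificity, 100)
  expect_equal(m$fpr, 0)
  expect_equal(round(m$accuracy), 94)
  expect_equal(m$sensitivity + m$fnr, 100)

  none <- structure(list(tp = 0, fp = 1, tn = 3, fn = 0),
                    class = "confusion_matrix")
  w <- capture_warnings(m0 <- classification_metrics(none))
  expect_true(any(grepl("sensitivity undefined", w)))
  expect_true(is.na(m0$sensitivity))
  expect_false(is.na(m0$specificity))
  expect_error(classification_metrics(
    structure(list(tp = 0, fp = 0, tn = 0, fn = 0),
              class = "confusion_matrix")), "no samples")
})

test_that("accuracy is the class-size-weighted mix of sensitivity and specificity", {
  set.seed(6)
  for (i in 1:20) {
    cm <- structure(as.list(stats::setNames(rpois(4, 5) + c(1, 0, 1, 0),
                                            c("tp", "fp", "tn", "fn"))),
                    class = "confusion_matrix")
    m <- suppressWarnings(classification_metrics(cm))
    pos <- cm$tp + cm$fn; neg <- cm$tn + cm$fp
    expect_equal(m$accuracy,
                 (m$sensitivity * pos + m$specificity * neg) / (pos + neg))
  }
})

test_that("perfect predictions give accuracy 100 and zero error rates", {
  truth <- rep(c("healthy", "unhealthy"), c(5, 7))
  m <- classification_metrics(confusion(truth, truth))
  expect_equal(m$accuracy, 100)
  expect_equal(m$fnr, 0)
  expect_equal(m$fpr, 0)
})

test_that("architecture search reports every candidate and selects by accuracy then size", {
  set.seed(30)
  n <- 60
  base <- fake_table(n / 2, n / 2)
  # inject a clean signal so candidates can learn
  shift <- ifelse(base$label == "unhealthy", 2, -2)
  for (nm in feature_names()[1:5]) base[[nm]] <- base[[nm]] + shift
  sp <- split_dataset(base, seed = 2)
  cfg <- training_config(max_epochs = 400, patience = 400)
  rep_tab <- architecture_search(list(4, c(8, 4)), sp$train, sp$val,
                                 config = cfg, seed = 9)
  expect_equal(nrow(rep_tab), 2)
  expect_true(all(!rep_tab$failed))
  expect_true(all(is.finite(rep_tab$val_accuracy)))
  expect_equal(sum(rep_tab$selected), 1)

  one <- architecture_search(list(c(6, 3)), sp$train, sp$val,
                             config = cfg, seed = 9)
  expect_true(one$selected[1])
  expect_equal(one$n_params, 15 * 6 + 6 + 6 * 3 + 3 + 3 + 1)
})
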