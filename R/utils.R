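# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Encode class labels as numeric targets
#'
#' Healthy is encoded as 1 and unhealthy as 2; the decision threshold between
#' them is 1.5.
#'
#' @param labels Character vector of `"healthy"` / `"unhealthy"`.
#' @return Numeric vector of 1s and 2s.
#' @export
encode_labels <- function(labels) {
  bad <- setdiff(unique(labels), c("healthy", "unhealthy"))
  if (length(bad) > 0) {
    stop("unknown label value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ifelse(labels == "unhealthy", 2, 1)
}

#' @describeIn encode_labels Map raw network scores back to labels: scores of
#'   at least `threshold` are `"unhealthy"` (the tie at exactly the threshold
#'   resolves to unhealthy, favoring sensitivity in a screening setting).
#' @param scores Numeric network outputs.
#' @param threshold Decision threshold (default 1.5).
#' @export
decode_scores <- function(scores, threshold = 1.5) {
  ifelse(scores >= threshold, "unhealthy", "healthy")
}
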