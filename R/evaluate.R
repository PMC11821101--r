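#' Evaluate predicted keyframes against per-frame labels
#'
#' With `tolerance = 0` this is the frame-wise confusion matrix of the
#' binary prediction vector against the binary truth vector. With
#' `tolerance = k > 0`, a predicted frame counts as a true positive if
#' an unmatched true keyframe lies within `k` frames; matching is greedy
#' one-to-one, nearest pair first, ties resolved toward the earlier
#' truth frame. Unmatched predictions are false positives, unmatched
#' truths false negatives, and the remaining frames true negatives.
#' Undefined precision or recall (zero denominator) is reported as
#' `NaN`, never coerced to 0 or 1.
#'
#' @param predicted A `keyframe_result` or integer vector of 0-based
#'   predicted keyframe indices.
#' @param truth Integer 0/1 label vector of length `N`.
#' @param tolerance Non-negative integer frame tolerance, `< N`.
#' @return A list of class `eval_report` with `tp`, `fp`, `fn`, `tn`,
#'   `accuracy`, `precision`, `recall`, `tolerance` and `n_frames`.
#' @export
evaluate_keyframes <- function(predicted, truth, tolerance = 0L) {
  if (inherits(predicted, "keyframe_result"))
    predicted <- predicted$keyframes
  predicted <- sort(unique(as.integer(predicted)))
  if (!all(truth %in% c(0L, 1L)))
    cdkd_error("truth labels must be 0 or 1", "validation")
  n <- length(truth)
  tolerance <- as.integer(tolerance)
  if (tolerance < 0L || tolerance >= n)
    cdkd_error(sprintf("tolerance must be in [0, %d)", n), "config")
  if (length(predicted) && (min(predicted) < 0L || max(predicted) > n - 1L))
    cdkd_error("predicted index outside the label range", "validation")
  truth_frames <- which(truth == 1L) - 1L

  if (tolerance == 0L) {
    tp <- sum(predicted %in% truth_frames)
    fp <- length(predicted) - tp
    fn <- length(truth_frames) - tp
  } else {
    pairs <- expand.grid(p = predicted, t = truth_frames)
    if (nrow(pairs)) {
      pairs$d <- abs(pairs$p - pairs$t)
      pairs <- pairs[pairs$d <= tolerance, , drop = FALSE]
      pairs <- pairs[order(pairs$d, pairs$t, pairs$p), , drop = FALSE]
    }
    used_p <- used_t <- integer(0)
    tp <- 0L
    for (r in seq_len(nrow(pairs))) {
      if (pairs$p[r] %in% used_p || pairs$t[r] %in% used_t) next
      used_p <- c(used_p, pairs$p[r])
      used_t <- c(used_t, pairs$t[r])
      tp <- tp + 1L
    }
    fp <- length(predicted) - tp
    fn <- length(truth_frames) - tp
  }
  tn <- n - tp - fp - fn
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = (tp + tn) / n,
    precision = if (tp + fp > 0L) tp / (tp + fp) else NaN,
    recall = if (tp + fn > 0L) tp / (tp + fn) else NaN,
    tolerance = tolerance, n_frames = n),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> tp=%d fp=%d fn=%d tn=%d | accuracy=%.3f precision=%.3f recall=%.3f (tolerance %d)\n",
    x$tp, x$fp, x$fn, x$tn, x$accuracy, x$precision, x$recall,
    x$tolerance))
  invisible(x)
}

#' Run several detectors on one sequence and tabulate their scores
#'
#' The multi-method comparison harness: each detector configuration is
#' run on the same sequence and evaluated against the same labels,
#' yielding one row of confusion counts and accuracy/precision/recall
#' per method.
#'
#' @param seq A [frame_sequence].
#' @param truth 0/1 label vector of length `N`.
#' @param methods Named list of [detector_params()] configurations.
#' @param tolerance Frame tolerance passed to [evaluate_keyframes()].
#' @param seed Integer seed forwarded to each detector.
#' @return A data frame with columns `method`, `tp`, `fp`, `fn`, `tn`,
#'   `accuracy`, `precision`, `recall`.
#' @export
compare_methods <- function(seq, truth, methods, tolerance = 0L,
                            seed = 0L) {
  if (length(methods) < 1L)
    cdkd_error("need at least one method", "config")
  if (is.null(names(methods)) || any(names(methods) == ""))
    names(methods) <- vapply(methods, function(m) m$metric$name,
                             character(1L))
  rows <- lapply(names(methods), function(nm) {
    res <- detect_keyframes(seq, methods[[nm]], seed = seed)
    ev <- evaluate_keyframes(res, truth, tolerance)
    data.frame(method = nm, tp = ev$tp, fp = ev$fp, fn = ev$fn,
               tn = ev$tn, accuracy = ev$accuracy,
               precision = ev$precision, recall = ev$recall)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
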