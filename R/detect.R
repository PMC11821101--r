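#' Detector parameters
#'
#' Bundles the metric, embedding backend, extremum window radius and
#' suppression separation used by [detect_keyframes()].
#'
#' @param metric A [metric_spec] or metric name (default `"cosine"`).
#' @param backend A [backend_spec] or backend name (default
#'   `"flatten"`); only used by embedding-domain metrics.
#' @param window_radius Chebyshev radius of the local-extremum window
#'   (default 2, i.e. a 5x5 neighborhood).
#' @param min_separation Minimum frame-index distance between keyframes
#'   and between the two frames of a candidate pair (default 2).
#' @param border Extremum-window policy at the matrix border:
#'   `"interior"` (default) only admits cells whose full window fits
#'   inside the matrix, so frames within `window_radius` of either
#'   sequence end are never certified as extremes; `"clip"` also admits
#'   border cells, comparing against the clipped window only. The
#'   interior policy avoids spurious detections at sequences that stop
#'   just short of a cardiac extreme, at the cost of never detecting a
#'   keyframe in the first or last `window_radius` frames.
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(metric = "cosine", backend = "flatten",
                            window_radius = 2L, min_separation = 2L,
                            border = c("interior", "clip")) {
  if (is.character(metric)) metric <- metric_spec(metric)
  if (is.character(backend)) backend <- backend_spec(backend)
  border <- match.arg(border)
  if (window_radius < 1L)
    cdkd_error("window_radius must be >= 1", "config")
  if (min_separation < 1L)
    cdkd_error("min_separation must be >= 1", "config")
  structure(list(metric = metric, backend = backend,
                 window_radius = as.integer(window_radius),
                 min_separation = as.integer(min_separation),
                 border = border),
            class = "detector_params")
}

#' Pairwise inter-frame matrix
#'
#' Wraps a symmetric `N x N` matrix of metric values together with its
#' orientation: `"similarity"` means keyframe pairs are local minima,
#' `"difference"` means maxima.
#'
#' @param values Symmetric numeric matrix.
#' @param orientation `"similarity"` or `"difference"`.
#' @param metric_name Metric label carried for provenance.
#' @return An object of class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(values,
                            orientation = c("similarity", "difference"),
                            metric_name = "unknown") {
  orientation <- match.arg(orientation)
  if (!is.matrix(values) || nrow(values) != ncol(values))
    cdkd_error("pairwise matrix must be square", "invariant")
  fin <- values[is.finite(values)]
  tol <- 1e-9 * max(1, if (length(fin)) max(abs(fin)) else 1)
  if (!isTRUE(all(abs(values - t(values)) <= tol |
                    (values == t(values))))) # Inf == Inf
    cdkd_error("pairwise matrix must be symmetric", "invariant")
  structure(list(values = values, orientation = orientation,
                 metric_name = metric_name),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix> %dx%d, metric = %s (%s orientation)\n",
              nrow(x$values), ncol(x$values), x$metric_name,
              x$orientation))
  invisible(x)
}

#' Build the all-pairs inter-frame matrix
#'
#' For the cosine metric the sequence is first embedded with the
#' configured backend and the full similarity matrix is computed from
#' normalized rows; pixel metrics are evaluated once per unordered pair
#' and mirrored. The diagonal holds the metric's self-comparison value
#' (cosine 1, SSIM 1, L1 0); PSNR's self-value (+Inf) is stored as the
#' finite matrix maximum plus one so the matrix stays exportable — it
#' can never be a similarity minimum, so detection is unaffected.
#'
#' @param seq A [frame_sequence].
#' @param params [detector_params].
#' @param embeddings Optional precomputed embedding matrix (bypasses the
#'   backend).
#' @param seed Integer seed forwarded to the embedding backend.
#' @return A [pairwise_matrix].
#' @export
build_matrix <- function(seq, params = detector_params(),
                         embeddings = NULL, seed = 0L) {
  stopifnot(inherits(seq, "frame_sequence"))
  spec <- params$metric
  n <- length(seq$frames)
  if (spec$domain == "embedding") {
    emb <- if (is.null(embeddings)) embed(seq, params$backend, seed)
           else embeddings
    if (nrow(emb) != n)
      cdkd_error(sprintf(
        "embedding rows (%d) do not match frame count (%d)", nrow(emb), n),
        "validation")
    norms <- sqrt(rowSums(emb^2))
    zero <- which(norms == 0)
    if (length(zero))
      cdkd_error(sprintf(
        "frame %d has a zero-norm embedding; cosine similarity is undefined",
        zero[1L] - 1L), "degenerate")
    u <- emb / norms
    v <- tcrossprod(u)
    v <- pmin(pmax(v, -1), 1)
    v <- (v + t(v)) / 2
    diag(v) <- 1
  } else {
    v <- matrix(0, n, n)
    for (i in seq_len(n - 1L))
      for (j in seq.int(i + 1L, n))
        v[i, j] <- v[j, i] <- compare_frames(seq, i - 1L, j - 1L, spec)
    diag(v) <- switch(spec$name,
                      l1 = 0,
                      ssim = 1,
                      psnr = Inf)
    if (spec$name == "psnr") {
      fin <- v[is.finite(v)]
      cap <- if (length(fin)) max(fin) else 0
      diag(v) <- cap + 1
    }
  }
  pairwise_matrix(v, spec$orientation, spec$name)
}

#' Find windowed local extrema of a pairwise matrix
#'
#' Scans upper-triangle cells `(i, j)` with `j - i >= min_separation`; a
#' cell qualifies iff its value is strictly more extreme (smaller for
#' similarity orientation, larger for difference) than every other cell
#' of the full symmetric matrix within Chebyshev distance
#' `window_radius`. Plateaus never qualify. With `border = "clip"`
#' (default) windows are clipped at the matrix border; with
#' `border = "interior"` cells whose full window does not fit are
#' skipped (the detector's default, see [detector_params()]).
#' Candidates are returned most-extreme first (ties broken by `(i, j)`
#' lexicographic order).
#'
#' @param M A [pairwise_matrix].
#' @param window_radius Chebyshev window radius (default 2).
#' @param min_separation Minimum `j - i` for a candidate cell (default 2).
#' @param border `"clip"` or `"interior"` (see above).
#' @return A data frame with 0-based columns `i`, `j` and `value`;
#'   zero rows when no cell qualifies (e.g. a constant matrix).
#' @export
find_local_extrema <- function(M, window_radius = 2L, min_separation = 2L,
                               border = c("clip", "interior")) {
  stopifnot(inherits(M, "pairwise_matrix"))
  border <- match.arg(border)
  v <- M$values
  n <- nrow(v)
  if (n < 3L)
    cdkd_error("matrix must be at least 3x3", "validation")
  w <- as.integer(window_radius)
  minimize <- M$orientation == "similarity"
  out_i <- integer(0)
  out_j <- integer(0)
  out_v <- numeric(0)
  lo <- if (border == "interior") 1L + w else 1L
  hi <- if (border == "interior") n - w else n
  for (i in lo:max(lo, hi)) {
    if (i > hi) break
    jmin <- i + as.integer(min_separation)
    if (jmin > hi) break
    for (j in seq.int(jmin, hi)) {
      val <- v[i, j]
      win <- v[max(1L, i - w):min(n, i + w),
               max(1L, j - w):min(n, j + w)]
      ok <- if (minimize) sum(win <= val) == 1L else sum(win >= val) == 1L
      if (ok) {
        out_i <- c(out_i, i - 1L)
        out_j <- c(out_j, j - 1L)
        out_v <- c(out_v, val)
      }
    }
  }
  cands <- data.frame(i = out_i, j = out_j, value = out_v)
  ord <- order(if (minimize) cands$value else -cands$value,
               cands$i, cands$j)
  cands[ord, , drop = FALSE]
}

#' Non-extremum suppression of candidate pairs
#'
#' Processes candidate pairs from most to least extreme (ascending value
#' for similarity metrics, descending for difference metrics; ties by
#' `(i, j)`). Each endpoint frame is accepted iff its index distance to
#' every already-accepted frame is at least `min_separation`; frames
#' closer than that to an accepted keyframe are skipped, which also
#' deduplicates repeats.
#'
#' @param cands Data frame of candidates (`i`, `j`, `value`, 0-based)
#'   as produced by [find_local_extrema()].
#' @param orientation `"similarity"` or `"difference"`.
#' @param min_separation Minimum keyframe separation (default 2).
#' @param parameters Optional parameter record stored on the result.
#' @return A `keyframe_result`: list with `keyframes` (sorted 0-based
#'   indices), `provenance` (accepted pairs and which endpoints each
#'   contributed) and `parameters`.
#' @export
suppress_candidates <- function(cands,
                                orientation = c("similarity", "difference"),
                                min_separation = 2L, parameters = list()) {
  orientation <- match.arg(orientation)
  min_separation <- as.integer(min_separation)
  cols <- c("i", "j", "value")
  if (!all(cols %in% names(cands)))
    cdkd_error("candidates need columns i, j, value", "validation")
  if (nrow(cands) > 0L && any(cands$j - cands$i < min_separation))
    cdkd_error("candidate pair closer than min_separation", "invariant")
  key <- if (orientation == "similarity") cands$value else -cands$value
  cands <- cands[order(key, cands$i, cands$j), , drop = FALSE]
  accepted <- integer(0)
  prov <- list()
  for (r in seq_len(nrow(cands))) {
    got <- integer(0)
    for (f in c(cands$i[r], cands$j[r])) {
      if (length(accepted) == 0L ||
          all(abs(accepted - f) >= min_separation)) {
        accepted <- c(accepted, f)
        got <- c(got, f)
      }
    }
    if (length(got))
      prov[[length(prov) + 1L]] <- data.frame(
        i = cands$i[r], j = cands$j[r], value = cands$value[r],
        accepted = paste(got, collapse = ";"))
  }
  provenance <- if (length(prov)) do.call(rbind, prov)
                else data.frame(i = integer(0), j = integer(0),
                                value = numeric(0),
                                accepted = character(0))
  structure(list(keyframes = sort(accepted),
                 provenance = provenance,
                 parameters = c(parameters,
                                list(min_separation = min_separation,
                                     orientation = orientation))),
            class = "keyframe_result")
}

#' @export
print.keyframe_result <- function(x, ...) {
  cat(sprintf("<keyframe_result> %d keyframes: %s\n",
              length(x$keyframes), paste(x$keyframes, collapse = ", ")))
  invisible(x)
}

#' Detect heartbeat keyframes in a frame sequence
#'
#' Runs the full pipeline: embed (for embedding-domain metrics), build
#' the pairwise matrix, locate windowed local extrema, and apply
#' non-extremum suppression. Deterministic given inputs and seed.
#'
#' @param seq A [frame_sequence].
#' @param params [detector_params].
#' @param embeddings Optional precomputed embedding matrix.
#' @param seed Integer seed forwarded to the embedding backend.
#' @param return_matrix Also attach the pairwise matrix to the result.
#' @return A `keyframe_result` (see [suppress_candidates()]).
#' @export
detect_keyframes <- function(seq, params = detector_params(),
                             embeddings = NULL, seed = 0L,
                             return_matrix = FALSE) {
  M <- build_matrix(seq, params, embeddings = embeddings, seed = seed)
  cands <- find_local_extrema(M, params$window_radius,
                              params$min_separation,
                              border = params$border %||% "interior")
  res <- suppress_candidates(
    cands, M$orientation, params$min_separation,
    parameters = list(window_radius = params$window_radius,
                      border = params$border %||% "interior",
                      metric = params$metric$name,
                      backend = params$backend$name))
  if (return_matrix) res$matrix <- M
  res
}

#' Export a pairwise matrix as CSV
#'
#' Writes the matrix with a 0-based frame-index header row and column;
#' re-importable with [import_matrix()] to within 1e-9.
#'
#' @param M A [pairwise_matrix].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
export_matrix <- function(M, path) {
  stopifnot(inherits(M, "pairwise_matrix"))
  n <- nrow(M$values)
  df <- as.data.frame(format(M$values, digits = 17, scientific = TRUE,
                             trim = TRUE))
  names(df) <- as.character(0:(n - 1L))
  df <- cbind(frame = 0:(n - 1L), df)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    cdkd_error(sprintf("cannot write matrix CSV to %s", path), "io")
  invisible(path)
}

#' Import a pairwise matrix from CSV
#'
#' @param path CSV written by [export_matrix()].
#' @param orientation Orientation to attach (`"similarity"` default).
#' @param metric_name Metric label to attach.
#' @return A [pairwise_matrix].
#' @export
import_matrix <- function(path, orientation = "similarity",
                          metric_name = "unknown") {
  if (!file.exists(path))
    cdkd_error(sprintf("matrix file does not exist: %s", path), "input")
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(m) <- NULL
  pairwise_matrix(m, orientation, metric_name)
}
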