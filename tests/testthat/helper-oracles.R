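# Independent brute-force oracles. These deliberately share no code with
# the package: plain double loops over window offsets, naive counting.

# Exhaustive windowed-extremum checker over the full symmetric matrix.
# Returns a data.frame(i, j, value) of 0-based qualifying cells, ordered
# most-extreme first with (i, j) tie-breaks, like the package output.
brute_extrema <- function(values, orientation, window_radius,
                          min_separation, border = "clip") {
  n <- nrow(values)
  w <- window_radius
  minimize <- orientation == "similarity"
  rows <- list()
  for (i in 1:n) {
    for (j in 1:n) {
      if (j - i < min_separation) next
      if (border == "interior" &&
          (i - w < 1 || i + w > n || j - w < 1 || j + w > n)) next
      val <- values[i, j]
      is_ext <- TRUE
      for (di in -w:w) {
        for (dj in -w:w) {
          if (di == 0 && dj == 0) next
          r <- i + di
          c <- j + dj
          if (r < 1 || r > n || c < 1 || c > n) next
          other <- values[r, c]
          if (minimize && other <= val) is_ext <- FALSE
          if (!minimize && other >= val) is_ext <- FALSE
        }
      }
      if (is_ext)
        rows[[length(rows) + 1L]] <- data.frame(i = i - 1L, j = j - 1L,
                                                value = val)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(i = integer(0), j = integer(0),
                         value = numeric(0))
  key <- if (minimize) out$value else -out$value
  out[order(key, out$i, out$j), , drop = FALSE]
}

# Step-through reimplementation of greedy non-extremum suppression.
brute_suppress <- function(cands, orientation, min_separation) {
  key <- if (orientation == "similarity") cands$value else -cands$value
  cands <- cands[order(key, cands$i, cands$j), , drop = FALSE]
  kept <- integer(0)
  for (r in seq_len(nrow(cands))) {
    for (f in c(cands$i[r], cands$j[r])) {
      far_enough <- TRUE
      for (a in kept)
        if (abs(a - f) < min_separation) far_enough <- FALSE
      if (far_enough) kept <- c(kept, f)
    }
  }
  sort(kept)
}

# Naive frame-wise confusion counts at tolerance 0.
brute_confusion <- function(pred_frames, truth) {
  n <- length(truth)
  pred_vec <- integer(n)
  pred_vec[pred_frames + 1L] <- 1L
  list(tp = sum(pred_vec == 1 & truth == 1),
       fp = sum(pred_vec == 1 & truth == 0),
       fn = sum(pred_vec == 0 & truth == 1),
       tn = sum(pred_vec == 0 & truth == 0))
}

random_symmetric_matrix <- function(n) {
  m <- matrix(stats::rnorm(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# Small random frame sequence for metric/embedding tests.
random_sequence <- function(n_frames = 5L, h = 12L, w = 10L,
                            max_value = 255) {
  frames <- replicate(n_frames,
                      matrix(stats::runif(h * w, 0, max_value), h, w),
                      simplify = FALSE)
  frame_sequence(frames, max_value = max_value)
}

# Random well-formed candidate list for suppression tests.
random_candidates <- function(n_frames, k, min_separation = 2L) {
  i <- sample.int(n_frames - min_separation, k, replace = TRUE) - 1L
  gap <- min_separation +
    sample.int(n_frames, k, replace = TRUE) %% (n_frames %/% 2L)
  j <- pmin(i + gap, n_frames - 1L)
  ok <- j - i >= min_separation
  d <- unique(data.frame(i = i[ok], j = j[ok]))
  d$value <- stats::runif(nrow(d))
  d
}
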