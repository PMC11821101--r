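#' Metric specification
#'
#' Describes one of the four inter-frame comparators. `cosine` operates
#' on embedding vectors and is a similarity (keyframe pairs are matrix
#' minima); `l1` is a pixel-domain difference (keyframe pairs are
#' maxima); `psnr` and `ssim` are pixel-domain similarities.
#'
#' @param name One of `"cosine"`, `"l1"`, `"psnr"`, `"ssim"`.
#' @return A list with elements `name`, `orientation` (`"similarity"` or
#'   `"difference"`) and `domain` (`"embedding"` or `"pixel"`), class
#'   `metric_spec`.
#' @export
metric_spec <- function(name = c("cosine", "l1", "psnr", "ssim")) {
  name <- match.arg(name)
  structure(list(
    name = name,
    orientation = if (name == "l1") "difference" else "similarity",
    domain = if (name == "cosine") "embedding" else "pixel"
  ), class = "metric_spec")
}

#' Cosine similarity between two feature vectors
#'
#' `(a . b) / (|a| |b|)`: 1 means identical direction (most similar
#' frames), values near the sequence minimum flag the frame pair with
#' the largest latent-space difference.
#'
#' @param a,b Numeric vectors of equal length, each with nonzero norm.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b))
    cdkd_error(sprintf("vector lengths differ: %d vs %d",
                       length(a), length(b)), "shape")
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0)
    cdkd_error("cosine similarity is undefined for a zero-norm vector",
               "degenerate")
  s <- sum(a * b) / (na * nb)
  # clamp accumulated floating error at the boundary
  max(-1, min(1, s))
}

check_same_shape <- function(x, y) {
  if (!identical(dim(x), dim(y)))
    cdkd_error(sprintf("frame shapes differ: %dx%d vs %dx%d",
                       nrow(x), ncol(x), nrow(y), ncol(y)), "shape")
}

#' L1 distance between two frames
#'
#' Sum (not mean) of absolute per-pixel differences; zero iff the frames
#' are identical. Set `normalize = TRUE` for a per-pixel mean instead.
#'
#' @param x,y Numeric matrices of identical shape.
#' @param normalize Divide by the pixel count (default `FALSE`).
#' @return A non-negative number.
#' @export
l1_distance <- function(x, y, normalize = FALSE) {
  check_same_shape(x, y)
  s <- sum(abs(x - y))
  if (normalize) s / length(x) else s
}

#' Peak signal-to-noise ratio between two frames
#'
#' `10 log10(max_value^2 / MSE)` with `MSE` the mean squared per-pixel
#' difference. Identical frames give `+Inf`, which compares greater than
#' any finite PSNR — identical frames are legitimately the most similar.
#'
#' @param x,y Numeric matrices of identical shape.
#' @param max_value Dynamic range `L` (255 for 8-bit frames).
#' @return PSNR in dB, possibly `Inf`.
#' @export
psnr <- function(x, y, max_value = 255) {
  check_same_shape(x, y)
  if (!is.numeric(max_value) || max_value <= 0)
    cdkd_error("max_value must be positive", "config")
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

#' Global (single-window) structural similarity between two frames
#'
#' The SSIM index computed once over the whole frame:
#' `((2 mux muy + C1)(2 sxy + C2)) / ((mux^2 + muy^2 + C1)(sx^2 + sy^2 + C2))`
#' with population (1/n) variances and covariance and the usual
#' stabilizers `C1 = (K1 L)^2`, `C2 = (K2 L)^2`. This is deliberately
#' the one-window form, not the 11x11 Gaussian-windowed mean SSIM.
#'
#' @param x,y Numeric matrices of identical shape, at least 2 pixels.
#' @param max_value Dynamic range `L`.
#' @param K1,K2 Stabilizer fractions (defaults 0.01 and 0.03).
#' @return A number in `(-1, 1]`; 1 iff `x == y` elementwise.
#' @export
ssim_global <- function(x, y, max_value = 255, K1 = 0.01, K2 = 0.03) {
  check_same_shape(x, y)
  n <- length(x)
  if (n < 2L)
    cdkd_error("SSIM needs at least 2 pixels", "validation")
  if (K1 <= 0 || K2 <= 0 || max_value <= 0)
    cdkd_error("SSIM constants require K1, K2, max_value > 0", "config")
  C1 <- (K1 * max_value)^2
  C2 <- (K2 * max_value)^2
  mx <- mean(x)
  my <- mean(y)
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

#' Compare two frames (or two embedding rows) under a metric
#'
#' Uniform dispatch over the four comparators. Pixel metrics take a
#' [frame_sequence]; cosine takes an embedding matrix (one row per
#' frame). Indices are 0-based.
#'
#' @param input A `frame_sequence` (pixel metrics) or numeric embedding
#'   matrix (cosine).
#' @param i,j 0-based frame indices.
#' @param spec A [metric_spec] or metric name string.
#' @return The metric value; symmetric in `(i, j)`.
#' @export
compare_frames <- function(input, i, j, spec) {
  if (is.character(spec)) spec <- metric_spec(spec)
  n <- if (inherits(input, "frame_sequence")) length(input$frames)
       else nrow(input)
  for (k in c(i, j))
    if (k < 0L || k > n - 1L)
      cdkd_error(sprintf("frame index %d outside [0, %d]", k, n - 1L),
                 "validation")
  if (spec$domain == "embedding") {
    if (inherits(input, "frame_sequence"))
      cdkd_error(paste("metric", spec$name, "needs an embedding matrix;",
                       "embed the sequence first (see embed())"), "config")
    return(cosine_similarity(input[i + 1L, ], input[j + 1L, ]))
  }
  if (!inherits(input, "frame_sequence"))
    cdkd_error(sprintf("metric %s operates on frames, not embeddings",
                       spec$name), "config")
  x <- input$frames[[i + 1L]]
  y <- input$frames[[j + 1L]]
  switch(spec$name,
         l1 = l1_distance(x, y),
         psnr = psnr(x, y, input$max_value),
         ssim = ssim_global(x, y, input$max_value))
}
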