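#' Embedding backend specification
#'
#' Names the frame-to-feature-vector backend used before the cosine
#' metric. `flatten` uses raw pixels; `downsample` block-averages first
#' (more noise-robust); `pca` projects onto per-sequence principal
#' components; `external` loads precomputed vectors (e.g. GAN-inversion
#' w+ latent codes saved as a delimited matrix) from disk.
#'
#' @param name One of `"flatten"`, `"downsample"`, `"pca"`, `"external"`.
#' @param downsample_factor Block size for `downsample` (default 8).
#' @param pca_components Number of components for `pca` (default 32).
#' @param external_path File with one embedding row per frame
#'   (required for `external`).
#' @return A list of class `backend_spec`.
#' @export
backend_spec <- function(name = c("flatten", "downsample", "pca", "external"),
                         downsample_factor = 8L, pca_components = 32L,
                         external_path = NULL) {
  if (is.character(name) && length(name) == 1L &&
      !name %in% c("flatten", "downsample", "pca", "external"))
    cdkd_error(sprintf("unknown embedding backend '%s'", name), "config")
  name <- match.arg(name)
  if (downsample_factor < 1L)
    cdkd_error("downsample_factor must be >= 1", "config")
  if (pca_components < 1L)
    cdkd_error("pca_components must be >= 1", "config")
  if (name == "external" && is.null(external_path))
    cdkd_error("external backend requires external_path", "config")
  structure(list(name = name,
                 downsample_factor = as.integer(downsample_factor),
                 pca_components = as.integer(pca_components),
                 external_path = external_path),
            class = "backend_spec")
}

as_embedding <- function(values, backend_name) {
  dimnames(values) <- NULL
  structure(values, backend_name = backend_name)
}

#' Flatten frames to raw-pixel embedding rows
#'
#' Row `i` of the result is the row-major flattening of frame `i`
#' (`d = H * W`).
#'
#' @param seq A [frame_sequence].
#' @return An `N x d` numeric matrix.
#' @export
embed_flatten <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  as_embedding(t(vapply(seq$frames, function(f) as.numeric(t(f)),
                        numeric(length(seq$frames[[1L]])))),
               "flatten")
}

block_average <- function(f, factor) {
  h <- nrow(f)
  w <- ncol(f)
  ri <- ceiling(seq_len(h) / factor)
  ci <- ceiling(seq_len(w) / factor)
  counts <- tcrossprod(tabulate(ri), tabulate(ci))
  sums <- rowsum(t(rowsum(f, ri)), ci)
  t(sums) / counts
}

#' Block-averaged embedding
#'
#' Each frame is averaged over non-overlapping `factor x factor` blocks
#' (trailing partial blocks averaged over their actual size), then
#' flattened. `factor = 1` reduces to [embed_flatten()].
#'
#' @param seq A [frame_sequence].
#' @param factor Positive integer block size.
#' @return An `N x (ceil(H/factor) * ceil(W/factor))` matrix.
#' @export
embed_downsample <- function(seq, factor = 8L) {
  stopifnot(inherits(seq, "frame_sequence"))
  factor <- as.integer(factor)
  if (factor < 1L)
    cdkd_error("downsample factor must be >= 1", "config")
  d <- dim(seq$frames[[1L]])
  if (factor > min(d))
    cdkd_error(sprintf("downsample factor %d exceeds frame size %dx%d",
                       factor, d[1L], d[2L]), "config")
  rows <- lapply(seq$frames, function(f) as.numeric(t(block_average(f, factor))))
  as_embedding(do.call(rbind, rows), "downsample")
}

#' Per-sequence PCA embedding
#'
#' Flattened frames are centered by the sequence mean and projected onto
#' the top principal directions (scores as rows). Signs are fixed so
#' each component's largest-magnitude loading is positive, making the
#' result deterministic. A constant sequence yields all-zero scores,
#' which the cosine metric later rejects as degenerate.
#'
#' @param seq A [frame_sequence].
#' @param components Number of components, at most `min(N, H*W)`.
#' @param seed Unused (the projection is deterministic); kept so every
#'   backend shares the `(sequence, spec, seed)` signature.
#' @return An `N x components` matrix.
#' @export
embed_pca <- function(seq, components = 32L, seed = 0L) {
  stopifnot(inherits(seq, "frame_sequence"))
  x <- embed_flatten(seq)
  components <- as.integer(components)
  if (components > min(nrow(x), ncol(x)))
    cdkd_error(sprintf(
      "pca components %d exceeds min(N, H*W) = %d",
      components, min(nrow(x), ncol(x))), "config")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = components)
  rot <- p$rotation
  scores <- p$x
  if (ncol(scores) < components)
    cdkd_error(sprintf(
      "sequence rank too low for %d components (got %d)",
      components, ncol(scores)), "config")
  flip <- vapply(seq_len(ncol(rot)), function(k) {
    l <- rot[, k]
    sign(l[which.max(abs(l))])
  }, numeric(1L))
  flip[flip == 0] <- 1
  as_embedding(sweep(scores[, seq_len(components), drop = FALSE],
                     2L, flip[seq_len(components)], `*`),
               "pca")
}

#' Embed a frame sequence with a named backend
#'
#' Dispatches to [embed_flatten()], [embed_downsample()], [embed_pca()]
#' or, for `external`, loads precomputed per-frame vectors via
#' [read_embeddings()] and checks the row count against the sequence.
#'
#' @param seq A [frame_sequence].
#' @param spec A [backend_spec] or backend name string.
#' @param seed Integer seed forwarded to the backend.
#' @return An `N x d` numeric matrix, one row per frame.
#' @export
embed <- function(seq, spec = backend_spec("flatten"), seed = 0L) {
  if (is.character(spec)) spec <- backend_spec(spec)
  switch(spec$name,
         flatten = embed_flatten(seq),
         downsample = embed_downsample(seq, spec$downsample_factor),
         pca = embed_pca(seq, spec$pca_components, seed),
         external = {
           m <- read_embeddings(spec$external_path)
           if (nrow(m) != length(seq$frames))
             cdkd_error(sprintf(
               "external embeddings have %d rows but the sequence has %d frames",
               nrow(m), length(seq$frames)), "validation")
           as_embedding(m, "external")
         })
}
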