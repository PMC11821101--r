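#' Construct a frame sequence
#'
#' A `frame_sequence` is the package's container for an ordered stack of
#' same-shape single-channel grayscale frames, the shared input of every
#' detector and metric. Frame indices are 0-based throughout the package
#' (files, results, messages).
#'
#' @param frames List of numeric matrices, all of identical dimensions,
#'   with intensities in `[0, max_value]`.
#' @param max_value Dynamic range `L` of the frames (255 for 8-bit data).
#' @param source_ids Optional character vector of per-frame identifiers
#'   (filenames or synthetic indices); defaults to `"frame_<k>"`.
#' @return An object of class `frame_sequence` with elements `frames`,
#'   `max_value` and `source_ids`.
#' @export
frame_sequence <- function(frames, max_value = 255, source_ids = NULL) {
  if (!is.list(frames) || length(frames) < 3L)
    cdkd_error(sprintf(
      "a frame sequence needs at least 3 frames, got %d", length(frames)),
      "validation")
  if (!is.numeric(max_value) || length(max_value) != 1L || max_value <= 0)
    cdkd_error("max_value must be a single positive number", "validation")
  dims <- dim(frames[[1L]])
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!is.matrix(f) || !is.numeric(f))
      cdkd_error(sprintf("frame %d is not a numeric matrix", k - 1L),
                 "validation")
    if (!identical(dim(f), dims))
      cdkd_error(sprintf(
        "frame %d has shape %dx%d, expected %dx%d",
        k - 1L, nrow(f), ncol(f), dims[1L], dims[2L]), "shape")
    rng <- range(f)
    if (rng[1L] < 0 || rng[2L] > max_value)
      cdkd_error(sprintf(
        "frame %d has intensities outside [0, %g]", k - 1L, max_value),
        "validation")
  }
  if (is.null(source_ids))
    source_ids <- sprintf("frame_%03d", seq_along(frames) - 1L)
  if (length(source_ids) != length(frames))
    cdkd_error("source_ids length must match the number of frames",
               "validation")
  structure(list(frames = frames, max_value = max_value,
                 source_ids = as.character(source_ids)),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<frame_sequence> %d frames of %dx%d, max_value = %g\n",
              length(x$frames), d[1L], d[2L], x$max_value))
  invisible(x)
}

# Numeric-aware (natural) sort key: every digit run is zero-padded so
# f2 < f10 sorts as humans expect.
natural_order <- function(x) {
  pad <- function(s) {
    loc <- gregexpr("[0-9]+", s)
    runs <- regmatches(s, loc)[[1L]]
    if (length(runs) == 0L) return(s)
    regmatches(s, loc) <- list(formatC(runs, width = 20, flag = "0"))
    s
  }
  order(vapply(x, pad, character(1L)), x)
}

png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 25L) return(8L)
  as.integer(hdr[25L]) # IHDR bit-depth byte
}

read_one_png <- function(path) {
  img <- png::readPNG(path)
  bits <- png_bit_depth(path)
  maxv <- 2^bits - 1
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  list(pixels = round(img * maxv), max_value = maxv)
}

read_one_tiff <- function(path) {
  img <- tiff::readTIFF(path, info = TRUE)
  bits <- attr(img, "bits.per.sample") %||% 8L
  maxv <- 2^bits - 1
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  pix <- round(img * maxv)
  attributes(pix) <- list(dim = dim(pix)) # drop TIFF metadata attributes
  list(pixels = pix, max_value = maxv)
}

#' Read an ordered grayscale frame sequence from disk
#'
#' Frames are ordered by a numeric-aware (natural) sort of their
#' filenames, so `f1, f2, f10` order correctly; DICOM series are ordered
#' by `InstanceNumber` when every file carries a distinct one. Color
#' images are averaged to a single channel. The dynamic range is taken
#' from the stored bit depth.
#'
#' @param path Directory containing the frames (or a single multi-frame
#'   locator is not supported; frames are one file each).
#' @param dialect One of `"png"`, `"tiff"`, `"dicom"`; default guesses
#'   from the file extensions present.
#' @return A [frame_sequence].
#' @export
read_sequence <- function(path, dialect = c("auto", "png", "tiff", "dicom")) {
  dialect <- match.arg(dialect)
  if (!dir.exists(path))
    cdkd_error(sprintf("frame directory does not exist: %s", path), "input")
  exts <- c(png = "png", tiff = "tif|tiff", dicom = "dcm|dicom")
  if (dialect == "auto") {
    for (d in names(exts)) {
      if (length(list.files(path, pattern = paste0(
        "\\.(", exts[[d]], ")$"), ignore.case = TRUE)) > 0L) {
        dialect <- d
        break
      }
    }
    if (dialect == "auto")
      cdkd_error(sprintf("no PNG/TIFF/DICOM frames found in %s", path),
                 "input")
  }
  files <- list.files(path, pattern = paste0("\\.(", exts[[dialect]], ")$"),
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) < 3L)
    cdkd_error(sprintf(
      "need at least 3 %s frames in %s, found %d",
      dialect, path, length(files)), "input")
  files <- files[natural_order(basename(files))]

  reader <- switch(dialect, png = read_one_png, tiff = read_one_tiff,
                   dicom = read_one_dicom)
  reads <- lapply(files, reader)

  if (dialect == "dicom") {
    inst <- vapply(reads, function(r) r$instance_number %||% NA_real_,
                   numeric(1L))
    if (!anyNA(inst) && !anyDuplicated(inst)) {
      ord <- order(inst)
      reads <- reads[ord]
      files <- files[ord]
    }
  }

  frames <- lapply(reads, `[[`, "pixels")
  dims <- dim(frames[[1L]])
  for (k in seq_along(frames))
    if (!identical(dim(frames[[k]]), dims))
      cdkd_error(sprintf(
        "frame shape mismatch in %s: expected %dx%d, got %dx%d",
        basename(files[k]), dims[1L], dims[2L],
        nrow(frames[[k]]), ncol(frames[[k]])), "shape")
  maxv <- max(vapply(reads, `[[`, numeric(1L), "max_value"))
  frame_sequence(frames, max_value = maxv, source_ids = basename(files))
}

#' Write a frame sequence to a directory of image files
#'
#' 8-bit data (`max_value <= 255`) is written as PNG; wider dynamic
#' ranges as 16-bit TIFF. Filenames are zero-padded so read-back order
#' matches.
#'
#' @param seq A [frame_sequence].
#' @param path Output directory, created if absent.
#' @param prefix Filename prefix (default `"frame"`).
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, the vector of files written.
#' @export
write_sequence <- function(seq, path, prefix = "frame", force = FALSE) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (dir.exists(path) && length(list.files(path)) > 0L && !force)
    cdkd_error(sprintf(
      "directory %s is not empty; use force = TRUE to overwrite", path),
      "io")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- length(seq$frames)
  pad <- max(3L, nchar(as.character(n - 1L)))
  use_png <- seq$max_value <= 255
  ext <- if (use_png) "png" else "tiff"
  files <- file.path(path, sprintf(
    paste0(prefix, "_%0", pad, "d.", ext), seq_len(n) - 1L))
  for (k in seq_len(n)) {
    img <- seq$frames[[k]] / seq$max_value
    if (use_png) png::writePNG(img, files[k])
    else tiff::writeTIFF(img, files[k], bits.per.sample = 16L)
  }
  invisible(files)
}

#' Read per-frame binary keyframe labels from CSV
#'
#' Expects columns `frame_index` (0-based, complete and contiguous) and
#' `label` (0 or 1). Rows may appear in any order.
#'
#' @param path CSV file.
#' @param n_frames Optional expected sequence length; a mismatch is an
#'   error.
#' @return Integer vector of 0/1 labels in frame order.
#' @export
read_labels <- function(path, n_frames = NULL) {
  if (!file.exists(path))
    cdkd_error(sprintf("label file does not exist: %s", path), "input")
  df <- utils::read.csv(path)
  if (!all(c("frame_index", "label") %in% names(df)))
    cdkd_error("label CSV must have columns frame_index,label", "parse")
  if (!all(df$label %in% c(0L, 1L)))
    cdkd_error("labels must be 0 or 1", "validation")
  idx <- df$frame_index
  n <- length(idx)
  if (!setequal(idx, 0:(n - 1L)))
    cdkd_error("frame_index must cover 0..N-1 with no gaps or duplicates",
               "validation")
  if (!is.null(n_frames) && n != n_frames)
    cdkd_error(sprintf(
      "label count %d does not match sequence length %d", n, n_frames),
      "validation")
  as.integer(df$label[order(idx)])
}

#' Write per-frame labels to CSV
#'
#' @param labels Vector of 0/1 labels.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  if (!all(labels %in% c(0L, 1L)))
    cdkd_error("labels must be 0 or 1", "validation")
  utils::write.csv(
    data.frame(frame_index = seq_along(labels) - 1L,
               label = as.integer(labels)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a per-frame embedding matrix from delimited text
#'
#' One row per frame, numeric columns, comma- or tab-separated, no
#' header. This is the hook for externally computed feature vectors
#' (e.g. flattened 18x512 GAN-inversion latent codes, giving 9216
#' columns).
#'
#' @param path CSV/TSV file.
#' @return Numeric matrix, row `i` = feature vector of frame `i` (row 1
#'   is frame 0).
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path))
    cdkd_error(sprintf("embedding file does not exist: %s", path), "input")
  sep <- detect_sep(path)
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE,
                      colClasses = "numeric", fill = FALSE),
    error = function(e) cdkd_error(sprintf(
      "cannot parse embedding matrix %s: %s", path, conditionMessage(e)),
      "parse"),
    warning = function(w) cdkd_error(sprintf(
      "cannot parse embedding matrix %s: %s", path, conditionMessage(w)),
      "parse"))
  m <- as.matrix(df)
  if (anyNA(m))
    cdkd_error(sprintf("non-numeric cell in embedding matrix %s", path),
               "parse")
  dimnames(m) <- NULL
  m
}

#' Write an embedding matrix as CSV
#'
#' @param mat Numeric matrix, one row per frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_embeddings <- function(mat, path) {
  utils::write.table(format(mat, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a keyframe detection result as JSON
#'
#' The JSON object has keys `keyframes` (0-based indices), `provenance`
#' (the accepted candidate pairs) and `parameters`.
#'
#' @param result A `keyframe_result` (see [detect_keyframes()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "keyframe_result"))
  jsonlite::write_json(
    list(keyframes = result$keyframes,
         provenance = result$provenance,
         parameters = result$parameters),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read a keyframe detection result from JSON
#'
#' @param path JSON file written by [write_result()].
#' @return A `keyframe_result`.
#' @export
read_result <- function(path) {
  if (!file.exists(path))
    cdkd_error(sprintf("result file does not exist: %s", path), "input")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(keyframes = as.integer(obj$keyframes),
                 provenance = as.data.frame(obj$provenance),
                 parameters = obj$parameters),
            class = "keyframe_result")
}
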