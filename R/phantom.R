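#' Phantom configuration
#'
#' Describes a synthetic pulsating-vessel sequence: a dark curvilinear
#' vessel on a brighter, smoothly textured background whose width and
#' position modulate sinusoidally with a cardiac phase. Ground-truth
#' keyframes are the per-cycle extremes of the sampled vessel width.
#'
#' @param n_frames Number of frames (>= 3 and >= one full cycle).
#' @param period Cardiac period in frames per cycle (>= 4; default 20).
#' @param height,width Frame size in pixels (default 128).
#' @param vessel_control_points Optional `k x 2` matrix of (row, col)
#'   centerline control points; default a fixed 5-point arc scaled to
#'   the frame.
#' @param base_width Vessel base width in pixels (default 4).
#' @param pulsation_amplitude Fractional width modulation in `[0, 1)`
#'   (default 0.35).
#' @param displacement_amplitude Perpendicular centerline displacement
#'   in pixels (default 2).
#' @param phase_offset Phase of frame 0 in radians; the default `-pi/2`
#'   puts the width extremes exactly on integer frames.
#' @param vessel_contrast Intensity drop at the vessel center
#'   (default 120).
#' @param background_level Background intensity (default 200).
#' @param texture_scale Amplitude of the smooth static background
#'   texture (default 10).
#' @param noise_sigma Std. dev. of additive per-frame Gaussian noise in
#'   intensity units (default 0).
#' @param seed Integer seed driving texture and noise.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(n_frames = 60L, period = 20, height = 128L,
                           width = 128L, vessel_control_points = NULL,
                           base_width = 4, pulsation_amplitude = 0.35,
                           displacement_amplitude = 2,
                           phase_offset = -pi / 2, vessel_contrast = 120,
                           background_level = 200, texture_scale = 10,
                           noise_sigma = 0, seed = 0L) {
  if (n_frames < 3L)
    cdkd_error("n_frames must be >= 3", "config")
  if (period < 4)
    cdkd_error("period must be >= 4 frames per cycle", "config")
  if (n_frames < period)
    cdkd_error("sequence must contain at least one full cycle", "config")
  if (pulsation_amplitude < 0 || pulsation_amplitude >= 1)
    cdkd_error("pulsation_amplitude must be in [0, 1)", "config")
  if (base_width <= 0 || height < 8L || width < 8L)
    cdkd_error("invalid phantom geometry", "config")
  if (noise_sigma < 0)
    cdkd_error("noise_sigma must be >= 0", "config")
  if (is.null(vessel_control_points))
    vessel_control_points <- cbind(
      row = c(0.15, 0.30, 0.50, 0.70, 0.85) * height,
      col = c(0.30, 0.55, 0.65, 0.55, 0.30) * width)
  structure(list(
    n_frames = as.integer(n_frames), period = period,
    height = as.integer(height), width = as.integer(width),
    vessel_control_points = vessel_control_points,
    base_width = base_width, pulsation_amplitude = pulsation_amplitude,
    displacement_amplitude = displacement_amplitude,
    phase_offset = phase_offset, vessel_contrast = vessel_contrast,
    background_level = background_level, texture_scale = texture_scale,
    noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "phantom_config")
}

# Dense centerline samples and unit normals from the control points.
phantom_centerline <- function(config, n_samples = 200L) {
  cp <- config$vessel_control_points
  t0 <- seq(0, 1, length.out = nrow(cp))
  tt <- seq(0, 1, length.out = n_samples)
  r <- stats::spline(t0, cp[, 1L], xout = tt)$y
  c_ <- stats::spline(t0, cp[, 2L], xout = tt)$y
  dr <- c(r[2L] - r[1L], diff(r))
  dc <- c(c_[2L] - c_[1L], diff(c_))
  len <- sqrt(dr^2 + dc^2)
  len[len == 0] <- 1
  list(row = r, col = c_, nrow_ = -dc / len, ncol_ = dr / len)
}

# Smooth static background texture: coarse seeded Gaussian grid,
# bilinearly interpolated to frame size, scaled to texture_scale.
phantom_texture <- function(config) {
  if (config$texture_scale == 0)
    return(matrix(0, config$height, config$width))
  g <- 8L
  coarse <- matrix(stats::rnorm(g * g), g, g)
  rs <- seq(1, g, length.out = config$height)
  cs <- seq(1, g, length.out = config$width)
  r0 <- pmin(floor(rs), g - 1L)
  c0 <- pmin(floor(cs), g - 1L)
  fr <- rs - r0
  fc <- cs - c0
  # bilinear blend of the four surrounding coarse cells
  fine <- outer(1 - fr, 1 - fc) * coarse[r0, c0] +
    outer(fr, 1 - fc) * coarse[r0 + 1L, c0] +
    outer(1 - fr, fc) * coarse[r0, c0 + 1L] +
    outer(fr, fc) * coarse[r0 + 1L, c0 + 1L]
  mx <- max(abs(fine))
  if (mx == 0) fine else fine / mx * config$texture_scale
}

# Render one noiseless frame for modulation value s = sin(phase).
phantom_render <- function(config, cl, texture, s) {
  width_t <- config$base_width * (1 + config$pulsation_amplitude * s)
  disp <- config$displacement_amplitude * s
  rr <- cl$row + disp * cl$nrow_
  cc <- cl$col + disp * cl$ncol_
  px_r <- rep(seq_len(config$height), times = config$width)
  px_c <- rep(seq_len(config$width), each = config$height)
  d2 <- rep(Inf, length(px_r))
  for (k in seq_along(rr))
    d2 <- pmin(d2, (px_r - rr[k])^2 + (px_c - cc[k])^2)
  sigma2 <- 2 * (width_t / 2)^2
  img <- config$background_level + texture -
    config$vessel_contrast * exp(-matrix(d2, config$height,
                                         config$width) / sigma2)
  round(pmin(pmax(img, 0), 255))
}

#' Generate a synthetic pulsating-vessel phantom sequence
#'
#' Frame `t` has cardiac phase `2*pi*(t mod period)/period +
#' phase_offset`; the vessel width is `base_width * (1 +
#' pulsation_amplitude * sin(phase))` and the centerline is displaced
#' perpendicular to itself by `displacement_amplitude * sin(phase)`.
#' Frames are rendered with a Gaussian vessel cross-section (soft
#' borders, as in angiography), quantized to 8-bit, and optional
#' Gaussian noise is added per frame. Labels mark the per-cycle argmax
#' and argmin of the sampled width over each complete cycle (ties to the
#' earlier frame); a pulsation-free phantom has no labeled frames.
#' Deterministic given the seed; frames one exact period apart are
#' identical when `noise_sigma = 0`.
#'
#' @param config A [phantom_config].
#' @return A list of class `phantom_output` with elements `sequence`
#'   (a [frame_sequence]), `labels` (0/1 integer vector), `phase`
#'   (per-frame radians), `width` (per-frame vessel width in pixels) and
#'   `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  cl <- phantom_centerline(config)
  texture <- phantom_texture(config)
  t_ <- seq_len(config$n_frames) - 1L
  phase <- 2 * pi * (t_ %% config$period) / config$period +
    config$phase_offset
  s <- sin(phase)
  width_t <- config$base_width * (1 + config$pulsation_amplitude * s)

  cache <- new.env(parent = emptyenv())
  frames <- vector("list", config$n_frames)
  for (k in seq_along(t_)) {
    key <- sprintf("%.17g", s[k])
    base <- cache[[key]]
    if (is.null(base)) {
      base <- phantom_render(config, cl, texture, s[k])
      cache[[key]] <- base
    }
    frames[[k]] <- if (config$noise_sigma > 0) {
      noisy <- base + stats::rnorm(length(base), sd = config$noise_sigma)
      round(pmin(pmax(matrix(noisy, nrow(base), ncol(base)), 0), 255))
    } else base
  }

  labels <- integer(config$n_frames)
  n_cycles <- floor(config$n_frames / config$period)
  for (c_ in seq_len(n_cycles) - 1L) {
    lo <- ceiling(c_ * config$period)
    hi <- ceiling((c_ + 1) * config$period) - 1L
    idx <- seq.int(lo, min(hi, config$n_frames - 1L)) + 1L
    wcyc <- width_t[idx]
    if (max(wcyc) - min(wcyc) > 1e-12) {
      labels[idx[which.max(wcyc)]] <- 1L
      labels[idx[which.min(wcyc)]] <- 1L
    }
  }

  structure(list(
    sequence = frame_sequence(frames, max_value = 255),
    labels = labels, phase = phase, width = width_t, config = config),
    class = "phantom_output")
}

#' Write a phantom to disk
#'
#' Writes zero-padded PNG frames plus `labels.csv`, `phase.csv` and
#' `config.json` into `path`.
#'
#' @param out A `phantom_output` from [generate_phantom()].
#' @param path Output directory (created if absent).
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, `path`.
#' @export
write_phantom <- function(out, path, force = FALSE) {
  stopifnot(inherits(out, "phantom_output"))
  if (dir.exists(path) && length(list.files(path)) > 0L && !force)
    cdkd_error(sprintf(
      "directory %s is not empty; use force = TRUE to overwrite", path),
      "io")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_sequence(out$sequence, path, force = TRUE)
  write_labels(out$labels, file.path(path, "labels.csv"))
  utils::write.csv(
    data.frame(frame_index = seq_along(out$phase) - 1L,
               phase = out$phase),
    file.path(path, "phase.csv"), row.names = FALSE, quote = FALSE)
  cfg <- out$config
  cfg$vessel_control_points <- unclass(cfg$vessel_control_points)
  jsonlite::write_json(unclass(cfg), file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
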