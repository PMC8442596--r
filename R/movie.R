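#' Specification of a synthetic movie with salient blobs
#'
#' Frames are 8-bit RGB on a uniform gray background; each blob event adds
#' an isotropic Gaussian luminance/color blob (truncated at 3 sigma) during
#' its `[onset, offset)` interval. Ground-truth per-frame masks mark the
#' blob support for downstream saliency validation.
#'
#' @param width,height frame size in pixels (both >= 64).
#' @param fps frames per second.
#' @param duration movie length in seconds.
#' @param blob_events list of events, each a list with `onset_s`, `offset_s`,
#'   `cx`, `cy` (center, pixels), `radius_px` (Gaussian sigma), `contrast`
#'   in `[0, 1]`, and `color` (length-3 RGB in `[0, 1]`).
#' @param background_level background gray value in `[0, 1]`.
#' @param seed integer seed (reserved for stochastic backgrounds; frames are
#'   deterministic given the spec).
#' @return A list of class `movie_spec`.
#' @export
movie_spec <- function(width = 256, height = 256, fps = 24, duration = 4,
                       blob_events = list(), background_level = 0.25,
                       seed = 1L) {
  if (width < 64 || height < 64) stop("width and height must be >= 64")
  if (fps <= 0) stop("fps must be > 0")
  for (ev in blob_events) {
    if (ev$onset_s < 0 || ev$offset_s > duration || ev$onset_s >= ev$offset_s) {
      stop("blob event interval must lie within [0, duration]")
    }
    if (ev$cx < 1 || ev$cx > width || ev$cy < 1 || ev$cy > height) {
      stop("blob center outside frame bounds")
    }
    if (ev$contrast < 0 || ev$contrast > 1) stop("contrast must be in [0, 1]")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 fps = fps, duration = duration, blob_events = blob_events,
                 background_level = background_level, seed = as.integer(seed)),
            class = "movie_spec")
}

#' Generate synthetic movie frames with ground-truth masks
#'
#' @param spec a `movie_spec`.
#' @return A list of class `movie_stack` with `frames` (list of
#'   height x width x 3 arrays in `[0, 1]`), `masks` (list of logical
#'   height x width matrices marking blob support within 3 sigma), `fps`,
#'   and `timestamps` (frame onset times, seconds).
#' @export
generate_synthetic_movie <- function(spec) {
  stopifnot(inherits(spec, "movie_spec"))
  n_frames <- floor(spec$fps * spec$duration)
  W <- spec$width; H <- spec$height
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), times = W), H, W)
  base <- array(spec$background_level, dim = c(H, W, 3))
  frames <- vector("list", n_frames)
  masks <- vector("list", n_frames)
  timestamps <- (seq_len(n_frames) - 1) / spec$fps
  for (f in seq_len(n_frames)) {
    t <- timestamps[f]
    fr <- base
    mask <- matrix(FALSE, H, W)
    for (ev in spec$blob_events) {
      if (t >= ev$onset_s && t < ev$offset_s) {
        d2 <- (xs - ev$cx)^2 + (ys - ev$cy)^2
        sigma <- ev$radius_px
        prof <- exp(-d2 / (2 * sigma^2))
        prof[d2 > (3 * sigma)^2] <- 0     # truncate at 3 sigma
        for (ch in 1:3) {
          fr[, , ch] <- fr[, , ch] +
            ev$contrast * ev$color[ch] * prof
        }
        mask <- mask | (prof > 0)
      }
    }
    fr[fr > 1] <- 1
    fr[fr < 0] <- 0
    # quantize to 8 bit so written PNGs round-trip exactly
    frames[[f]] <- round(fr * 255) / 255
    masks[[f]] <- mask
  }
  structure(list(frames = frames, masks = masks, fps = spec$fps,
                 timestamps = timestamps),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<movie_stack> %d frames, %d x %d px, %g fps\n",
              length(x$frames), d[2], d[1], x$fps))
  invisible(x)
}

#' Write movie frames as a zero-padded numbered PNG sequence
#'
#' @param movie a `movie_stack`.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return Invisibly, the written file paths.
#' @export
write_movie_frames <- function(movie, dir, prefix = "frame") {
  stopifnot(inherits(movie, "movie_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pad <- max(4L, nchar(as.character(length(movie$frames))))
  paths <- file.path(dir, sprintf("%s_%0*d.png", prefix, pad,
                                  seq_along(movie$frames)))
  for (i in seq_along(movie$frames)) {
    png::writePNG(movie$frames[[i]], paths[i])
  }
  invisible(paths)
}

#' Read a PNG frame sequence as a movie stack
#'
#' Files are read in lexicographic order (zero-padded numbering preserves
#' temporal order). Grayscale PNGs are expanded to three channels.
#'
#' @param dir directory containing the PNG files.
#' @param fps frames per second of the sequence.
#' @param pattern filename regular expression.
#' @return A `movie_stack` (without ground-truth masks).
#' @export
read_movie_frames <- function(dir, fps = 24, pattern = "\\.png$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files)) stop("no PNG frames found in ", dir)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  })
  structure(list(frames = frames, masks = NULL, fps = fps,
                 timestamps = (seq_along(frames) - 1) / fps),
            class = "movie_stack")
}
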