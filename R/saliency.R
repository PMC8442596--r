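# ---- Gaussian pyramid -------------------------------------------------------

# 5-tap binomial smoothing kernel [1 4 6 4 1]/16, applied separably.
binomial5 <- c(1, 4, 6, 4, 1) / 16

conv2d <- function(m, kern) {
  # levels too small to carry structure at the kernel's scale pass through
  if (min(dim(m)) < 3L) return(m)
  as.matrix(EBImage::filter2(m, kern, boundary = "replicate"))
}

# Centre-crop a kernel to odd dimensions fitting an image. The caller must
# restore the kernel's defining property afterwards (unit sum for a
# smoothing kernel, zero DC for a contrast kernel) — cropping alone breaks
# both.
crop_kernel <- function(kern, dims) {
  kh <- nrow(kern); kw <- ncol(kern)
  odd_fit <- function(d) if (d %% 2L == 1L) d else d - 1L
  th <- min(kh, odd_fit(dims[1]))
  tw <- min(kw, odd_fit(dims[2]))
  if (th < kh || tw < kw) {
    ch <- (kh - th) %/% 2L; cw <- (kw - tw) %/% 2L
    kern <- kern[(ch + 1L):(ch + th), (cw + 1L):(cw + tw), drop = FALSE]
  }
  kern
}

smooth5 <- function(m) {
  k <- crop_kernel(outer(binomial5, binomial5), dim(m))
  k <- k / sum(k)   # unit DC gain even when cropped
  conv2d(m, k)
}

# One pyramid reduction: separable binomial smoothing then factor-2
# decimation with ceiling dimensions at odd sizes.
pyr_reduce <- function(m) {
  s <- smooth5(m)
  s[seq(1, nrow(s), by = 2), seq(1, ncol(s), by = 2), drop = FALSE]
}

gaussian_pyramid <- function(m, n_levels = 8L) {
  pyr <- vector("list", n_levels + 1L)
  pyr[[1]] <- m
  for (k in seq_len(n_levels)) pyr[[k + 1]] <- pyr_reduce(pyr[[k]])
  pyr
}

# Bilinear resampling of a 2D map to target dims (rows, cols).
resample_map <- function(m, nr, nc) {
  if (nrow(m) == nr && ncol(m) == nc) return(m)
  EBImage::resize(m, w = nr, h = nc)
}

# ---- Channels ---------------------------------------------------------------

# Intensity and colour-opponency channels of an RGB frame (values in [0,1]).
# Colour channels use the standard broadly-tuned opponents with negatives
# clamped and low-luminance suppression (zeroed where I < max(I)/10).
frame_channels <- function(frame) {
  r <- frame[, , 1]; g <- frame[, , 2]; b <- frame[, , 3]
  I <- (r + g + b) / 3
  thr <- max(I) / 10
  clamp0 <- function(x) { x[x < 0] <- 0; x }
  R <- clamp0(r - (g + b) / 2)
  G <- clamp0(g - (r + b) / 2)
  B <- clamp0(b - (r + g) / 2)
  Y <- clamp0((r + g) / 2 - abs(r - g) / 2 - b)
  low <- I < thr
  R[low] <- 0; G[low] <- 0; B[low] <- 0; Y[low] <- 0
  list(I = I, RG = R - G, BY = B - Y)
}

# Gabor energy (two quadrature phases) at one orientation.
# Wavelength 7 px, aspect ratio 1, sigma = 0.56 * wavelength.
gabor_kernels <- function(theta, wavelength = 7) {
  sigma <- 0.56 * wavelength
  half <- ceiling(2.5 * sigma)
  xs <- -half:half
  X <- outer(xs, xs, function(x, y) x * cos(theta) + y * sin(theta))
  Y <- outer(xs, xs, function(x, y) -x * sin(theta) + y * cos(theta))
  env <- exp(-(X^2 + Y^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * X / wavelength)
  odd <- env * sin(2 * pi * X / wavelength)
  even <- even - mean(even)   # zero DC so uniform regions give no response
  list(even = even, odd = odd)
}

gabor_energy <- function(m, kerns) {
  # levels smaller than one Gabor wavelength carry no orientation signal
  if (min(dim(m)) < 7L) return(matrix(0, nrow(m), ncol(m)))
  ke <- crop_kernel(kerns$even, dim(m))
  ke <- ke - mean(ke)   # keep zero DC after cropping
  ko <- crop_kernel(kerns$odd, dim(m))
  e <- conv2d(m, ke)
  o <- conv2d(m, ko)
  sqrt(e^2 + o^2)
}

# ---- Centre-surround feature maps ------------------------------------------

CS_CENTERS <- 2:4
CS_DELTAS <- 3:4
OUTPUT_LEVEL <- 4L
N_PYR_LEVELS <- 8L

# |centre - upsampled surround| maps for every (c, s = c + delta) pair,
# rescaled to the output level's dimensions.
center_surround <- function(pyr, out_dim) {
  maps <- list()
  for (cc in CS_CENTERS) {
    for (dd in CS_DELTAS) {
      ss <- cc + dd
      ctr <- pyr[[cc + 1L]]
      sur <- resample_map(pyr[[ss + 1L]], nrow(ctr), ncol(ctr))
      m <- abs(ctr - sur)
      maps[[length(maps) + 1L]] <- resample_map(m, out_dim[1], out_dim[2])
    }
  }
  maps
}

#' Centre-surround feature maps of a movie frame
#'
#' Decomposes an RGB frame into intensity, colour-opponency (red-green and
#' blue-yellow) and four Gabor orientation channels, builds dyadic Gaussian
#' pyramids (levels 0-8), and computes centre-surround contrast maps
#' `|centre - upsampled surround|` for centre levels 2-4 and surround
#' offsets 3-4, all resampled to level-4 resolution: 6 intensity, 12 colour
#' and 24 orientation maps.
#'
#' @param frame height x width x 3 RGB array with values in `[0, 1]`.
#' @return A list with elements `intensity`, `color`, `orientation` (lists
#'   of 2D maps) and `out_dim` (level-4 map dimensions).
#' @export
compute_feature_maps <- function(frame) {
  d <- dim(frame)
  if (length(d) != 3L || d[3] < 3L) stop("frame must be an RGB array")
  min_dim <- 2^N_PYR_LEVELS
  if (min(d[1:2]) < min_dim) {
    stop("frame too small for ", N_PYR_LEVELS, " pyramid levels; minimum ",
         "dimension is ", min_dim, " px")
  }
  ch <- frame_channels(frame)
  out_dim <- c(ceiling(d[1] / 2^OUTPUT_LEVEL), ceiling(d[2] / 2^OUTPUT_LEVEL))

  ipyr <- gaussian_pyramid(ch$I, N_PYR_LEVELS)
  imaps <- center_surround(ipyr, out_dim)

  cmaps <- c(center_surround(gaussian_pyramid(ch$RG, N_PYR_LEVELS), out_dim),
             center_surround(gaussian_pyramid(ch$BY, N_PYR_LEVELS), out_dim))

  omaps <- list()
  for (theta in c(0, 45, 90, 135) * pi / 180) {
    kerns <- gabor_kernels(theta)
    opyr <- lapply(ipyr, gabor_energy, kerns = kerns)
    omaps <- c(omaps, center_surround(opyr, out_dim))
  }
  list(intensity = imaps, color = cmaps, orientation = omaps,
       out_dim = out_dim)
}

# ---- Normalization ----------------------------------------------------------

# Strict 3x3 local maxima (greater than all 8 neighbours); only interior
# pixels, which have a complete neighbourhood, qualify.
local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) return(matrix(FALSE, nr, nc))
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  res <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nb <- pad[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
    res <- res & (m > nb)
  }
  res[c(1L, nr), ] <- FALSE
  res[, c(1L, nc)] <- FALSE
  res
}

#' Max-norm feature-map normalization
#'
#' Rescales a map to `[0, 1]` and multiplies it by `(M - mbar)^2`, where
#' `M` is the global maximum (1 after rescaling) and `mbar` the mean of all
#' other 3x3-strict local maxima. Maps with a single dominant peak keep a
#' large weight; maps with many comparable peaks are suppressed. Constant
#' (including all-zero) maps pass through unchanged.
#'
#' @param m a 2D map.
#' @return The normalized map.
#' @export
normalize_map <- function(m) {
  rng <- range(m)
  # maps that are constant to within numerical noise (e.g. FFT residue on a
  # featureless frame) must not be rescaled into spurious structure
  if (rng[2] - rng[1] < 1e-9) return(m)
  m <- (m - rng[1]) / (rng[2] - rng[1])
  M <- 1
  peaks <- m[local_maxima(m)]
  # exclude one instance of the global maximum; remaining peaks define mbar
  if (length(peaks) && max(peaks) >= M) {
    peaks <- peaks[-which.max(peaks)]
  }
  mbar <- if (length(peaks)) mean(peaks) else 0
  m * (M - mbar)^2
}

# ---- Saliency map & signal --------------------------------------------------

#' Bottom-up visual saliency map of a frame
#'
#' Normalizes each centre-surround feature map, sums them within the
#' intensity, colour and orientation channels into conspicuity maps at
#' level-4 resolution, normalizes each conspicuity map again, and averages
#' the three channels. For a 1024 x 720 frame the map is 64 x 45
#' (`scale_factor` 16).
#'
#' @param frame height x width x 3 RGB array in `[0, 1]`.
#' @return A list of class `saliency_map` with `values` (non-negative 2D
#'   map) and `scale_factor`.
#' @export
compute_saliency_map <- function(frame) {
  fm <- compute_feature_maps(frame)
  conspicuity <- function(maps) {
    s <- Reduce(`+`, lapply(maps, normalize_map))
    normalize_map(s)
  }
  sal <- (conspicuity(fm$intensity) + conspicuity(fm$color) +
            conspicuity(fm$orientation)) / 3
  sal[sal < 0] <- 0
  structure(list(values = sal, scale_factor = 2^OUTPUT_LEVEL),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> %d x %d (width x height), scale 1/%d\n",
              ncol(x$values), nrow(x$values), x$scale_factor))
  invisible(x)
}

#' Saliency maps for every frame of a movie
#'
#' @param movie a `movie_stack`.
#' @return A list of `saliency_map` objects, one per frame.
#' @export
saliency_map_stack <- function(movie) {
  stopifnot(inherits(movie, "movie_stack"))
  lapply(movie$frames, compute_saliency_map)
}

#' Per-TR mean visual saliency signal
#'
#' Bins the frame sequence into TRs of `F = fps * tr_seconds` frames and
#' averages each bin's saliency maps over all frames and all pixels,
#' yielding one scalar per TR. A trailing partial bin is dropped.
#'
#' @param maps a list of `saliency_map` objects (or plain 2D maps).
#' @param fps frames per second.
#' @param tr_seconds sampling interval of the target signal.
#' @return A numeric vector of class `saliency_signal` with attributes
#'   `tr_seconds`, `filtered`, `cutoff_hz`.
#' @export
mean_saliency_signal <- function(maps, fps = 24, tr_seconds = 1) {
  F <- fps * tr_seconds
  if (abs(F - round(F)) > 1e-9) {
    stop("fps * tr_seconds must be an integer number of frames per TR (got ",
         F, ")")
  }
  F <- as.integer(round(F))
  vals <- vapply(maps, function(m) {
    if (inherits(m, "saliency_map")) mean(m$values) else mean(m)
  }, numeric(1))
  n_bins <- length(vals) %/% F
  if (n_bins < 1L) stop("fewer frames than one TR bin")
  s <- colMeans(matrix(vals[seq_len(n_bins * F)], nrow = F))
  saliency_signal(s, tr_seconds = tr_seconds)
}

saliency_signal <- function(values, tr_seconds, filtered = FALSE,
                            cutoff_hz = NULL) {
  structure(as.numeric(values), class = "saliency_signal",
            tr_seconds = tr_seconds, filtered = filtered,
            cutoff_hz = cutoff_hz)
}

#' @export
print.saliency_signal <- function(x, ...) {
  cat(sprintf("<saliency_signal> %d samples, TR = %g s%s\n", length(x),
              attr(x, "tr_seconds"),
              if (isTRUE(attr(x, "filtered")))
                sprintf(", low-pass %g Hz", attr(x, "cutoff_hz")) else ""))
  invisible(x)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Order-5 Butterworth applied forward and backward (zero phase) with odd
#' reflective padding at both ends to suppress edge transients. DC gain is
#' 1, so constant signals and the signal mean are preserved.
#'
#' @param x a `saliency_signal` or plain numeric vector.
#' @param cutoff_hz cutoff frequency, must be below Nyquist.
#' @param tr_seconds sampling interval; taken from the object when `x` is a
#'   `saliency_signal`.
#' @param order filter order.
#' @return Filtered signal of the same class/length.
#' @export
lowpass_filter <- function(x, cutoff_hz = 0.1, tr_seconds = NULL, order = 5L) {
  if (inherits(x, "saliency_signal") && is.null(tr_seconds)) {
    tr_seconds <- attr(x, "tr_seconds")
  }
  if (is.null(tr_seconds)) stop("tr_seconds required for a plain vector")
  fs <- 1 / tr_seconds
  nyq <- fs / 2
  if (cutoff_hz >= nyq) {
    stop("cutoff (", cutoff_hz, " Hz) must be below Nyquist (", nyq, " Hz)")
  }
  v <- as.numeric(x)
  n <- length(v)
  minlen <- 6L * order
  if (n <= minlen) stop("signal too short for filtering (need > ", minlen,
                        " samples)")
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  pad <- min(n - 1L, 3L * 6L * order)
  # odd (point-symmetric) reflection preserves local trend at the edges
  head_ref <- 2 * v[1] - v[(pad + 1L):2]
  tail_ref <- 2 * v[n] - v[(n - 1L):(n - pad)]
  padded <- c(head_ref, v, tail_ref)
  filt <- signal::filtfilt(bf, padded)
  out <- filt[(pad + 1L):(pad + n)]
  if (inherits(x, "saliency_signal")) {
    saliency_signal(out, tr_seconds = tr_seconds, filtered = TRUE,
                    cutoff_hz = cutoff_hz)
  } else {
    out
  }
}
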