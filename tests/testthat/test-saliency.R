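# Frames in these tests are 256 x 256 (the smallest size supporting the
# 8-level pyramid) so each saliency map evaluates in well under a second.

uniform_frame <- function(level = 0.5, n = 256) array(level, c(n, n, 3))

blob_frame <- function(n = 256, cx = 128, cy = 128, sigma = 10,
                       contrast = 0.7, color = c(1, 1, 1), bg = 0.25) {
  spec <- movie_spec(width = n, height = n, fps = 1, duration = 1,
                     background_level = bg,
                     blob_events = list(list(
                       onset_s = 0, offset_s = 1, cx = cx, cy = cy,
                       radius_px = sigma, contrast = contrast,
                       color = color)))
  generate_synthetic_movie(spec)
}

test_that("uniform frames produce (near-)zero feature and saliency maps", {
  fr <- uniform_frame(0.5)
  fm <- compute_feature_maps(fr)
  allmaps <- c(fm$intensity, fm$color, fm$orientation)
  expect_length(fm$intensity, 6)
  expect_length(fm$color, 12)
  expect_length(fm$orientation, 24)
  expect_lt(max(vapply(allmaps, max, numeric(1))), 1e-6)
  sm <- compute_saliency_map(fr)
  expect_lt(max(sm$values), 1e-6)
  expect_true(all(sm$values >= 0))
})

test_that("a pure colour field has no spatial opponency contrast", {
  fr <- uniform_frame(0)
  fr[, , 1] <- 0.8    # pure red field
  fm <- compute_feature_maps(fr)
  expect_lt(max(vapply(fm$color, max, numeric(1))), 1e-6)
})

test_that("frames below the pyramid minimum are rejected", {
  expect_error(compute_feature_maps(array(0.5, c(128, 512, 3))), "256")
})

test_that("map dimensions follow the 1/16 downscale contract", {
  sm <- compute_saliency_map(uniform_frame(0.4, 256))
  expect_equal(dim(sm$values), c(16, 16))
  expect_equal(sm$scale_factor, 16)
  sm2 <- compute_saliency_map(array(0.4, c(720, 1024, 3)))
  expect_equal(dim(sm2$values), c(45, 64))   # 45 high, 64 wide
})

test_that("normalize_map matches a brute-force local-maxima oracle", {
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(runif(20 * 15), 20, 15)
    out <- normalize_map(m)
    # oracle: rescale, scan every interior pixel for strict 3x3 maxima
    r <- (m - min(m)) / (max(m) - min(m))
    peaks <- c()
    for (i in 2:19) for (j in 2:14) {
      nb <- r[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (r[i, j] > max(nb[-5])) peaks <- c(peaks, r[i, j])
    }
    peaks <- peaks[peaks < 1]
    mbar <- if (length(peaks)) mean(peaks) else 0
    expect_equal(out, r * (1 - mbar)^2, tolerance = 1e-12)
  }
})

test_that("normalize_map promotes lone peaks and suppresses many equal peaks", {
  single <- matrix(0, 32, 32)
  single[16, 16] <- 1
  out1 <- normalize_map(single)
  expect_equal(max(out1), 1, tolerance = 1e-12)  # (M - 0)^2 weight retained

  many <- matrix(0, 32, 32)
  many[seq(4, 28, by = 4), 16] <- 1
  many[16, seq(4, 28, by = 4)] <- 1
  out2 <- normalize_map(many)
  expect_lt(max(out2), 0.05)                     # (M - mbar)^2 ~ 0

  z <- matrix(0, 8, 8)
  expect_identical(normalize_map(z), z)          # all-zero passes through
})

test_that("saliency peaks inside the planted blob support", {
  mv <- blob_frame(cx = 180, cy = 70, sigma = 12)
  sm <- compute_saliency_map(mv$frames[[1]])
  peak <- which(sm$values == max(sm$values), arr.ind = TRUE)[1, ]
  # map the level-4 peak back to pixel coordinates and check the mask
  py <- (peak[1] - 0.5) * 16
  px <- (peak[2] - 0.5) * 16
  expect_true(mv$masks[[1]][round(py), round(px)])
})

test_that("saliency is invariant to a global additive pixel constant", {
  mv <- blob_frame(bg = 0.3, contrast = 0.4)
  f1 <- mv$frames[[1]]
  f2 <- pmin(f1 + 0.2, 1)
  s1 <- compute_saliency_map(f1)$values
  s2 <- compute_saliency_map(f2)$values
  expect_lt(max(abs(s1 - s2)) / max(s1), 0.05)
})

test_that("mean saliency signal reduces frames by exact grand means", {
  # toy stack of 3 known 2x2 maps, F = 3 -> single-sample grand mean
  maps <- list(matrix(c(1, 2, 3, 4), 2), matrix(c(5, 6, 7, 8), 2),
               matrix(0, 2, 2))
  s <- mean_saliency_signal(maps, fps = 3, tr_seconds = 1)
  expect_length(s, 1)
  expect_equal(as.numeric(s), mean(c(1:8, 0, 0, 0, 0)))

  # identical frames -> constant signal; trailing partial bin dropped
  maps2 <- rep(list(matrix(2.5, 4, 4)), 50)
  s2 <- mean_saliency_signal(maps2, fps = 24, tr_seconds = 1)
  expect_length(s2, 2)
  expect_equal(as.numeric(s2), c(2.5, 2.5))

  expect_error(mean_saliency_signal(maps, fps = 24, tr_seconds = 0.7),
               "integer")
})

test_that("scaling all maps by k scales the signal by k", {
  set.seed(32)
  maps <- replicate(12, matrix(runif(16), 4), simplify = FALSE)
  s1 <- as.numeric(mean_saliency_signal(maps, fps = 4, tr_seconds = 1))
  maps3 <- lapply(maps, function(m) 3 * m)
  s3 <- as.numeric(mean_saliency_signal(maps3, fps = 4, tr_seconds = 1))
  expect_equal(s3, 3 * s1, tolerance = 1e-12)
})

test_that("low-pass filter passes 0.01 Hz, kills 0.4 Hz, preserves DC", {
  t <- 0:899
  slow <- sin(2 * pi * 0.01 * t)
  y <- lowpass_filter(slow, 0.1, tr_seconds = 1)
  expect_lt(abs(max(abs(y[100:800])) - 1), 0.05)

  fast <- sin(2 * pi * 0.4 * t)
  y2 <- lowpass_filter(fast, 0.1, tr_seconds = 1)
  expect_lt(20 * log10(max(abs(y2[100:800]))), -20)

  const <- rep(3.7, 200)
  expect_equal(lowpass_filter(const, 0.1, tr_seconds = 1), const,
               tolerance = 1e-9)

  expect_error(lowpass_filter(slow, 0.6, tr_seconds = 1), "Nyquist")
  expect_error(lowpass_filter(rnorm(20), 0.1, tr_seconds = 1), "too short")
})

test_that("filtering a saliency_signal records the cutoff", {
  s <- mean_saliency_signal(replicate(240, matrix(runif(4), 2),
                                      simplify = FALSE),
                            fps = 4, tr_seconds = 1)
  f <- lowpass_filter(s, 0.1)
  expect_s3_class(f, "saliency_signal")
  expect_true(attr(f, "filtered"))
  expect_equal(attr(f, "cutoff_hz"), 0.1)
  expect_equal(mean(as.numeric(f)), mean(as.numeric(s)), tolerance = 0.02)
})
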