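# CWT scalograms: frequency localization against an FFT oracle, energy
# behavior, and image rendering contracts.

fft_peak_hz <- function(x, fs) {
  spec <- Mod(stats::fft(x))[2:floor(length(x) / 2)]
  which.max(spec) * fs / length(x)
}

test_that("tones localize to the FFT-oracle row within one grid step", {
  fs <- 500
  t <- (0:4999) / fs
  for (f0 in c(2, 9, 20, 50, 80)) {
    x <- sin(2 * pi * f0 * t)
    sc <- cwt_scalogram(x, fs)
    cwt_row <- which.max(rowMeans(sc$magnitudes))
    oracle_row <- which.min(abs(sc$freqs_hz - fft_peak_hz(x, fs)))
    expect_lte(abs(cwt_row - oracle_row), 1)
  }
})

test_that("an all-zero epoch gives an all-zero scalogram", {
  sc <- cwt_scalogram(numeric(5000), 500)
  expect_true(all(sc$magnitudes == 0))
})

test_that("a two-tone mixture shows local maxima at both tone rows", {
  fs <- 500
  t <- (0:4999) / fs
  x <- sin(2 * pi * 5 * t) + sin(2 * pi * 40 * t)
  sc <- cwt_scalogram(x, fs)
  prof <- rowMeans(sc$magnitudes)
  is_peak <- c(FALSE, diff(sign(diff(prof))) < 0, FALSE)
  peak_freqs <- sc$freqs_hz[is_peak]
  expect_true(any(abs(peak_freqs - 5) / 5 < 0.06))
  expect_true(any(abs(peak_freqs - 40) / 40 < 0.06))
})

test_that("scalogram energy grows monotonically with input amplitude", {
  x <- gen_background(10, 250, seed = 4)
  e <- vapply(c(0.5, 1, 2, 4),
              function(a) scalogram_energy(cwt_scalogram(a * x, 250)),
              numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("NaN samples are rejected with an informative error", {
  x <- numeric(2500); x[17] <- NaN
  expect_error(cwt_scalogram(x, 250), "NaN")
})

test_that("frequency grid spans [1, 100] Hz and magnitudes are non-negative", {
  sc <- cwt_scalogram(gen_background(10, 500, seed = 5), 500)
  expect_gte(min(sc$freqs_hz), 1)
  expect_lte(max(sc$freqs_hz), 100)
  expect_true(all(sc$magnitudes >= 0))
  expect_identical(dim(sc$magnitudes), c(96L, 5000L))
})

test_that("rendering honors the shape contract and scale invariance", {
  sc <- cwt_scalogram(gen_background(10, 250, seed = 6), 250)
  img <- render_scalogram(sc, height = 224, width = 224)
  expect_identical(dim(img), c(224L, 224L, 3L))
  expect_true(all(img >= 0 & img <= 1))
  # doubling all magnitudes under per-image normalization changes nothing
  sc2 <- sc; sc2$magnitudes <- 2 * sc$magnitudes
  expect_identical(render_scalogram(sc, 64, 64), render_scalogram(sc2, 64, 64))
})

test_that("magnitude maps monotonically onto the colormap index", {
  pal <- scalodetect:::scalodetect_colormaps("viridis")
  set.seed(7)
  v <- sort(runif(50))
  idx <- pmin(floor(v * length(pal)) + 1L, length(pal))
  expect_sorted(idx)
  # grayscale map: larger magnitude -> brighter pixel, checked on the image
  sc <- cwt_scalogram(sin(2 * pi * 9 * (0:2499) / 250), 250, n_freqs = 48)
  img <- render_scalogram(sc, 32, 32, colormap = "gray")
  m <- resize_input <- scalodetect:::resize_matrix(sc$magnitudes, 32, 32)
  m <- m[rev(seq_len(32)), ] / max(m)
  ord <- order(as.vector(m))
  expect_sorted(as.vector(img[, , 1])[ord])
})

test_that("a constant scalogram renders as a uniform image without error", {
  sc <- structure(list(magnitudes = matrix(1, 48, 100),
                       freqs_hz = exp(seq(log(1), log(100), length.out = 48)),
                       times_s = seq_len(100) / 250, fs = 250),
                  class = "scalogram")
  img <- render_scalogram(sc, 32, 32)
  expect_equal(length(unique(as.vector(img[, , 1]))), 1L)
  sc$magnitudes[] <- 0
  expect_silent(img0 <- render_scalogram(sc, 32, 32))
})
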