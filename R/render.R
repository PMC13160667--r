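# Scalogram rendering: fixed-size RGB rasters for the image classifier.

.render_cache <- new.env(parent = emptyenv())

# Area-averaging resize matrix mapping n input bins onto m output bins.
# Works for both down- and up-sampling; rows sum to 1. Cached per (n, m).
resize_map <- function(n, m) {
  key <- paste0(n, "x", m)
  hit <- .render_cache[[key]]
  if (!is.null(hit)) return(hit)
  .render_cache[[key]] <- resize_map_build(n, m)
}

resize_map_build <- function(n, m) {
  edges <- seq(0, n, length.out = m + 1)
  A <- matrix(0, m, n)
  for (i in seq_len(m)) {
    lo <- edges[i]; hi <- edges[i + 1]
    j0 <- floor(lo) + 1; j1 <- ceiling(hi)
    for (j in j0:min(j1, n)) {
      A[i, j] <- min(hi, j) - max(lo, j - 1)
    }
    A[i, ] <- A[i, ] / sum(A[i, ])
  }
  A
}

resize_matrix <- function(mat, height, width) {
  A <- resize_map(nrow(mat), height)
  B <- resize_map(ncol(mat), width)
  A %*% mat %*% t(B)
}

scalodetect_colormaps <- function(name, n = 256) {
  key <- paste0("pal_", name, "_", n)
  hit <- .render_cache[[key]]
  if (!is.null(hit)) return(hit)
  .render_cache[[key]] <- scalodetect_colormaps_build(name, n)
}

scalodetect_colormaps_build <- function(name, n) {
  switch(name,
    viridis = grDevices::hcl.colors(n, "viridis"),
    jet = grDevices::colorRampPalette(
      c("#00007F", "blue", "cyan", "yellow", "red", "#7F0000"))(n),
    gray = grDevices::gray(seq(0, 1, length.out = n)),
    stop_arg("unknown colormap: ", name))
}

#' Render a scalogram as a fixed-size RGB image
#'
#' Resizes the magnitude matrix to `height` x `width` by area averaging
#' (high frequencies at the top row, time running left to right), normalizes
#' magnitudes, and maps them through a monotone colormap. Per-image
#' max-normalization is the default, so the rendered image is invariant to
#' overall amplitude scaling; `scaling = "global"` divides by a supplied
#' fixed maximum instead. A constant (degenerate) magnitude matrix renders
#' as a uniform image.
#'
#' @param scal a `scalogram` from [cwt_scalogram()].
#' @param height,width output raster size in pixels (default 64 x 64; use
#'   224 for pretrained-backbone-sized images).
#' @param colormap `"viridis"` (default), `"jet"`, or `"gray"`.
#' @param scaling `"per_image"` (default) or `"global"`.
#' @param global_max magnitude mapped to the top color when
#'   `scaling = "global"`.
#' @return numeric array `height x width x 3` with values in \[0, 1\].
#' @export
render_scalogram <- function(scal, height = 64, width = 64,
                             colormap = "viridis",
                             scaling = c("per_image", "global"),
                             global_max = NULL) {
  stopifnot(inherits(scal, "scalogram"))
  scaling <- match.arg(scaling)
  m <- resize_matrix(scal$magnitudes, height, width)
  m <- m[rev(seq_len(height)), , drop = FALSE]  # top row = highest frequency
  denom <- switch(scaling,
    per_image = max(m),
    global = global_max %||% stop_arg("`global_max` required for global scaling"))
  v <- if (denom > 0) pmin(m / denom, 1) else m * 0
  pal <- scalodetect_colormaps(colormap)
  idx <- pmin(floor(v * length(pal)) + 1L, length(pal))
  rgbkey <- paste0("rgb_", colormap)
  rgb <- .render_cache[[rgbkey]]
  if (is.null(rgb)) {
    rgb <- grDevices::col2rgb(pal) / 255
    .render_cache[[rgbkey]] <- rgb
  }
  img <- array(0, dim = c(height, width, 3))
  for (ch in 1:3) img[, , ch] <- matrix(rgb[ch, idx], height, width)
  img
}

#' Write a rendered scalogram image to PNG
#' @param img array from [render_scalogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scalogram_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' Epoch-to-image convenience wrapper
#'
#' Applies [cwt_scalogram()] and [render_scalogram()] to every epoch of an
#' `epoch_set`, returning the classifier-ready image stack.
#'
#' @param epochs an `epoch_set` from [segment_record()].
#' @param n_freqs,freq_range,omega0 passed to [cwt_scalogram()].
#' @param height,width,colormap,scaling,global_max passed to
#'   [render_scalogram()].
#' @return list of `height x width x 3` arrays, one per epoch.
#' @export
epochs_to_images <- function(epochs, n_freqs = 96, freq_range = c(1, 100),
                             omega0 = 6, height = 64, width = 64,
                             colormap = "viridis",
                             scaling = "per_image", global_max = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  lapply(seq_len(n_epochs(epochs)), function(i) {
    scal <- cwt_scalogram(epochs$samples[i, ], epochs$fs, n_freqs = n_freqs,
                          freq_range = freq_range, omega0 = omega0)
    render_scalogram(scal, height = height, width = width, colormap = colormap,
                     scaling = scaling, global_max = global_max)
  })
}
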