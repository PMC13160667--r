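# Small convolutional network for scalogram images.
#
# A compact conv/ReLU/maxpool stack with a softmax head, implemented with
# im2col-based convolutions on base-R matrices. At the 32-64 px image sizes
# used for scalogram classification the whole model has a few thousand
# parameters and trains in seconds on one CPU, while exposing the same
# train/predict surface a large pretrained backbone would.

.cnn_cache <- new.env(parent = emptyenv())

# Linear-index map for im2col on an H x W x C array with a k x k kernel.
im2col_idx <- function(H, W, C, k) {
  key <- paste(H, W, C, k, sep = "|")
  hit <- .cnn_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- H - k + 1L; Wo <- W - k + 1L
  offs <- as.vector(outer(as.vector(outer(0:(k - 1), (0:(k - 1)) * H, "+")),
                          (0:(C - 1)) * H * W, "+"))
  starts <- as.vector(outer(1:Ho, (1:Wo - 1L) * H, "+"))
  idx <- outer(offs, starts, "+")
  .cnn_cache[[key]] <- list(idx = idx, Ho = Ho, Wo = Wo)
}

conv_forward <- function(x, layer) {
  d <- dim(x); k <- layer$k
  m <- im2col_idx(d[1], d[2], d[3], k)
  cols <- matrix(x[m$idx], nrow = nrow(m$idx))
  out <- layer$W %*% cols + layer$b
  list(out = array(t(out), c(m$Ho, m$Wo, nrow(layer$W))), cols = cols,
       in_dim = d)
}

conv_backward <- function(dout, layer, cache) {
  d <- cache$in_dim; k <- layer$k
  F_ <- nrow(layer$W); kk <- k * k
  Ho <- dim(dout)[1]; Wo <- dim(dout)[2]
  dO <- t(matrix(dout, Ho * Wo, F_))
  dW <- dO %*% t(cache$cols)
  db <- rowSums(dO)
  # gradient w.r.t. input: full convolution of dout with rotated kernels
  pad <- k - 1L
  dp <- array(0, c(Ho + 2L * pad, Wo + 2L * pad, F_))
  dp[pad + seq_len(Ho), pad + seq_len(Wo), ] <- dout
  m <- im2col_idx(dim(dp)[1], dim(dp)[2], F_, k)
  colsP <- matrix(dp[m$idx], nrow = nrow(m$idx))
  W2 <- matrix(layer$W[layer$rot_idx], d[3], kk * F_)
  dx <- array(t(W2 %*% colsP), c(d[1], d[2], d[3]))
  list(dx = dx, dW = dW, db = db)
}

# Permutation turning W (F x kk*C) into the rotated, channel-swapped
# W2 (C x kk*F) used by the input-gradient full convolution.
rot_index <- function(F_, C, k) {
  kk <- k * k
  idx <- integer(C * kk * F_)
  for (c in seq_len(C)) for (f in seq_len(F_)) for (p in seq_len(kk)) {
    # W2[c, (f-1)*kk + p] = W[f, (c-1)*kk + (kk + 1 - p)]
    idx[c + ((f - 1) * kk + p - 1) * C] <-
      f + ((c - 1) * kk + kk - p) * F_
  }
  idx
}

relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_backward <- function(dout, cache) dout * cache$mask

maxpool_forward <- function(x) {
  d <- dim(x)
  H2 <- 2L * (d[1] %/% 2L); W2 <- 2L * (d[2] %/% 2L)
  x <- x[seq_len(H2), seq_len(W2), , drop = FALSE]
  io <- seq(1L, H2, 2L); ie <- seq(2L, H2, 2L)
  jo <- seq(1L, W2, 2L); je <- seq(2L, W2, 2L)
  a <- list(x[io, jo, , drop = FALSE], x[ie, jo, , drop = FALSE],
            x[io, je, , drop = FALSE], x[ie, je, , drop = FALSE])
  m <- pmax(a[[1]], a[[2]], a[[3]], a[[4]])
  list(out = m, a = a, m = m, in_dim = d, H2 = H2, W2 = W2)
}

maxpool_backward <- function(dout, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  H2 <- cache$H2; W2 <- cache$W2
  io <- seq(1L, H2, 2L); ie <- seq(2L, H2, 2L)
  jo <- seq(1L, W2, 2L); je <- seq(2L, W2, 2L)
  slots <- list(list(io, jo), list(ie, jo), list(io, je), list(ie, je))
  taken <- array(FALSE, dim(cache$m))
  for (s in 1:4) {
    hit <- (cache$a[[s]] == cache$m) & !taken
    taken <- taken | hit
    g <- dout * hit
    dx[slots[[s]][[1]], slots[[s]][[2]], ] <-
      dx[slots[[s]][[1]], slots[[s]][[2]], ] + g
  }
  dx
}

cnn_init <- function(input_dim, channels = c(8, 16, 32), k = 3L,
                     n_classes = 2L, seed = NULL) {
  with_seed(seed, {
    layers <- list()
    d <- input_dim
    cin <- d[3]
    for (f in channels) {
      if (d[1] < k + 1L || d[2] < k + 1L) {
        stop_arg("image too small for a ", length(channels),
                 "-layer backbone; enlarge images or use fewer channels")
      }
      fan_in <- k * k * cin
      layers[[length(layers) + 1L]] <- list(
        type = "conv", k = k,
        W = matrix(stats::rnorm(f * fan_in, sd = sqrt(2 / fan_in)), f, fan_in),
        b = numeric(f),
        rot_idx = rot_index(f, cin, k))
      d <- c((d[1] - k + 1L) %/% 2L, (d[2] - k + 1L) %/% 2L, f)
      cin <- f
    }
    n_flat <- prod(d)
    layers[[length(layers) + 1L]] <- list(
      type = "dense",
      W = matrix(stats::rnorm(n_classes * n_flat, sd = sqrt(2 / n_flat)),
                 n_classes, n_flat),
      b = numeric(n_classes))
    list(layers = layers, input_dim = input_dim, flat_dim = d)
  })
}

cnn_forward <- function(net, x, keep_cache = FALSE) {
  caches <- list()
  for (li in seq_along(net$layers)) {
    layer <- net$layers[[li]]
    if (layer$type == "conv") {
      cc <- conv_forward(x, layer)
      rc <- relu_forward(cc$out)
      pc <- maxpool_forward(rc$out)
      x <- pc$out
      if (keep_cache) caches[[li]] <- list(conv = cc, relu = rc, pool = pc)
    } else {
      flat <- as.vector(x)
      z <- as.vector(layer$W %*% flat + layer$b)
      if (keep_cache) caches[[li]] <- list(flat = flat, x_dim = dim(x))
      x <- z
    }
  }
  z <- x - max(x)
  p <- exp(z) / sum(exp(z))
  list(probs = p, caches = caches)
}

cnn_backward <- function(net, fwd, y_onehot) {
  grads <- vector("list", length(net$layers))
  delta <- fwd$probs - y_onehot  # softmax cross-entropy gradient
  for (li in rev(seq_along(net$layers))) {
    layer <- net$layers[[li]]
    cache <- fwd$caches[[li]]
    if (layer$type == "dense") {
      grads[[li]] <- list(dW = outer(delta, cache$flat), db = delta)
      delta <- array(as.vector(t(layer$W) %*% delta), cache$x_dim)
    } else {
      delta <- maxpool_backward(delta, cache$pool)
      delta <- relu_backward(delta, cache$relu)
      cb <- conv_backward(delta, layer, cache$conv)
      grads[[li]] <- list(dW = cb$dW, db = cb$db)
      delta <- cb$dx
    }
  }
  grads
}

# Adam with per-layer moment estimates; grads accumulated over a minibatch.
cnn_train_loop <- function(net, images, y, epochs = 30, lr = 3e-3,
                           batch_size = 8, seed = NULL) {
  n <- length(images)
  oneh <- diag(2)[y, , drop = FALSE]
  mstate <- lapply(net$layers, function(l) list(
    mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (bs in split(ord, ceiling(seq_along(ord) / batch_size))) {
        acc <- NULL
        for (i in bs) {
          fwd <- cnn_forward(net, images[[i]], keep_cache = TRUE)
          g <- cnn_backward(net, fwd, oneh[i, ])
          if (is.null(acc)) acc <- g else {
            for (li in seq_along(g)) {
              acc[[li]]$dW <- acc[[li]]$dW + g[[li]]$dW
              acc[[li]]$db <- acc[[li]]$db + g[[li]]$db
            }
          }
        }
        step <- step + 1
        for (li in seq_along(net$layers)) {
          dW <- acc[[li]]$dW / length(bs)
          db <- acc[[li]]$db / length(bs)
          st <- mstate[[li]]
          st$mW <- b1 * st$mW + (1 - b1) * dW
          st$vW <- b2 * st$vW + (1 - b2) * dW^2
          st$mb <- b1 * st$mb + (1 - b1) * db
          st$vb <- b2 * st$vb + (1 - b2) * db^2
          mstate[[li]] <- st
          corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
          net$layers[[li]]$W <- net$layers[[li]]$W -
            lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
          net$layers[[li]]$b <- net$layers[[li]]$b -
            lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
        }
      }
    }
  })
  net
}

cnn_predict_probs <- function(net, images) {
  t(vapply(images, function(im) cnn_forward(net, im)$probs, numeric(2)))
}
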