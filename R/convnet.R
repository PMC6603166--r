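# Minimal convolutional forward/backward machinery.
#
# Feature maps travel through these routines as N x C matrices, N = h*w spatial
# positions in column-major order (row index fastest), matching how R lays out
# an h x w x C array. Convolutions are 3x3, stride 1, zero-padded "same",
# realized as a gather (im2col) followed by one matrix multiply; pooling is
# 2x2 average with stride 2. Only the gradient with respect to the *input* is
# ever needed (weights stay fixed during style transfer), which keeps the
# backward pass to a matrix multiply plus a scatter.

.idx_cache <- new.env(parent = emptyenv())

# 3x3 neighborhood offsets, fixed ordering shared by im2col and kernel packing
conv_offsets <- function() expand.grid(dr = -1:1, dc = -1:1)

# N x 9 matrix of row indices into rbind(0, x): entry 1 means the zero pad row
conv_index <- function(h, w) {
  key <- sprintf("c%d_%d", h, w)
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  offs <- conv_offsets()
  r <- rep.int(seq_len(h), w)
  c <- rep(seq_len(w), each = h)
  idx <- matrix(1L, nrow = h * w, ncol = 9L)
  for (o in seq_len(9L)) {
    rr <- r + offs$dr[o]; cc <- c + offs$dc[o]
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    idx[ok, o] <- (cc[ok] - 1L) * h + rr[ok] + 1L
  }
  .idx_cache[[key]] <- idx
  idx
}

# list of 4 disjoint index vectors selecting each corner of the 2x2 windows
pool_index <- function(h, w) {
  key <- sprintf("p%d_%d", h, w)
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  h2 <- h %/% 2L; w2 <- w %/% 2L
  r2 <- rep.int(seq_len(h2), w2)
  c2 <- rep(seq_len(w2), each = h2)
  sets <- list()
  k <- 1L
  for (b in 0:1) for (a in 0:1) {
    sets[[k]] <- (2L * c2 - 2L + b) * h + (2L * r2 - 1L + a)
    k <- k + 1L
  }
  out <- list(sets = sets, h2 = h2, w2 = w2)
  .idx_cache[[key]] <- out
  out
}

conv_forward <- function(x, wmat, bias, idx) {
  n <- nrow(x); cin <- ncol(x)
  xpad <- rbind(0, x)
  xpat <- matrix(0, nrow = n, ncol = 9L * cin)
  for (o in seq_len(9L)) {
    xpat[, ((o - 1L) * cin + 1L):(o * cin)] <- xpad[idx[, o], , drop = FALSE]
  }
  y <- xpat %*% wmat
  if (!is.null(bias)) y <- sweep(y, 2L, bias, "+")
  y
}

conv_backward <- function(dy, wmat, cin, idx) {
  dxpat <- dy %*% t(wmat)
  dxpad <- matrix(0, nrow = nrow(dy) + 1L, ncol = cin)
  for (o in seq_len(9L)) {
    rows <- idx[, o]
    blk <- dxpat[, ((o - 1L) * cin + 1L):(o * cin), drop = FALSE]
    # per offset the in-bounds targets are distinct; duplicates land only on
    # the discarded pad row
    dxpad[rows, ] <- dxpad[rows, , drop = FALSE] + blk
  }
  dxpad[-1L, , drop = FALSE]
}

pool_forward <- function(x, pidx) {
  s <- pidx$sets
  (x[s[[1]], , drop = FALSE] + x[s[[2]], , drop = FALSE] +
     x[s[[3]], , drop = FALSE] + x[s[[4]], , drop = FALSE]) / 4
}

pool_backward <- function(dy, pidx, n, cin) {
  dx <- matrix(0, nrow = n, ncol = cin)
  g <- dy / 4
  for (s in pidx$sets) dx[s, ] <- g
  dx
}

# pack a 3x3 x Cin x Cout kernel array into the (9*Cin) x Cout matrix layout
# used by conv_forward
pack_kernel <- function(kernel) {
  stopifnot(length(dim(kernel)) == 4L, dim(kernel)[1] == 3L, dim(kernel)[2] == 3L)
  cin <- dim(kernel)[3]; cout <- dim(kernel)[4]
  offs <- conv_offsets()
  wmat <- matrix(0, nrow = 9L * cin, ncol = cout)
  for (o in seq_len(9L)) {
    wmat[((o - 1L) * cin + 1L):(o * cin), ] <-
      kernel[offs$dr[o] + 2L, offs$dc[o] + 2L, , ]
  }
  wmat
}

# Forward pass through `layers` (a list of conv/relu/pool descriptors),
# stopping once every layer named in `record` has been captured. Returns the
# captured activations and, when `keep_cache`, what the backward pass needs.
net_forward <- function(layers, x, h, w, record, keep_cache = FALSE) {
  captured <- list()
  cache <- if (keep_cache) vector("list", length(layers)) else NULL
  n_wanted <- length(record)
  last <- 0L
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      idx <- conv_index(h, w)
      x <- conv_forward(x, ly$wmat, ly$bias, idx)
      if (keep_cache) cache[[i]] <- list(type = "conv", name = ly$name,
                                         wmat = ly$wmat, cin = ly$in_channels,
                                         h = h, w = w)
    } else if (ly$type == "relu") {
      mask <- x > 0
      x <- x * mask
      if (keep_cache) cache[[i]] <- list(type = "relu", name = ly$name, mask = mask)
    } else if (ly$type == "pool") {
      pidx <- pool_index(h, w)
      n_in <- h * w
      x <- pool_forward(x, pidx)
      if (keep_cache) cache[[i]] <- list(type = "pool", name = ly$name,
                                         h = h, w = w, n_in = n_in)
      h <- pidx$h2; w <- pidx$w2
    }
    if (ly$name %in% record) {
      captured[[ly$name]] <- structure(x, h = h, w = w)
      if (length(captured) == n_wanted) { last <- i; break }
    }
    last <- i
  }
  list(captured = captured, cache = if (keep_cache) cache[seq_len(last)] else NULL)
}

# Backward pass: `inject` maps layer names to gradients w.r.t. that layer's
# output; returns the gradient w.r.t. the network input.
net_backward <- function(cache, inject) {
  g <- NULL
  for (i in rev(seq_along(cache))) {
    cc <- cache[[i]]
    if (is.null(cc)) next
    gi <- inject[[cc$name]]
    if (!is.null(gi)) g <- if (is.null(g)) gi else g + gi
    if (is.null(g)) next
    g <- switch(cc$type,
      conv = conv_backward(g, cc$wmat, cc$cin, conv_index(cc$h, cc$w)),
      relu = g * cc$mask,
      pool = pool_backward(g, pool_index(cc$h, cc$w), cc$n_in, ncol(g))
    )
  }
  g
}
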