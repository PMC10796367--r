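# Internal numeric and RNG helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation; keeps results in [1, 2^31 - 2].
derive_seed <- function(seed, k) {
  ((as.double(seed) %% 1048573) * 2039 + as.double(k) * 7919 + 1) %% 2147483646 + 1
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Coerce an image-like object to a numeric [0,1] H x W x 3 array.
as_pixels <- function(x) {
  if (is.list(x) && !is.null(x$pixels)) x <- x$pixels
  if (length(dim(x)) != 3L || dim(x)[3] < 3L)
    stop("invalid input: expected an RGB array (H x W x 3)", call. = FALSE)
  x <- x[, , 1:3, drop = FALSE]
  storage.mode(x) <- "double"
  if (max(x) > 1 + 1e-9) x <- x / 255
  x
}

# ITU-R BT.601 luminance of an RGB array -> H x W matrix.
luminance <- function(pixels) {
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

# Block-mean pooling of an H x W x C array to a g x g x C array.
pool_blocks <- function(img, g) {
  d <- dim(img)
  h <- d[1]; w <- d[2]; nc <- d[3]
  if (h < g || w < g) stop("image smaller than pooling grid", call. = FALSE)
  rb <- floor((seq_len(h) - 1) * g / h) + 1L
  cb <- floor((seq_len(w) - 1) * g / w) + 1L
  rn <- tabulate(rb, g); cn <- tabulate(cb, g)
  out <- array(0, c(g, g, nc))
  denom <- outer(rn, cn)
  for (k in seq_len(nc)) {
    m <- rowsum(img[, , k], rb, reorder = TRUE)
    m <- t(rowsum(t(m), cb, reorder = TRUE))
    out[, , k] <- m / denom
  }
  out
}

# Vectorized bilinear resize of an H x W x C array (pixel-center alignment).
resize_bilinear <- function(img, h2, w2) {
  d <- dim(img)
  h <- d[1]; w <- d[2]; nc <- d[3]
  ys <- (seq_len(h2) - 0.5) * h / h2 + 0.5
  xs <- (seq_len(w2) - 0.5) * w / w2 + 0.5
  y0 <- pmin(pmax(floor(ys), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xs), 1), w); x1 <- pmin(x0 + 1, w)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, c(h2, w2, nc))
  for (k in seq_len(nc)) {
    m <- img[, , k]
    out[, , k] <-
      ((1 - wy) %o% (1 - wx)) * m[y0, x0, drop = FALSE] +
      ((1 - wy) %o% wx)       * m[y0, x1, drop = FALSE] +
      (wy %o% (1 - wx))       * m[y1, x0, drop = FALSE] +
      (wy %o% wx)             * m[y1, x1, drop = FALSE]
  }
  out
}

# Vectorized HSV -> RGB; h, s, v equal-length vectors in [0,1] (h wraps).
# Returns a 3 x n matrix (rows r, g, b).
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t_ <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t_, v)))))
  g <- ifelse(i == 0, t_, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t_,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  rbind(r, g, b)
}

# Row-wise numerically stable softmax.
softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# x * log(x) with the 0 * log(0) := 0 convention.
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
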