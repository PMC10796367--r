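#' The six augmentation operators
#'
#' Canonical operator names, in the order they are applied when selected:
#' flip, rotation, contrast, scaling, hsv, noise.
#'
#' @return Character vector of the six operator names.
#' @export
augment_ops <- function() c("flip", "rotation", "contrast", "scaling", "hsv", "noise")

#' Default augmentation parameter ranges
#'
#' Ranges for the seeded parameter draws of each operator: horizontal and
#' vertical flips each with probability `flip_p`; rotation uniformly from
#' `rot_angles` (degrees, multiples of 90 so tiles stay square); contrast
#' gain about mid-gray in `contrast`; scale factor in `scale` followed by
#' center crop / white pad back to the input shape; HSV jitter of at most
#' `hue` (wrapping), `sat`, `val`; Gaussian noise standard deviation drawn
#' from `noise_sd` in 8-bit intensity units.
#'
#' @return Named list of parameter ranges.
#' @export
augment_params <- function() {
  list(flip_p = 0.5,
       rot_angles = c(0, 90, 180, 270),
       contrast = c(0.8, 1.2),
       scale = c(0.9, 1.1),
       hue = 0.05, sat = 0.2, val = 0.2,
       noise_sd = c(0, 8))
}

rotate90 <- function(img, k) {
  k <- k %% 4L
  if (k == 0L) return(img)
  d3 <- dim(img)[3]
  out <- img
  for (i in seq_len(k)) {
    h <- dim(out)[1]; w <- dim(out)[2]
    rot <- array(0, c(w, h, d3))
    for (ch in seq_len(d3)) rot[, , ch] <- t(out[h:1, , ch])
    out <- rot
  }
  out
}

# Resize by factor s, then center-crop (s > 1) or center-pad with white
# background (s < 1) back to the original shape.
scale_to_shape <- function(img, s) {
  h <- dim(img)[1]; w <- dim(img)[2]
  h2 <- max(1L, round(h * s)); w2 <- max(1L, round(w * s))
  if (h2 == h && w2 == w) return(img)
  r <- resize_bilinear(img, h2, w2)
  out <- array(1, c(h, w, dim(img)[3]))
  if (h2 >= h) {
    off_r <- (h2 - h) %/% 2L; off_c <- (w2 - w) %/% 2L
    out <- r[(off_r + 1L):(off_r + h), (off_c + 1L):(off_c + w), , drop = FALSE]
  } else {
    off_r <- (h - h2) %/% 2L; off_c <- (w - w2) %/% 2L
    out[(off_r + 1L):(off_r + h2), (off_c + 1L):(off_c + w2), ] <- r
  }
  out
}

#' Apply seeded random augmentations to a tile image
#'
#' Applies the selected operators (in the canonical [augment_ops()] order)
#' with parameters drawn from a generator seeded by `seed`, so the output is
#' bit-reproducible for identical `(seed, ops, params, input)`. The output
#' always has the input's shape: rotations are multiples of 90 degrees and
#' scaling crops or pads back to shape.
#'
#' @param pixels RGB pixel array (any square or rectangular size) or a
#'   `tile_record`.
#' @param ops Non-empty subset of [augment_ops()].
#' @param seed Integer seed for the parameter draws.
#' @param params Parameter ranges, see [augment_params()].
#' @return Augmented pixel array with the same dimensions as the input.
#' @export
augment <- function(pixels, ops = augment_ops(), seed = 1L, params = augment_params()) {
  px <- as_pixels(pixels)
  if (length(ops) == 0L) stop("ops must be non-empty", call. = FALSE)
  bad <- setdiff(ops, augment_ops())
  if (length(bad) > 0L)
    stop("unknown augmentation op(s): ", paste(bad, collapse = ", "), call. = FALSE)
  with_local_seed(seed, {
    for (op in intersect(augment_ops(), ops)) {
      px <- switch(op,
        flip = {
          if (runif(1) < params$flip_p) px <- px[, dim(px)[2]:1, , drop = FALSE]
          if (runif(1) < params$flip_p) px <- px[dim(px)[1]:1, , , drop = FALSE]
          px
        },
        rotation = rotate90(px, sample(params$rot_angles, 1L) / 90),
        contrast = {
          g <- runif(1, params$contrast[1], params$contrast[2])
          clamp01(0.5 + (px - 0.5) * g)
        },
        scaling = scale_to_shape(px, runif(1, params$scale[1], params$scale[2])),
        hsv = {
          d <- dim(px)
          m <- matrix(px, nrow = d[1] * d[2], ncol = 3)
          hsv <- grDevices::rgb2hsv(t(m), maxColorValue = 1)
          h <- (hsv[1, ] + runif(1, -params$hue, params$hue)) %% 1
          s <- clamp01(hsv[2, ] + runif(1, -params$sat, params$sat))
          v <- clamp01(hsv[3, ] + runif(1, -params$val, params$val))
          array(t(hsv_to_rgb(h, s, v)), d)
        },
        noise = {
          sdv <- runif(1, params$noise_sd[1], params$noise_sd[2]) / 255
          clamp01(px + array(rnorm(length(px), 0, sdv), dim(px)))
        }
      )
    }
    px
  })
}

#' Build an augmented view pair for contrastive training
#'
#' Generates two independent augmentations of the same tile using sub-seeds
#' derived deterministically from `seed`, so the pair is reproducible. The
#' two views feed the shared-weight twin encoder.
#'
#' @param tile A `tile_record` or pixel array.
#' @param seed Integer pair seed.
#' @param ops,params Passed to [augment()].
#' @return List with `view_a`, `view_b`, `source`, `seed`.
#' @export
make_pair <- function(tile, seed = 1L, ops = augment_ops(), params = augment_params()) {
  px <- as_pixels(tile)
  list(view_a = augment(px, ops, derive_seed(seed, 0L), params),
       view_b = augment(px, ops, derive_seed(seed, 1L), params),
       source = tile, seed = seed)
}
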