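# Model: shared-weight encoder + instance head + cluster head.
#
# tiny-mlp backbone:
#   features x = vec(block-mean pool to g x g x 3) - 0.5        (p = 3 g^2)
#   encoder   h1 = relu(x W1 + b1);  z = h1 W2 + b2             (N x d)
#   instance  i1 = relu(z Wi1 + bi1); h = i1 Wi2 + bi2          (N x p_i)
#   cluster   c1 = relu(z Wc1 + bc1); y = softmax(c1 Wc2 + bc2) (N x M)

#' Initialize a DL-CC model
#'
#' Creates the weight tensors of the encoder and both contrastive heads with
#' seeded He-style initialization. Only the `"tiny-mlp"` backbone ships with
#' a trainable implementation; the `"resnet50"` profile is a configuration
#' contract for published-scale runs and has no bundled encoder weights.
#'
#' @param config A [dlcc_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `dlcc_model` object.
#' @export
dlcc_init <- function(config, seed = 1L) {
  if (!inherits(config, "dlcc_config")) stop("config must be a dlcc_config")
  if (config$backbone != "tiny-mlp")
    stop("backbone '", config$backbone, "' has no bundled encoder; ",
         "use dlcc_desk_config() for a trainable profile", call. = FALSE)
  p <- 3L * config$pool_grid^2
  he <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  weights <- with_local_seed(seed, list(
    W1 = he(p, config$hidden),                 b1 = numeric(config$hidden),
    W2 = he(config$hidden, config$d),          b2 = numeric(config$d),
    Wi1 = he(config$d, config$head_hidden),    bi1 = numeric(config$head_hidden),
    Wi2 = he(config$head_hidden, config$instance_proj_dim),
    bi2 = numeric(config$instance_proj_dim),
    Wc1 = he(config$d, config$head_hidden),    bc1 = numeric(config$head_hidden),
    Wc2 = he(config$head_hidden, config$M),    bc2 = numeric(config$M)
  ))
  structure(list(config = config, weights = weights, seed = seed,
                 trained = FALSE), class = "dlcc_model")
}

add_bias <- function(m, b) m + matrix(b, nrow(m), length(b), byrow = TRUE)

# Batch of images -> backbone input features (N x p matrix).
# Accepts an N x H x W x 3 array, a list of tile_records/arrays, or an
# already-featurized N x p matrix (p must match).
backbone_features <- function(model, batch) {
  g <- model$config$pool_grid
  p <- 3L * g^2
  if (is.matrix(batch)) {
    if (ncol(batch) != p) stop("feature matrix has wrong width", call. = FALSE)
    return(batch)
  }
  imgs <- if (is.list(batch)) {
    lapply(batch, as_pixels)
  } else if (length(dim(batch)) == 4L) {
    lapply(seq_len(dim(batch)[1]), function(i) batch[i, , , , drop = TRUE])
  } else if (length(dim(batch)) == 3L) {
    list(as_pixels(batch))
  } else stop("invalid input: expected image batch", call. = FALSE)
  t(vapply(imgs, function(im) as.vector(pool_blocks(as_pixels(im), g)) - 0.5,
           numeric(p)))
}

# Full forward pass; returns all intermediate activations for backprop.
dlcc_forward <- function(model, x) {
  W <- model$weights
  a1 <- add_bias(x %*% W$W1, W$b1);   h1 <- pmax(a1, 0)
  z  <- add_bias(h1 %*% W$W2, W$b2)
  ai <- add_bias(z %*% W$Wi1, W$bi1); i1 <- pmax(ai, 0)
  h  <- add_bias(i1 %*% W$Wi2, W$bi2)
  ac <- add_bias(z %*% W$Wc1, W$bc1); c1 <- pmax(ac, 0)
  lg <- add_bias(c1 %*% W$Wc2, W$bc2)
  y  <- softmax_rows(lg)
  list(x = x, a1 = a1, h1 = h1, z = z, ai = ai, i1 = i1, h = h,
       ac = ac, c1 = c1, logits = lg, y = y)
}

#' Encode a batch of tiles into d-dimensional representations
#'
#' Both views of a pair must be encoded with the same model state; the twin
#' encoder shares all weights, which this single-model design enforces by
#' construction. Deterministic: identical inputs give identical embeddings.
#'
#' @param batch `N x H x W x 3` array, list of tiles, or `N x p` feature matrix.
#' @param model A `dlcc_model`.
#' @return `N x d` matrix of representations `z`.
#' @export
encode <- function(batch, model) {
  x <- backbone_features(model, batch)
  fw <- dlcc_forward(model, x)
  fw$z
}

#' Soft cluster labels for a batch
#'
#' The cluster head's softmax output: an `N x M` matrix whose rows are
#' probability vectors over the M clusters ("soft labels").
#'
#' @inheritParams encode
#' @return `N x M` soft-label matrix.
#' @export
soft_labels <- function(batch, model) {
  x <- backbone_features(model, batch)
  dlcc_forward(model, x)$y
}

#' Assign tiles to histomorphological phenotype clusters
#'
#' Argmax of the cluster head's soft label per tile; exact ties resolve to
#' the lowest cluster index. Assignment is per-tile (no batch coupling at
#' inference). Requires a trained model unless `allow_untrained = TRUE`.
#'
#' @inheritParams encode
#' @param allow_untrained Permit assignment from a freshly initialized model
#'   (useful for smoke tests).
#' @return Integer vector of 0-based cluster ids in `[0, M)`.
#' @export
assign_clusters <- function(batch, model, allow_untrained = FALSE) {
  if (!isTRUE(model$trained) && !allow_untrained)
    stop("model state error: model has not been trained ",
         "(pass allow_untrained = TRUE to override)", call. = FALSE)
  y <- soft_labels(batch, model)
  max.col(y, ties.method = "first") - 1L
}
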