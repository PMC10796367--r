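#' DL-CC model configuration
#'
#' The default profile mirrors the published setting: a ResNet50 twin
#' encoder mapping 224x224 tiles into a `d = 2048`-dimensional
#' representation, an instance-level contrastive head projecting to 128
#' dimensions, and a cluster-level contrastive head with `M = 50` soft-label
#' outputs; tiles pass a 60% tissue-coverage filter and six augmentation
#' operators generate views. The desk-scale profile (see
#' [dlcc_desk_config()]) swaps the backbone for a small trainable encoder.
#'
#' @param backbone Encoder name: `"resnet50"` (published-scale profile; a
#'   pretrained convolutional stack is not bundled, so this profile is a
#'   configuration contract only) or `"tiny-mlp"` (trainable desk-scale
#'   encoder: block-mean pixel pooling to a `pool_grid` x `pool_grid` x 3
#'   grid followed by a two-layer perceptron).
#' @param d Representation dimension (default 2048).
#' @param M Number of clusters / soft-label dimension (default 50).
#' @param instance_proj_dim Output dimension of the instance head (default 128).
#' @param tau_instance,tau_cluster Positive softmax temperatures of the two
#'   NT-Xent heads (defaults 0.5 and 1.0).
#' @param lambda_offdiag Weight of the off-diagonal (redundancy) term of the
#'   representation loss; must be >= 0 (default 0.005).
#' @param alpha Mixing weight in `[0, 1]` between the contrastive losses and
#'   the representation loss (default 0.5).
#' @param tile_size Tile side in pixels (default 224).
#' @param min_coverage Tissue-coverage retention threshold (default 0.60).
#' @param augmentations Operator names used to build view pairs (default all
#'   six, see [augment_ops()]).
#' @param normalization Cross-correlation scaling mode, see
#'   [cross_correlation()].
#' @param input_size Resolution at which the trainer augments views
#'   (tiny-mlp backbone; tiles are block-mean downscaled to this size once).
#' @param pool_grid Pooling grid of the tiny-mlp backbone.
#' @param hidden Hidden width of the tiny-mlp encoder.
#' @param head_hidden Hidden width of the two contrastive heads.
#' @return A `dlcc_config` object.
#' @export
dlcc_config <- function(backbone = "resnet50", d = 2048L, M = 50L,
                        instance_proj_dim = 128L,
                        tau_instance = 0.5, tau_cluster = 1.0,
                        lambda_offdiag = 0.005, alpha = 0.5,
                        tile_size = 224L, min_coverage = 0.60,
                        augmentations = augment_ops(),
                        normalization = c("batch_bn_over_N", "paper_1_over_d"),
                        input_size = 32L, pool_grid = 8L,
                        hidden = 128L, head_hidden = 64L) {
  normalization <- match.arg(normalization)
  stopifnot(M >= 2, d >= M)
  if (tau_instance <= 0 || tau_cluster <= 0)
    stop("temperatures must be positive", call. = FALSE)
  if (lambda_offdiag < 0) stop("lambda_offdiag must be >= 0", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  structure(list(backbone = backbone, d = as.integer(d), M = as.integer(M),
                 instance_proj_dim = as.integer(instance_proj_dim),
                 tau_instance = tau_instance, tau_cluster = tau_cluster,
                 lambda_offdiag = lambda_offdiag, alpha = alpha,
                 tile_size = as.integer(tile_size), min_coverage = min_coverage,
                 augmentations = augmentations, normalization = normalization,
                 input_size = as.integer(input_size),
                 pool_grid = as.integer(pool_grid),
                 hidden = as.integer(hidden),
                 head_hidden = as.integer(head_hidden)),
            class = "dlcc_config")
}

#' Desk-scale DL-CC configuration
#'
#' A small, CPU-trainable profile: the `"tiny-mlp"` backbone with `d = 64`
#' and `M = 5` clusters, used throughout the test fixtures and the worked
#' examples. All other semantics (losses, heads, augmentation) are identical
#' to the published-scale profile.
#'
#' @param M,d,instance_proj_dim,... Overridable; passed to [dlcc_config()].
#' @return A `dlcc_config` object.
#' @export
dlcc_desk_config <- function(M = 5L, d = 64L, instance_proj_dim = 32L, ...) {
  dlcc_config(backbone = "tiny-mlp", d = d, M = M,
              instance_proj_dim = instance_proj_dim, ...)
}

#' @export
print.dlcc_config <- function(x, ...) {
  cat("DL-CC config:", x$backbone, sprintf("(d=%d, M=%d)\n", x$d, x$M))
  cat("  heads: instance ->", x$instance_proj_dim,
      sprintf("(tau=%.3g), cluster -> %d (tau=%.3g)\n",
              x$tau_instance, x$M, x$tau_cluster))
  cat(sprintf("  lambda=%.4g alpha=%.3g tile=%d min_coverage=%.2f\n",
              x$lambda_offdiag, x$alpha, x$tile_size, x$min_coverage))
  cat("  augmentations:", paste(x$augmentations, collapse = ", "), "\n")
  invisible(x)
}
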