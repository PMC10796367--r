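# The three DL-CC loss components: redundancy-reduction representation loss
# on the cross-correlation of the two views' embeddings, instance-level
# NT-Xent over samples, and cluster-level NT-Xent over soft-label columns
# with an entropy anti-collapse term.

BN_EPS <- 1e-8

# Column-wise batch standardization (mean 0, biased variance 1, eps-stabilized).
standardize_cols <- function(z) {
  mu <- colMeans(z)
  zc <- sweep(z, 2, mu)
  v <- colMeans(zc^2)
  s <- sqrt(v + BN_EPS)
  list(zhat = sweep(zc, 2, s, "/"), mu = mu, s = s)
}

#' Cross-correlation matrix of two embedding views
#'
#' Each column of each view is standardized over the batch (mean 0,
#' variance 1), then `c = standardized(z_a)^T standardized(z_b)` is scaled by
#' `1/N` (default, making the diagonal a true per-feature correlation with
#' target 1) or by `1/d` (literal published scaling, retained as a fidelity
#' mode).
#'
#' @param z_a,z_b `N x d` embedding matrices of the two augmented views.
#' @param normalization `"batch_bn_over_N"` (default) or `"paper_1_over_d"`.
#' @return `d x d` cross-correlation matrix.
#' @export
cross_correlation <- function(z_a, z_b,
                              normalization = c("batch_bn_over_N", "paper_1_over_d")) {
  normalization <- match.arg(normalization)
  if (!is.matrix(z_a) || !is.matrix(z_b) || !all(dim(z_a) == dim(z_b)))
    stop("z_a and z_b must be matrices of identical shape", call. = FALSE)
  n <- nrow(z_a)
  if (n < 2L) stop("degenerate batch: N >= 2 required (batch variance undefined)",
                   call. = FALSE)
  za <- standardize_cols(z_a)$zhat
  zb <- standardize_cols(z_b)$zhat
  denom <- if (normalization == "batch_bn_over_N") n else ncol(z_a)
  crossprod(za, zb) / denom
}

#' Redundancy-reduction representation loss
#'
#' `sum_i (c_ii - 1)^2 + lambda * sum_{i<j} c_ij^2`: the diagonal term pulls
#' each feature's cross-view correlation to 1 (invariance), the strictly
#' upper-triangular term decorrelates distinct features (redundancy
#' reduction). Zero exactly when the diagonal is all 1 and the upper
#' triangle all 0.
#'
#' @param c_mat Square cross-correlation matrix.
#' @param lambda_offdiag Off-diagonal weight, must be >= 0.
#' @return Non-negative scalar loss.
#' @export
representation_loss <- function(c_mat, lambda_offdiag = 0.005) {
  if (!is.matrix(c_mat) || nrow(c_mat) != ncol(c_mat))
    stop("c must be a square matrix", call. = FALSE)
  if (lambda_offdiag < 0) stop("lambda_offdiag must be >= 0", call. = FALSE)
  sum((diag(c_mat) - 1)^2) + lambda_offdiag * sum(c_mat[upper.tri(c_mat)]^2)
}

# Row-wise L2 normalization with zero-row guard.
l2_normalize_rows <- function(m) {
  r <- sqrt(rowSums(m^2))
  r[r < 1e-12] <- 1
  m / r
}

# Shared NT-Xent over a stack of 2K vectors with positives k <-> k + K.
# Returns mean over the 2K anchors of
#   -log( exp(s(anchor, positive)/tau) / sum_{other != anchor} exp(s/tau) ).
ntxent_stack <- function(V, tau) {
  K2 <- nrow(V)
  K <- K2 %/% 2L
  S <- tcrossprod(V) / tau
  diag(S) <- -Inf                      # exclude self from the candidate set
  pos <- c((K + 1L):K2, 1L:K)
  m <- apply(S, 1, max)
  lse <- m + log(rowSums(exp(S - m)))
  mean(lse - S[cbind(seq_len(K2), pos)])
}

#' Instance-level NT-Xent contrastive loss
#'
#' Rows of both projections are L2-normalized internally; each of the 2N
#' samples is an anchor whose sole positive is its counterpart in the other
#' view, with cosine similarity divided by `tau_instance` as logits over the
#' remaining 2N - 1 candidates. Returns the average of the per-sample terms
#' over both views. At N = 1 the only candidate is the positive, so the loss
#' is exactly 0.
#'
#' @param h_a,h_b `N x p` instance-head projections of the two views.
#' @param tau_instance Positive temperature.
#' @return Non-negative scalar loss.
#' @export
instance_loss <- function(h_a, h_b, tau_instance = 0.5) {
  if (!is.matrix(h_a)) h_a <- rbind(h_a)
  if (!is.matrix(h_b)) h_b <- rbind(h_b)
  if (!all(dim(h_a) == dim(h_b)))
    stop("h_a and h_b must have identical shape", call. = FALSE)
  n <- nrow(h_a)
  if (n == 0L) stop("empty batch", call. = FALSE)
  if (n == 1L) return(0)
  V <- l2_normalize_rows(rbind(h_a, h_b))
  ntxent_stack(V, tau_instance)
}

#' Cluster-level NT-Xent contrastive loss with entropy term
#'
#' Treats each cluster's N-vector of soft assignment probabilities (one
#' column of the soft-label matrix) as a unit; the 2M columns from both
#' views form the contrastive stack, with the same cluster index in the
#' other view as the positive. From the contrastive average the entropy
#' `H(Y) = -sum_i [P_a(i) ln P_a(i) + P_b(i) ln P_b(i)]` of the mean
#' assignment probabilities is subtracted, discouraging collapse of all
#' tiles into few clusters. Bounded below by `-2 ln M`.
#'
#' @param y_a,y_b `N x M` soft-label matrices; rows must sum to 1.
#' @param tau_cluster Positive temperature.
#' @return Scalar loss (may be negative).
#' @export
cluster_loss <- function(y_a, y_b, tau_cluster = 1.0) {
  if (!is.matrix(y_a) || !is.matrix(y_b) || !all(dim(y_a) == dim(y_b)))
    stop("y_a and y_b must be matrices of identical shape", call. = FALSE)
  if (max(abs(rowSums(y_a) - 1)) > 1e-6 || max(abs(rowSums(y_b) - 1)) > 1e-6)
    stop("invalid input: soft-label rows must sum to 1", call. = FALSE)
  m <- ncol(y_a)
  V <- l2_normalize_rows(t(cbind(y_a, y_b)))   # 2M x N stack of columns
  contrastive <- ntxent_stack(V, tau_cluster)
  p_a <- colMeans(y_a); p_b <- colMeans(y_b)
  entropy <- -(sum(xlogx(p_a)) + sum(xlogx(p_b)))
  contrastive - entropy
}

#' Total DL-CC training objective
#'
#' `(instance + cluster) * (1 - alpha) + representation * alpha`.
#'
#' @param instance,cluster,representation The three finite loss components.
#' @param alpha Mixing weight in `[0, 1]`.
#' @return Scalar total loss.
#' @export
total_loss <- function(instance, cluster, representation, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (!all(is.finite(c(instance, cluster, representation))))
    stop("loss components must be finite", call. = FALSE)
  (instance + cluster) * (1 - alpha) + representation * alpha
}
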