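# Analytic gradients of the three losses and of the full model objective.
# All formulas are exact (the batch-standardization backward accounts for the
# epsilon inside the standard deviation) and are checked against central
# finite differences in the test suite.

# Backward through column-wise batch standardization.
# g: dL/dzhat (N x d); zhat, s from standardize_cols().
bn_backward <- function(g, zhat, s) {
  dx <- sweep(g, 2, colMeans(g)) - sweep(zhat, 2, colMeans(g * zhat), "*")
  sweep(dx, 2, s, "/")
}

# dL/dz_a, dL/dz_b of representation_loss(cross_correlation(z_a, z_b)).
grad_representation <- function(z_a, z_b, lambda_offdiag = 0.005,
                                normalization = "batch_bn_over_N") {
  n <- nrow(z_a); d <- ncol(z_a)
  sa <- standardize_cols(z_a); sb <- standardize_cols(z_b)
  denom <- if (normalization == "batch_bn_over_N") n else d
  c_mat <- crossprod(sa$zhat, sb$zhat) / denom
  G <- matrix(0, d, d)
  G[upper.tri(G)] <- 2 * lambda_offdiag * c_mat[upper.tri(c_mat)]
  diag(G) <- 2 * (diag(c_mat) - 1)
  ga_hat <- (sb$zhat %*% t(G)) / denom
  gb_hat <- (sa$zhat %*% G) / denom
  list(ga = bn_backward(ga_hat, sa$zhat, sa$s),
       gb = bn_backward(gb_hat, sb$zhat, sb$s),
       c_mat = c_mat)
}

# Backward through row-wise L2 normalization.
# g: dL/dVn; V raw rows, Vn normalized rows.
l2_backward <- function(g, V) {
  r <- sqrt(rowSums(V^2))
  small <- r < 1e-12
  r[small] <- 1
  Vn <- V / r
  out <- (g - Vn * rowSums(g * Vn)) / r
  out[small, ] <- g[small, ]
  out
}

# dL/dV (raw stack, 2K x p) of ntxent_stack(l2_normalize_rows(V), tau),
# together with the loss value.
grad_ntxent_stack <- function(V, tau) {
  K2 <- nrow(V)
  K <- K2 %/% 2L
  Vn <- l2_normalize_rows(V)
  S <- tcrossprod(Vn) / tau
  diag(S) <- -Inf
  pos <- c((K + 1L):K2, 1L:K)
  m <- apply(S, 1, max)
  P <- exp(S - m)
  P <- P / rowSums(P)
  loss <- mean((m + log(rowSums(exp(S - m)))) - S[cbind(seq_len(K2), pos)])
  A <- P
  A[cbind(seq_len(K2), pos)] <- A[cbind(seq_len(K2), pos)] - 1
  A <- A / K2
  gVn <- ((A + t(A)) %*% Vn) / tau
  list(loss = loss, gV = l2_backward(gVn, V))
}

# dL/dh_a, dL/dh_b of instance_loss.
grad_instance <- function(h_a, h_b, tau_instance = 0.5) {
  n <- nrow(h_a)
  if (n == 1L)
    return(list(ga = matrix(0, 1, ncol(h_a)), gb = matrix(0, 1, ncol(h_b)),
                loss = 0))
  r <- grad_ntxent_stack(rbind(h_a, h_b), tau_instance)
  list(ga = r$gV[1:n, , drop = FALSE],
       gb = r$gV[(n + 1L):(2L * n), , drop = FALSE],
       loss = r$loss)
}

# dL/dy_a, dL/dy_b of cluster_loss (contrastive over columns minus entropy).
grad_cluster <- function(y_a, y_b, tau_cluster = 1.0) {
  n <- nrow(y_a); m <- ncol(y_a)
  r <- grad_ntxent_stack(t(cbind(y_a, y_b)), tau_cluster)
  gC <- t(r$gV)                                   # N x 2M
  gy_a <- gC[, 1:m, drop = FALSE]
  gy_b <- gC[, (m + 1L):(2L * m), drop = FALSE]
  p_a <- colMeans(y_a); p_b <- colMeans(y_b)
  ent_a <- ifelse(p_a > 0, log(p_a) + 1, 0)       # d(-H)/dP = log P + 1
  ent_b <- ifelse(p_b > 0, log(p_b) + 1, 0)
  gy_a <- gy_a + matrix(ent_a, n, m, byrow = TRUE) / n
  gy_b <- gy_b + matrix(ent_b, n, m, byrow = TRUE) / n
  entropy <- -(sum(xlogx(p_a)) + sum(xlogx(p_b)))
  list(ga = gy_a, gb = gy_b, loss = r$loss - entropy)
}

# Loss components of one augmented batch pair (feature-matrix inputs).
dlcc_batch_loss <- function(model, xa, xb) {
  cfg <- model$config
  fa <- dlcc_forward(model, xa)
  fb <- dlcc_forward(model, xb)
  c_mat <- cross_correlation(fa$z, fb$z, cfg$normalization)
  rep_l <- representation_loss(c_mat, cfg$lambda_offdiag)
  ins_l <- instance_loss(fa$h, fb$h, cfg$tau_instance)
  clu_l <- cluster_loss(fa$y, fb$y, cfg$tau_cluster)
  list(instance = ins_l, cluster = clu_l, representation = rep_l,
       total = total_loss(ins_l, clu_l, rep_l, cfg$alpha))
}

zero_like <- function(W) lapply(W, function(w) if (is.matrix(w)) w * 0 else numeric(length(w)))

# Full analytic gradient of the total objective w.r.t. every weight, with
# gradients from both (shared-weight) views accumulated.
dlcc_batch_grad <- function(model, xa, xb) {
  cfg <- model$config
  W <- model$weights
  fa <- dlcc_forward(model, xa)
  fb <- dlcc_forward(model, xb)

  gr <- grad_representation(fa$z, fb$z, cfg$lambda_offdiag, cfg$normalization)
  rep_l <- representation_loss(gr$c_mat, cfg$lambda_offdiag)
  gi <- grad_instance(fa$h, fb$h, cfg$tau_instance)
  gc <- grad_cluster(fa$y, fb$y, cfg$tau_cluster)

  a <- cfg$alpha
  grads <- zero_like(W)

  backprop_view <- function(fw, gz_rep, gh, gy) {
    # instance head
    gh <- gh * (1 - a)
    gi1 <- gh %*% t(W$Wi2)
    gai <- gi1 * (fw$ai > 0)
    grads$Wi2 <<- grads$Wi2 + crossprod(fw$i1, gh)
    grads$bi2 <<- grads$bi2 + colSums(gh)
    grads$Wi1 <<- grads$Wi1 + crossprod(fw$z, gai)
    grads$bi1 <<- grads$bi1 + colSums(gai)
    gz <- gai %*% t(W$Wi1)
    # cluster head (softmax backward on logits)
    gy <- gy * (1 - a)
    glg <- fw$y * (gy - rowSums(gy * fw$y))
    gc1 <- glg %*% t(W$Wc2)
    gac <- gc1 * (fw$ac > 0)
    grads$Wc2 <<- grads$Wc2 + crossprod(fw$c1, glg)
    grads$bc2 <<- grads$bc2 + colSums(glg)
    grads$Wc1 <<- grads$Wc1 + crossprod(fw$z, gac)
    grads$bc1 <<- grads$bc1 + colSums(gac)
    gz <- gz + gac %*% t(W$Wc1)
    # representation loss contribution enters at z directly
    gz <- gz + gz_rep * a
    # encoder
    gh1 <- gz %*% t(W$W2)
    ga1 <- gh1 * (fw$a1 > 0)
    grads$W2 <<- grads$W2 + crossprod(fw$h1, gz)
    grads$b2 <<- grads$b2 + colSums(gz)
    grads$W1 <<- grads$W1 + crossprod(fw$x, ga1)
    grads$b1 <<- grads$b1 + colSums(ga1)
    invisible(NULL)
  }

  backprop_view(fa, gr$ga, gi$ga, gc$ga)
  backprop_view(fb, gr$gb, gi$gb, gc$gb)

  list(grads = grads,
       losses = list(instance = gi$loss, cluster = gc$loss,
                     representation = rep_l,
                     total = total_loss(gi$loss, gc$loss, rep_l, a)))
}
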