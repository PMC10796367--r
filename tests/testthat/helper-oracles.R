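# Independent brute-force oracles used to check the package implementations.
# Everything here is written as plainly as possible (loops, enumerations)
# and never calls the code paths under test.

# Classic Otsu: maximize between-class variance over a 256-bin histogram of
# grayscale values in [0, 1]; returns the fraction of pixels strictly below
# the selected threshold.
oracle_otsu_fraction <- function(gray, levels = 256) {
  h <- tabulate(pmin(floor(gray * levels) + 1, levels), levels)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[levels]
  bc <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  bc[!is.finite(bc)] <- 0
  thr <- mids[which.max(bc)]
  mean(gray < thr)
}

# Per-entry loop cross-correlation with column standardization.
oracle_cross_corr <- function(za, zb, denom_n = TRUE, eps = 1e-8) {
  std <- function(z) {
    out <- z
    for (j in seq_len(ncol(z))) {
      mu <- mean(z[, j])
      v <- mean((z[, j] - mu)^2)
      out[, j] <- (z[, j] - mu) / sqrt(v + eps)
    }
    out
  }
  a <- std(za); b <- std(zb)
  d <- ncol(za)
  cm <- matrix(0, d, d)
  denom <- if (denom_n) nrow(za) else d
  for (i in seq_len(d)) for (j in seq_len(d))
    cm[i, j] <- sum(a[, i] * b[, j]) / denom
  cm
}

oracle_representation_loss <- function(cm, lambda) {
  d <- nrow(cm)
  s <- 0
  for (i in seq_len(d)) s <- s + (cm[i, i] - 1)^2
  off <- 0
  for (i in seq_len(d - 1)) for (j in (i + 1):d) off <- off + cm[i, j]^2
  s + lambda * off
}

# NT-Xent by full enumeration over the 2K stack with positives k <-> k + K.
oracle_ntxent <- function(V, tau) {
  V <- V / sqrt(rowSums(V^2))
  K2 <- nrow(V)
  K <- K2 / 2
  total <- 0
  for (k in seq_len(K2)) {
    pos <- if (k <= K) k + K else k - K
    s_pos <- sum(V[k, ] * V[pos, ]) / tau
    denom <- 0
    for (l in seq_len(K2)) {
      if (l == k) next
      denom <- denom + exp(sum(V[k, ] * V[l, ]) / tau)
    }
    total <- total - log(exp(s_pos) / denom)
  }
  total / K2
}

oracle_instance_loss <- function(ha, hb, tau) {
  if (nrow(ha) == 1) return(0)
  oracle_ntxent(rbind(ha, hb), tau)
}

oracle_cluster_loss <- function(ya, yb, tau) {
  contr <- oracle_ntxent(t(cbind(ya, yb)), tau)
  ent <- 0
  for (y in list(ya, yb)) {
    pm <- colMeans(y)
    for (p in pm) if (p > 0) ent <- ent - p * log(p)
  }
  contr - ent
}

# Plain binary-label Youden cutoff with the "high iff score > c" rule and
# ties resolved to the lower threshold.
oracle_binary_youden <- function(scores, labels) {
  cand <- sort(unique(scores))
  best_j <- -Inf
  best_c <- NA
  for (cc in cand) {
    sens <- mean(scores[labels == 1] > cc)
    spec <- mean(scores[labels == 0] <= cc)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_c <- cc
    }
  }
  best_c
}

# Two-group log-rank by direct observed-minus-expected computation.
oracle_logrank_2g <- function(time, event, group) {
  g <- unique(group)
  stopifnot(length(g) == 2)
  times <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in times) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Tiny helper: simulate exponential PH survival for screening tests.
sim_surv <- function(lp, base_rate = 0.2, censor_at = Inf) {
  t <- rexp(length(lp), base_rate * exp(lp))
  cens <- if (is.finite(censor_at)) runif(length(lp), 0, censor_at) else rep(Inf, length(lp))
  list(time = pmin(t, cens), event = as.integer(t <= cens))
}

# A small textured tile for augmentation tests.
textured_tile <- function(size = 32, seed = 5) {
  pathoclust::gen_tile(pathoclust::texture_spec(1, hue = 0.7, density = 60,
                                                radius = c(2, 5)),
                       seed = seed, size = size)
}
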