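# Loss components versus brute-force oracles, exact identities, and
# analytic-gradient checks against finite differences.

test_that("cross-correlation matches construction and loop oracles", {
  # orthogonal design: z_b = z_a with orthogonal standardized columns -> identity
  A <- matrix(c(1, 1, 1, -1), 2, 2)
  H8 <- kronecker(A, kronecker(A, A))        # 8x8 Hadamard
  z <- H8[, 2:5] * 2 + 5                     # zero-mean orthogonal columns, affine-shifted
  cm <- cross_correlation(z, z)
  expect_equal(cm, diag(4), tolerance = 1e-6)

  expect_equal(diag(cross_correlation(z, -z)), rep(-1, 4), tolerance = 1e-6)

  set.seed(13)
  za <- matrix(rnorm(8 * 4), 8, 4)
  zb <- matrix(rnorm(8 * 4), 8, 4)
  expect_equal(cross_correlation(za, zb), oracle_cross_corr(za, zb),
               tolerance = 1e-10)
  expect_equal(cross_correlation(za, zb, "paper_1_over_d"),
               oracle_cross_corr(za, zb, denom_n = FALSE), tolerance = 1e-10)

  expect_error(cross_correlation(za[1, , drop = FALSE], zb[1, , drop = FALSE]),
               "degenerate")
})

test_that("representation loss matches hand values and the loop oracle", {
  expect_identical(representation_loss(diag(3), 0.005), 0)
  expect_identical(representation_loss(matrix(0, 2, 2), 123), 2)
  expect_equal(representation_loss(matrix(c(1, 0.3, 0.5, 1), 2, 2), 0.005),
               0.005 * 0.5^2)   # lower-triangle 0.3 excluded by i < j
  expect_error(representation_loss(diag(2), -1), ">= 0")

  set.seed(2)
  for (d in c(3, 6, 8)) {
    cm <- matrix(rnorm(d * d), d, d)
    expect_equal(representation_loss(cm, 0.01),
                 oracle_representation_loss(cm, 0.01), tolerance = 1e-12)
    expect_gte(representation_loss(cm, 0.01), 0)
  }
})

test_that("instance loss matches enumeration, hand value, and symmetries", {
  expect_identical(instance_loss(matrix(1, 1, 3), matrix(2, 1, 3)), 0)

  # N = 2, identical views, orthogonal samples, tau = 1
  h <- rbind(c(1, 0), c(0, 1))
  expect_equal(instance_loss(h, h, 1), -log(exp(1) / (exp(1) + 2)),
               tolerance = 1e-12)

  set.seed(3)
  for (n in c(2, 5, 8)) {
    ha <- matrix(rnorm(n * 4), n, 4)
    hb <- matrix(rnorm(n * 4), n, 4)
    expect_equal(instance_loss(ha, hb, 0.5),
                 oracle_instance_loss(ha, hb, 0.5), tolerance = 1e-8)
    expect_gte(instance_loss(ha, hb, 0.5), 0)
    # joint row permutation leaves the loss unchanged
    perm <- sample(n)
    expect_equal(instance_loss(ha[perm, ], hb[perm, ], 0.5),
                 instance_loss(ha, hb, 0.5), tolerance = 1e-12)
  }

  # pulling the positives together (views identical) lowers the loss
  set.seed(4)
  ha <- matrix(rnorm(6 * 4), 6, 4)
  hb <- matrix(rnorm(6 * 4), 6, 4)
  expect_lt(instance_loss(ha, ha, 0.5), instance_loss(ha, hb, 0.5))
})

test_that("cluster loss matches enumeration and penalizes collapse", {
  # balanced one-hot assignments: H(Y) = 2 ln M exactly
  M <- 4; N <- 8
  y <- diag(M)[rep(1:M, each = N / M), ]
  contr <- oracle_ntxent(t(cbind(y, y)), 1)
  expect_equal(cluster_loss(y, y, 1), contr - 2 * log(M), tolerance = 1e-10)

  set.seed(5)
  for (m in c(2, 4)) {
    ya <- pathoclust:::softmax_rows(matrix(rnorm(6 * m), 6, m))
    yb <- pathoclust:::softmax_rows(matrix(rnorm(6 * m), 6, m))
    expect_equal(cluster_loss(ya, yb, 1), oracle_cluster_loss(ya, yb, 1),
                 tolerance = 1e-8)
    expect_gte(cluster_loss(ya, yb, 1), -2 * log(m))
  }

  # collapsing all mass into one cluster raises the loss
  collapsed <- matrix(rep(c(1, rep(0, M - 1)), N), N, M, byrow = TRUE)
  expect_gt(cluster_loss(collapsed, collapsed, 1), cluster_loss(y, y, 1))

  bad <- matrix(0.3, 4, 3)
  expect_error(cluster_loss(bad, bad, 1), "sum to 1")
})

test_that("total loss is the printed affine combination", {
  expect_identical(total_loss(2, 3, 4, alpha = 1), 4)
  expect_identical(total_loss(2, 3, 4, alpha = 0), 5)
  expect_identical(total_loss(2, 3, 4, alpha = 0.25), 4.75)
  expect_error(total_loss(1, 1, 1, alpha = 1.5), "\\[0, 1\\]")
  expect_error(total_loss(NaN, 1, 1, alpha = 0.5), "finite")
})

test_that("analytic gradients match central finite differences", {
  fd_entry <- function(f, x, i, eps = 1e-6) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    (f(x1) - f(x2)) / (2 * eps)
  }
  set.seed(11)
  za <- matrix(rnorm(8 * 5), 8, 5); zb <- matrix(rnorm(8 * 5), 8, 5)
  gr <- pathoclust:::grad_representation(za, zb, 0.01)
  for (i in sample(length(za), 4)) {
    fd <- fd_entry(function(z) representation_loss(cross_correlation(z, zb), 0.01), za, i)
    expect_equal(gr$ga[i], fd, tolerance = 1e-4)
    fd <- fd_entry(function(z) representation_loss(cross_correlation(za, z), 0.01), zb, i)
    expect_equal(gr$gb[i], fd, tolerance = 1e-4)
  }

  ha <- matrix(rnorm(5 * 3), 5, 3); hb <- matrix(rnorm(5 * 3), 5, 3)
  gi <- pathoclust:::grad_instance(ha, hb, 0.5)
  for (i in sample(length(ha), 4)) {
    fd <- fd_entry(function(h) instance_loss(h, hb, 0.5), ha, i)
    expect_equal(gi$ga[i], fd, tolerance = 1e-4)
  }

  ya <- pathoclust:::softmax_rows(matrix(rnorm(5 * 3), 5, 3))
  yb <- pathoclust:::softmax_rows(matrix(rnorm(5 * 3), 5, 3))
  gc_ <- pathoclust:::grad_cluster(ya, yb, 1)
  # finite differences move along the simplex tangent (rows renormalized)
  for (i in sample(length(ya), 3)) {
    eps <- 1e-6
    y1 <- ya; y1[i] <- y1[i] + eps; y1 <- y1 / rowSums(y1)
    y2 <- ya; y2[i] <- y2[i] - eps; y2 <- y2 / rowSums(y2)
    fd <- (cluster_loss(y1, yb, 1) - cluster_loss(y2, yb, 1)) / (2 * eps)
    # project analytic gradient the same way (row-sum constraint)
    r <- (i - 1) %% nrow(ya) + 1
    proj <- gc_$ga[i] - sum(gc_$ga[r, ] * ya[r, ])
    expect_equal(proj, fd, tolerance = 1e-3)
  }
})

test_that("full-model weight gradient matches finite differences", {
  cfg <- dlcc_desk_config(d = 16, M = 3, instance_proj_dim = 8,
                          pool_grid = 4, hidden = 12, head_hidden = 8)
  model <- dlcc_init(cfg, seed = 7)
  set.seed(21)
  p <- 3 * cfg$pool_grid^2
  xa <- matrix(rnorm(8 * p, 0, 0.3), 8, p)
  xb <- xa + matrix(rnorm(8 * p, 0, 0.1), 8, p)
  bg <- pathoclust:::dlcc_batch_grad(model, xa, xb)
  for (nm in c("W1", "W2", "Wi2", "Wc1", "b1", "bc2")) {
    i <- sample(length(model$weights[[nm]]), 1)
    eps <- 1e-5
    m1 <- model; m1$weights[[nm]][i] <- m1$weights[[nm]][i] + eps
    m2 <- model; m2$weights[[nm]][i] <- m2$weights[[nm]][i] - eps
    fd <- (pathoclust:::dlcc_batch_loss(m1, xa, xb)$total -
           pathoclust:::dlcc_batch_loss(m2, xa, xb)$total) / (2 * eps)
    expect_equal(bg$grads[[nm]][i], fd, tolerance = 1e-4)
  }
})
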