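test_that("graph convolution reduces to the plain product on identity", {
  H <- matrix(rnorm(12), 4, 3)
  expect_equal(gcn_forward(diag(3), diag(4), H, "linear"), H)
  # hand-set 2x1 weight on a 3-node toy graph
  A <- normalize_adjacency(rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))
  H2 <- rbind(c(1, 2), c(3, 4), c(5, 6))
  W <- cbind(c(2, -1))
  expect_equal(gcn_forward(W, A, H2, "linear"), (A %*% H2) %*% W)
  # sigmoid output is confined to (0, 1)
  out <- gcn_forward(matrix(rnorm(4), 2, 2), A, H2, "sigmoid")
  expect_true(all(out > 0 & out < 1))
  expect_error(gcn_forward(matrix(0, 5, 2), A, H2), "expects 5 input columns")
})

test_that("graph convolution is node-permutation equivariant", {
  set.seed(8)
  for (i in 1:5) {
    p <- 20
    X <- matrix(rnorm(p * 4), p)
    A <- knn_graph(X, 3)$norm_adjacency
    W <- matrix(rnorm(4 * 2), 4)
    perm <- sample(p)
    P <- diag(p)[perm, ]
    out <- gcn_forward(W, A, X, "relu")
    out_perm <- gcn_forward(W, P %*% A %*% t(P), P %*% X, "relu")
    expect_equal(out_perm, P %*% out, tolerance = 1e-12)
  }
})

test_that("reparameterization recovers mu when noise vanishes", {
  mu <- matrix(rnorm(6), 2, 3); sigma <- matrix(exp(rnorm(6)), 2, 3)
  expect_equal(reparameterize(mu, sigma, eps = mu * 0), mu)
  expect_equal(reparameterize(mu, matrix(1e-300, 2, 3),
                              eps = matrix(1, 2, 3)), mu)
  expect_error(reparameterize(mu, -sigma), "strictly positive")
})

test_that("reparameterized samples have the posterior moments", {
  set.seed(123)
  n <- 1e5
  z <- reparameterize(matrix(0, n, 1), matrix(2, n, 1))
  se_mean <- 2 / sqrt(n)
  expect_lt(abs(mean(z) - 0), 3 * se_mean)
  se_var <- 4 * sqrt(2 / (n - 1))
  expect_lt(abs(var(as.vector(z)) - 4), 3 * se_var)
})

test_that("inference network forward pass honours its contracts", {
  set.seed(4)
  p <- 12; d <- 6; h <- 16
  X <- matrix(runif(p * d), p)
  A <- knn_graph(X, 3)$norm_adjacency
  q <- vemlda:::init_gnnq(d, h)
  fw1 <- vemlda:::gnnq_forward(q, A, X, training = FALSE)
  fw2 <- vemlda:::gnnq_forward(q, A, X, training = FALSE)
  # eval mode is deterministic and Z collapses to the posterior mean
  expect_identical(fw1$X_prime, fw2$X_prime)
  expect_identical(fw1$z, fw1$mu)
  expect_equal(dim(fw1$mu), c(p, h))
  expect_equal(dim(fw1$X_prime), dim(X))
  expect_true(all(fw1$sigma > 0))
  expect_true(all(fw1$X_prime > 0 & fw1$X_prime < 1))
  expect_error(vemlda:::gnnq_forward(q, A, X[-1, ]), "misaligned")
})

test_that("label network forward pass honours its contracts", {
  set.seed(5)
  p <- 10; n_lab <- 7; h <- 16
  Y <- matrix(rbinom(p * n_lab, 1, 0.2), p)
  A <- knn_graph(matrix(rnorm(p * 3), p), 3)$norm_adjacency
  pn <- vemlda:::init_gnnp(n_lab, h)
  fw <- vemlda:::gnnp_forward(pn, A, Y, training = FALSE)
  expect_equal(dim(fw$z_prime), c(p, h))
  expect_equal(dim(fw$F), dim(Y))
  expect_true(all(fw$F > 0 & fw$F < 1))
  expect_identical(fw$F, vemlda:::gnnp_forward(pn, A, Y, training = FALSE)$F)
  expect_true(all(is.finite(fw$F)))
})

# Full-network gradient checks: the training loss is re-evaluated under a
# pinned RNG stream so dropout masks and reparameterization noise are
# identical across finite-difference probes.
test_that("inference-network backprop matches finite differences", {
  set.seed(6)
  p <- 6; d <- 4; h <- 5
  X <- matrix(runif(p * d), p)
  Xb <- matrix(rbinom(p * d, 1, 0.4), p)
  A <- knn_graph(matrix(rnorm(p * 2), p), 2)$norm_adjacency
  q <- vemlda:::init_gnnq(d, h)
  Zd <- matrix(rnorm(3 * h), 3)
  Y <- matrix(rbinom(p * 3, 1, 0.3), p, 3)
  w <- 0.4; beta <- 0.7

  for (family in c("gaussian", "bernoulli")) {
    Xuse <- if (family == "gaussian") X else Xb
    loss_fn <- function(params) {
      fw <- vemlda:::with_seed(99,
        vemlda:::gnnq_forward(params, A, Xuse, training = TRUE,
                              dropout = 0.3))
      recon <- if (family == "gaussian") gaussian_recon_loss(Xuse, fw$X_prime)
               else vemlda:::bce_sum(Xuse, fw$X_prime)
      w * (recon + kl_loss(fw$mu, fw$sigma)) +
        beta * cotrain_loss(fw$z, Zd, Y)
    }
    fw <- vemlda:::with_seed(99,
      vemlda:::gnnq_forward(q, A, Xuse, training = TRUE, dropout = 0.3))
    dZ <- beta * vemlda:::grad_cotrain(fw$z, Zd, Y)$Z_l
    grads <- vemlda:::gnnq_backward(q, fw, A, Xuse, family, w, dZ)
    for (nm in names(q)) {
      fd <- fd_grad(function(Wm) {
        q2 <- q; q2[[nm]] <- Wm; loss_fn(q2)
      }, q[[nm]], h = 1e-5)
      expect_grad_close(grads[[nm]], fd, tol = 1e-4)
    }
  }
})

test_that("label-network backprop matches finite differences", {
  set.seed(7)
  p <- 6; n_lab <- 4; h <- 5
  Y <- matrix(rbinom(p * n_lab, 1, 0.3), p)
  A <- knn_graph(matrix(rnorm(p * 2), p), 2)$norm_adjacency
  pn <- vemlda:::init_gnnp(n_lab, h)
  Zt <- matrix(rnorm(p * h), p)
  w <- 0.6; gamma <- 0.8
  loss_fn <- function(params) {
    fw <- vemlda:::with_seed(77,
      vemlda:::gnnp_forward(params, A, Y, training = TRUE, dropout = 0.3))
    w * (vemlda:::bce_sum(Y, fw$F) + gamma * manifold_loss(fw$z_prime, Zt))
  }
  fw <- vemlda:::with_seed(77,
    vemlda:::gnnp_forward(pn, A, Y, training = TRUE, dropout = 0.3))
  grads <- vemlda:::gnnp_backward(pn, fw, A, Y, w, gamma, Zt)
  for (nm in names(pn)) {
    fd <- fd_grad(function(Wm) {
      p2 <- pn; p2[[nm]] <- Wm; loss_fn(p2)
    }, pn[[nm]], h = 1e-5)
    expect_grad_close(grads[[nm]], fd, tol = 1e-4)
  }
})

test_that("forward passes stay finite for unit-interval inputs", {
  set.seed(9)
  for (i in 1:5) {
    p <- 15; d <- 8
    X <- matrix(runif(p * d), p)
    A <- knn_graph(X, 4)$norm_adjacency
    q <- vemlda:::init_gnnq(d, 12)
    fw <- vemlda:::with_seed(i, vemlda:::gnnq_forward(q, A, X, TRUE, 0.5))
    expect_true(all(is.finite(fw$X_prime)), all(is.finite(fw$z)))
  }
})
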