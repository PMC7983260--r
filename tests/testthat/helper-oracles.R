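# Independent brute-force oracles and small fixture builders used across
# the suite.  These stay deliberately naive (pairwise enumeration, full
# sorts) so they cannot share bugs with the implementation paths.

# Mann-Whitney AUROC: average over every (positive, negative) pair, ties
# counting one half.
oracle_auroc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Non-interpolated average precision by direct re-counting at every
# distinct threshold (descending), tied scores forming one step.
oracle_aupr <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  ts <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; r_prev <- 0
  for (t in ts) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / n_pos
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}

# Exhaustive k-NN selection: sort every row's distances (index-ordered
# tie-break), excluding self by index.
oracle_knn <- function(features, k) {
  p <- nrow(features)
  D <- as.matrix(dist(features))
  C <- matrix(0, p, p)
  for (i in seq_len(p)) {
    others <- setdiff(seq_len(p), i)
    ord <- others[order(D[i, others], others)]
    C[i, ord[seq_len(k)]] <- 1
  }
  C
}

# Central finite-difference gradient of a scalar function of a matrix.
fd_grad <- function(f, X, h = 1e-5) {
  G <- X * 0
  for (i in seq_along(X)) {
    Xp <- X; Xp[i] <- Xp[i] + h
    Xm <- X; Xm[i] <- Xm[i] - h
    G[i] <- (f(Xp) - f(Xm)) / (2 * h)
  }
  G
}

expect_grad_close <- function(analytic, numeric, tol = 1e-4) {
  denom <- pmax(abs(numeric), 1)
  expect_lt(max(abs(analytic - numeric) / denom), tol)
}

# A small labelled association matrix plus matched features, for fast
# end-to-end runs.
tiny_problem <- function(seed = 1, m = 18, n = 14, r = 2, n_pos = 35) {
  synthetic_lda(synthetic_spec(m = m, n = n, r = r, n_positives = n_pos,
                               feature_dim_l = 10, feature_dim_d = 20,
                               seed = seed))
}

tiny_config <- function(epochs = 10, seed = 1, ...) {
  train_config(epochs = epochs, knn_k = 3, hidden_dim = 16, seed = seed, ...)
}
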