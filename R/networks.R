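# The two graph autoencoders and their hand-written backward passes.
#
# Every layer is a graph convolution H_out = act(A_hat %*% H_in %*% W)
# with A_hat the symmetrically normalized adjacency (self-loops included)
# and no bias, so a network is just a named list of weight matrices.
# Gradients are derived analytically and checked against finite
# differences in the test suite.

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

#' One graph-convolution layer forward pass
#'
#' Computes `act(A_hat %*% H_prev %*% weight)`.
#'
#' @param weight d_in x d_out weight matrix.
#' @param norm_adjacency p x p normalized adjacency.
#' @param H_prev p x d_in input activations.
#' @param activation `"relu"`, `"sigmoid"` or `"linear"`.
#' @return p x d_out output activations.
#' @export
gcn_forward <- function(weight, norm_adjacency, H_prev,
                        activation = c("relu", "sigmoid", "linear")) {
  activation <- match.arg(activation)
  if (ncol(norm_adjacency) != nrow(H_prev))
    stop("adjacency and input activations are misaligned", call. = FALSE)
  if (nrow(weight) != ncol(H_prev))
    stop(sprintf("layer weight expects %d input columns, got %d",
                 nrow(weight), ncol(H_prev)), call. = FALSE)
  S <- (norm_adjacency %*% H_prev) %*% weight
  switch(activation, relu = relu(S), sigmoid = sigmoid(S), linear = S)
}

#' Reparameterization trick
#'
#' Draws `Z = mu + sigma * eps` with `eps` i.i.d. standard normal (one
#' fresh draw per entry per call), so that gradients flow through `mu`
#' and `sigma`. Pass `eps` explicitly for deterministic behaviour.
#'
#' @param mu,sigma Equal-shaped matrices; `sigma` strictly positive.
#' @param eps Optional matrix of standard-normal draws (same shape); if
#'   `NULL`, drawn from the current RNG stream.
#' @return The sampled representation matrix.
#' @export
reparameterize <- function(mu, sigma, eps = NULL) {
  check_same_shape(mu, sigma)
  if (any(sigma <= 0)) stop("'sigma' must be strictly positive", call. = FALSE)
  if (is.null(eps)) {
    eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  } else {
    check_same_shape(mu, eps)
  }
  mu + sigma * eps
}

glorot <- function(d_in, d_out) {
  s <- sqrt(6 / (d_in + d_out))
  matrix(stats::runif(d_in * d_out, -s, s), d_in, d_out)
}

# Variational autoencoder (feature inference network): shared relu
# encoder layer, linear mu / log-sigma heads, two-layer decoder ending in
# a sigmoid so reconstructions live in (0, 1).
init_gnnq <- function(d_in, hidden = 256) {
  list(W_enc = glorot(d_in, hidden),
       W_mu = glorot(hidden, hidden),
       W_sig = glorot(hidden, hidden),
       W_dec1 = glorot(hidden, hidden),
       W_dec2 = glorot(hidden, d_in))
}

# Plain autoencoder (label propagation network): relu encoder producing
# the representation Z', sigmoid decoder producing the score block F.
init_gnnp <- function(n_labels, hidden = 256) {
  list(W_enc = glorot(n_labels, hidden),
       W_dec = glorot(hidden, n_labels))
}

draw_mask <- function(n_row, n_col, dropout) {
  (matrix(stats::runif(n_row * n_col), n_row, n_col) >= dropout) /
    (1 - dropout)
}

# Forward pass of the variational network.  In training mode dropout
# masks and the reparameterization noise are drawn from the current RNG
# stream; in eval mode dropout is off and Z = mu (eps = 0).
# encoder_only skips the decoder (used for the M-step manifold targets,
# where only the posterior mean is needed).
gnnq_forward <- function(q, A, X, training = FALSE, dropout = 0.5,
                         encoder_only = FALSE) {
  if (nrow(X) != nrow(A))
    stop("feature rows are misaligned with the graph nodes", call. = FALSE)
  AX <- A %*% X
  S0 <- AX %*% q$W_enc
  H1 <- relu(S0)
  M1 <- if (training && dropout > 0) draw_mask(nrow(H1), ncol(H1), dropout) else 1
  H1d <- H1 * M1
  AH <- A %*% H1d
  mu <- AH %*% q$W_mu
  logsig <- AH %*% q$W_sig
  sigma <- exp(logsig)
  eps <- if (training) matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
         else matrix(0, nrow(mu), ncol(mu))
  Z <- mu + sigma * eps
  if (encoder_only)
    return(list(mu = mu, sigma = sigma, z = Z, X_prime = NULL, cache = NULL))
  AZ <- A %*% Z
  S2 <- AZ %*% q$W_dec1
  D1 <- relu(S2)
  M2 <- if (training && dropout > 0) draw_mask(nrow(D1), ncol(D1), dropout) else 1
  D1d <- D1 * M2
  AD <- A %*% D1d
  S3 <- AD %*% q$W_dec2
  Xp <- sigmoid(S3)
  list(mu = mu, sigma = sigma, z = Z, X_prime = Xp,
       cache = list(AX = AX, S0 = S0, M1 = M1, AH = AH, eps = eps,
                    AZ = AZ, S2 = S2, M2 = M2, AD = AD))
}

# Backward pass of the variational network for the weighted per-space
# loss w * (recon + KL) plus an external gradient dZ_extra flowing into
# the sampled representation (the co-training term).  Returns gradients
# for each weight matrix.
gnnq_backward <- function(q, fw, A, X, family, w, dZ_extra = NULL) {
  cc <- fw$cache
  Xp <- fw$X_prime
  G3 <- if (family == "gaussian") {
    w * (Xp - X) * Xp * (1 - Xp)     # MSE through the output sigmoid
  } else {
    w * (Xp - X)                     # BCE + sigmoid cancel
  }
  gW_dec2 <- crossprod(cc$AD, G3)
  dD1d <- (A %*% G3) %*% t(q$W_dec2)
  dD1 <- dD1d * cc$M2
  G2 <- dD1 * (cc$S2 > 0)
  gW_dec1 <- crossprod(cc$AZ, G2)
  dZ <- (A %*% G2) %*% t(q$W_dec1)
  if (!is.null(dZ_extra)) dZ <- dZ + dZ_extra
  dmu <- dZ + w * fw$mu                              # KL: d/dmu = mu
  dlogsig <- dZ * fw$sigma * cc$eps + w * (fw$sigma^2 - 1)  # KL via log-sigma
  gW_mu <- crossprod(cc$AH, dmu)
  gW_sig <- crossprod(cc$AH, dlogsig)
  dH1d <- (A %*% dmu) %*% t(q$W_mu) + (A %*% dlogsig) %*% t(q$W_sig)
  dH1 <- dH1d * cc$M1
  G0 <- dH1 * (cc$S0 > 0)
  gW_enc <- crossprod(cc$AX, G0)
  list(W_enc = gW_enc, W_mu = gW_mu, W_sig = gW_sig,
       W_dec1 = gW_dec1, W_dec2 = gW_dec2)
}

# Forward pass of the label network: Z' is the (relu) hidden-layer
# output, F the sigmoid-decoded score block.  Dropout acts as input
# regularization of the decoder layer; the representation Z' itself is
# the undropped hidden output (as in canonical graph-autoencoder stacks,
# where dropout is applied at layer inputs).
gnnp_forward <- function(p, A, Y_in, training = FALSE, dropout = 0.5) {
  if (nrow(Y_in) != nrow(A))
    stop("label rows are misaligned with the graph nodes", call. = FALSE)
  AY <- A %*% Y_in
  S0 <- AY %*% p$W_enc
  H <- relu(S0)
  M <- if (training && dropout > 0) draw_mask(nrow(H), ncol(H), dropout) else 1
  Hd <- H * M
  AH <- A %*% Hd
  S1 <- AH %*% p$W_dec
  F_out <- sigmoid(S1)
  list(z_prime = H, F = F_out,
       cache = list(AY = AY, S0 = S0, M = M, AH = AH))
}

# Backward pass for w * (BCE(Y_in, F) + gamma * 0.5 ||Z' - Z_target||^2).
gnnp_backward <- function(p, fw, A, Y_in, w, gamma = 0, Z_target = NULL) {
  cc <- fw$cache
  G1 <- w * (fw$F - Y_in)
  gW_dec <- crossprod(cc$AH, G1)
  dH <- ((A %*% G1) %*% t(p$W_dec)) * cc$M   # decoder path, through dropout
  if (gamma > 0 && !is.null(Z_target))
    dH <- dH + w * gamma * (fw$z_prime - Z_target)  # manifold path, undropped
  G0 <- dH * (cc$S0 > 0)
  gW_enc <- crossprod(cc$AY, G0)
  list(W_enc = gW_enc, W_dec = gW_dec)
}

# ---- Adam optimizer over a flat named list of weight matrices ----

adam_init <- function(params) {
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0),
       t = 0L)
}

# Decoupled L2 via the gradient (PyTorch-style weight_decay): the decay
# term is added to the raw gradient before the moment updates.
adam_step <- function(state, params, grads, lr = 0.01, weight_decay = 1e-5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(state = state, params = params)
}
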