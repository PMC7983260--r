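# Loss terms of the two-autoencoder objective.  All losses are summed
# (Frobenius / elementwise-sum forms), not averaged; the learning rate
# absorbs the scale.

#' Gaussian reconstruction loss
#'
#' Half squared Frobenius distance between a continuous feature matrix
#' and its reconstruction: `0.5 * sum((X - X')^2)`.
#'
#' @param X,X_prime Equal-shaped numeric matrices.
#' @return Nonnegative scalar.
#' @export
gaussian_recon_loss <- function(X, X_prime) {
  check_same_shape(X, X_prime)
  0.5 * sum((X - X_prime)^2)
}

#' Bernoulli reconstruction loss (full binary cross entropy)
#'
#' `-sum(X log X' + (1 - X) log(1 - X'))`, with reconstructions clamped
#' to `[1e-10, 1 - 1e-10]` inside the logarithms.
#'
#' @param X Binary matrix.
#' @param X_prime Reconstruction in (0, 1), same shape.
#' @return Nonnegative scalar.
#' @export
bernoulli_recon_loss <- function(X, X_prime) {
  check_same_shape(X, X_prime)
  if (!is_binary(X)) stop("'X' must be binary", call. = FALSE)
  if (any(X_prime <= 0) || any(X_prime >= 1))
    stop("'X_prime' must lie strictly in (0, 1)", call. = FALSE)
  -sum(X * .log_clamp(X_prime) + (1 - X) * .log_clamp(1 - X_prime))
}

#' KL divergence of the variational posterior from the standard normal
#'
#' `-sum over i,j of 0.5 * (1 + 2 log sigma - mu^2 - sigma^2)`, the KL
#' divergence between elementwise `N(mu, sigma^2)` posteriors and the
#' `N(0, 1)` prior. Zero exactly at `mu = 0`, `sigma = 1`.
#'
#' @param mu Posterior mean matrix.
#' @param sigma Posterior standard-deviation matrix, strictly positive.
#' @return Nonnegative scalar.
#' @export
kl_loss <- function(mu, sigma) {
  check_same_shape(mu, sigma)
  if (any(sigma <= 0)) stop("'sigma' must be strictly positive", call. = FALSE)
  -sum(0.5 * (1 + 2 * log(sigma) - mu^2 - sigma^2))
}

#' Manifold loss coupling the two autoencoders' representations
#'
#' `0.5 * ||Z - Z'||_F^2` between the inference-network representation Z
#' and the label-network representation Z'.
#'
#' @param Z,Z_prime Equal-shaped representation matrices.
#' @return Nonnegative scalar; symmetric in its arguments.
#' @export
manifold_loss <- function(Z, Z_prime) {
  check_same_shape(Z, Z_prime)
  0.5 * sum((Z - Z_prime)^2)
}

#' Co-training loss linking the lncRNA and disease spaces
#'
#' `0.5 * ||Z_l Z_d^T - Y||_F^2`: the inner products of lncRNA and
#' disease representations should reproduce the association labels.
#'
#' @param Z_l m x h lncRNA representations.
#' @param Z_d n x h disease representations.
#' @param Y m x n association matrix.
#' @return Nonnegative scalar.
#' @export
cotrain_loss <- function(Z_l, Z_d, Y) {
  if (ncol(Z_l) != ncol(Z_d))
    stop("representation dimensions of Z_l and Z_d differ", call. = FALSE)
  if (nrow(Z_l) != nrow(Y) || nrow(Z_d) != ncol(Y))
    stop("Z_l Z_d^T does not match the shape of Y", call. = FALSE)
  0.5 * sum((tcrossprod(Z_l, Z_d) - Y)^2)
}

#' Total inference-network loss
#'
#' `alpha * L_ql + (1 - alpha) * L_qd + beta * L_c`, combining the
#' per-space inference losses (reconstruction + KL) with the co-training
#' coupling.
#'
#' @param loss_ql,loss_qd Per-space inference-network losses.
#' @param L_c Co-training loss.
#' @param weights List with elements `alpha` in (0,1) and `beta >= 0`
#'   (see [loss_weights()]).
#' @return Scalar.
#' @export
total_q_loss <- function(loss_ql, loss_qd, L_c, weights) {
  weights <- as_loss_weights(weights)
  weights$alpha * loss_ql + (1 - weights$alpha) * loss_qd + weights$beta * L_c
}

#' Total label-network loss
#'
#' `alpha * L_pl + (1 - alpha) * L_pd`; each per-space term is label
#' reconstruction plus `gamma` times the manifold loss.
#'
#' @param loss_pl,loss_pd Per-space label-network losses.
#' @inheritParams total_q_loss
#' @return Scalar.
#' @export
total_p_loss <- function(loss_pl, loss_pd, weights) {
  weights <- as_loss_weights(weights)
  weights$alpha * loss_pl + (1 - weights$alpha) * loss_pd
}

#' Loss combination weights
#'
#' @param alpha Balance between lncRNA and disease space, in (0, 1).
#' @param beta Co-training weight, nonnegative.
#' @param gamma Manifold weight, nonnegative.
#' @return A validated list of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 0.5, beta = 0, gamma = 0) {
  if (!(alpha > 0 && alpha < 1))
    stop("'alpha' must lie strictly in (0, 1)", call. = FALSE)
  if (beta < 0 || gamma < 0)
    stop("'beta' and 'gamma' must be nonnegative", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "loss_weights")
}

as_loss_weights <- function(w) {
  if (inherits(w, "loss_weights")) return(w)
  loss_weights(alpha = w$alpha, beta = w$beta %||% 0, gamma = w$gamma %||% 0)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("matrix arguments must have identical shapes", call. = FALSE)
  invisible(NULL)
}

# ---- analytic gradients (used by the trainer and by gradient tests) ----

grad_gaussian_recon <- function(X, X_prime) {
  list(X = X - X_prime, X_prime = X_prime - X)
}

grad_bernoulli_recon <- function(X, X_prime) {
  list(X_prime = -(X / X_prime) + (1 - X) / (1 - X_prime))
}

grad_kl <- function(mu, sigma) {
  list(mu = mu, sigma = sigma - 1 / sigma)
}

grad_manifold <- function(Z, Z_prime) {
  list(Z = Z - Z_prime, Z_prime = Z_prime - Z)
}

grad_cotrain <- function(Z_l, Z_d, Y) {
  R <- tcrossprod(Z_l, Z_d) - Y
  list(Z_l = R %*% Z_d, Z_d = crossprod(R, Z_l))
}
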