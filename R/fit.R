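#' Training configuration
#'
#' Defaults are the published operating point of the method: Adam with
#' learning rate 0.01 and weight decay 1e-5, dropout 0.5, 256-dimensional
#' hidden representations, mutual 10-NN graphs, 500 epochs, and an even
#' balance `alpha = 0.5` between the lncRNA and disease spaces.
#'
#' @param alpha Balance between lncRNA-space and disease-space losses,
#'   strictly in (0, 1).
#' @param epochs Number of alternating E/M epochs (`e_n`).
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty added to gradients.
#' @param dropout Dropout rate on hidden activations during training.
#' @param hidden_dim Width of every hidden representation.
#' @param knn_k Neighbour count for the mutual k-NN graphs.
#' @param seed Integer seed controlling initialization, dropout and the
#'   reparameterization noise.
#' @return A validated list of class `train_config`.
#' @export
train_config <- function(alpha = 0.5, epochs = 500, learning_rate = 0.01,
                         weight_decay = 1e-5, dropout = 0.5,
                         hidden_dim = 256, knn_k = 10, seed = 1) {
  stopifnot(alpha > 0, alpha < 1, epochs >= 1, learning_rate > 0,
            weight_decay >= 0, dropout >= 0, dropout < 1,
            hidden_dim >= 1, knn_k >= 1)
  structure(list(alpha = alpha, epochs = as.integer(epochs),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 dropout = dropout, hidden_dim = as.integer(hidden_dim),
                 knn_k = as.integer(knn_k), seed = as.integer(seed)),
            class = "train_config")
}

#' Coupling-weight schedule
#'
#' The co-training weight `beta` and manifold weight `gamma` both ramp
#' linearly with training progress: `beta = gamma = e / e_n` at epoch
#' `e`, reaching 1 at the final epoch. The coupling terms depend on the
#' quality of the inferred representations, so they are phased in as the
#' inference network matures.
#'
#' @param e Current epoch, `1 <= e <= e_n`.
#' @param e_n Total number of epochs.
#' @return Numeric vector `c(beta, gamma)`.
#' @export
schedule_beta_gamma <- function(e, e_n) {
  if (e < 1 || e > e_n) stop("epoch out of range", call. = FALSE)
  c(beta = e / e_n, gamma = e / e_n)
}

# Internal clamped binary cross entropy (training-loop variant: tolerates
# numerically saturated sigmoid outputs).
bce_sum <- function(X, X_prime) {
  -sum(X * .log_clamp(X_prime) + (1 - X) * .log_clamp(1 - X_prime))
}

# Assemble the mutable training state: graphs, data, weights, optimizers.
# All random draws (initialization included) come from the current RNG
# stream, so a single set.seed upstream fixes the whole run.
em_state_init <- function(Y, X_l, X_d, config, schedule) {
  G_l <- knn_graph(X_l, config$knn_k)
  G_d <- knn_graph(X_d, config$knn_k)
  h <- config$hidden_dim
  q_l <- init_gnnq(ncol(X_l), h)
  q_d <- init_gnnq(ncol(X_d), h)
  p_l <- init_gnnp(ncol(Y), h)
  p_d <- init_gnnp(nrow(Y), h)
  q_par <- c(prefix_names(q_l, "ql."), prefix_names(q_d, "qd."))
  p_par <- c(prefix_names(p_l, "pl."), prefix_names(p_d, "pd."))
  list(Y = Y, X_l = X_l, X_d = X_d,
       A_l = G_l$norm_adjacency, A_d = G_d$norm_adjacency,
       G_l = G_l, G_d = G_d,
       q = q_par, p = p_par,
       opt_q = adam_init(q_par), opt_p = adam_init(p_par),
       config = config, schedule = schedule, history = list())
}

prefix_names <- function(x, pre) { names(x) <- paste0(pre, names(x)); x }
take_prefix <- function(x, pre) {
  out <- x[startsWith(names(x), pre)]
  names(out) <- substring(names(out), nchar(pre) + 1)
  out
}

# One full E/M epoch.  E-step: one Adam update of the two inference
# networks (label networks frozen).  M-step: one Adam update of the two
# label networks against frozen, freshly recomputed posterior-mean
# representations.
em_epoch <- function(state, e) {
  bg <- state$schedule(e, state$config$epochs)
  state <- e_step(state, beta = bg[[1]])
  state <- m_step(state, gamma = bg[[2]])
  losses <- c(state$last_q_losses, state$last_p_losses)
  if (any(!is.finite(losses)))
    stop(sprintf("non-finite training loss at epoch %d", e), call. = FALSE)
  state$history[[e]] <- c(epoch = e, losses, beta = bg[[1]], gamma = bg[[2]])
  state
}

# E-step: feature inference.  Only state$q and its optimizer change.
e_step <- function(state, beta) {
  cfg <- state$config
  alpha <- cfg$alpha
  q_l <- take_prefix(state$q, "ql."); q_d <- take_prefix(state$q, "qd.")
  fql <- gnnq_forward(q_l, state$A_l, state$X_l, TRUE, cfg$dropout)
  fqd <- gnnq_forward(q_d, state$A_d, state$X_d, TRUE, cfg$dropout)
  gc <- grad_cotrain(fql$z, fqd$z, state$Y)
  gl <- gnnq_backward(q_l, fql, state$A_l, state$X_l, "gaussian", alpha,
                      beta * gc$Z_l)
  gd <- gnnq_backward(q_d, fqd, state$A_d, state$X_d, "bernoulli", 1 - alpha,
                      beta * gc$Z_d)
  gq <- c(prefix_names(gl, "ql."), prefix_names(gd, "qd."))
  up <- adam_step(state$opt_q, state$q, gq, cfg$learning_rate,
                  cfg$weight_decay)
  state$opt_q <- up$state; state$q <- up$params

  state$last_q_losses <- c(
    L_ql = gaussian_recon_loss(state$X_l, fql$X_prime) +
      kl_loss(fql$mu, fql$sigma),
    L_qd = bce_sum(state$X_d, fqd$X_prime) + kl_loss(fqd$mu, fqd$sigma),
    L_c = cotrain_loss(fql$z, fqd$z, state$Y))
  state
}

# M-step: label propagation.  Only state$p and its optimizer change; the
# manifold targets are the frozen posterior means of the just-updated
# inference networks.
m_step <- function(state, gamma) {
  cfg <- state$config
  alpha <- cfg$alpha
  q_l <- take_prefix(state$q, "ql."); q_d <- take_prefix(state$q, "qd.")
  Zl_star <- gnnq_forward(q_l, state$A_l, state$X_l, FALSE,
                          encoder_only = TRUE)$z  # = posterior mean
  Zd_star <- gnnq_forward(q_d, state$A_d, state$X_d, FALSE,
                          encoder_only = TRUE)$z
  p_l <- take_prefix(state$p, "pl."); p_d <- take_prefix(state$p, "pd.")
  fpl <- gnnp_forward(p_l, state$A_l, state$Y, TRUE, cfg$dropout)
  fpd <- gnnp_forward(p_d, state$A_d, t(state$Y), TRUE, cfg$dropout)
  gpl <- gnnp_backward(p_l, fpl, state$A_l, state$Y, alpha, gamma, Zl_star)
  gpd <- gnnp_backward(p_d, fpd, state$A_d, t(state$Y), 1 - alpha, gamma,
                       Zd_star)
  gp <- c(prefix_names(gpl, "pl."), prefix_names(gpd, "pd."))
  up <- adam_step(state$opt_p, state$p, gp, cfg$learning_rate,
                  cfg$weight_decay)
  state$opt_p <- up$state; state$p <- up$params

  state$last_p_losses <- c(
    L_pl = bce_sum(state$Y, fpl$F) +
      gamma * manifold_loss(Zl_star, fpl$z_prime),
    L_pd = bce_sum(t(state$Y), fpd$F) +
      gamma * manifold_loss(Zd_star, fpd$z_prime))
  state
}

# Deterministic (eval-mode) score blocks from the current label networks.
em_predict <- function(state) {
  p_l <- take_prefix(state$p, "pl."); p_d <- take_prefix(state$p, "pd.")
  F_l <- gnnp_forward(p_l, state$A_l, state$Y, FALSE)$F
  F_d <- gnnp_forward(p_d, state$A_d, t(state$Y), FALSE)$F
  list(F_l = F_l, F_d = F_d)
}

#' Fit the two coupled graph autoencoders by variational EM
#'
#' Alternates, once per epoch, between (E-step) one optimizer update of
#' the two variational inference networks — feature reconstruction + KL
#' divergence + co-training coupling, with the label networks frozen —
#' and (M-step) one optimizer update of the two label-propagation
#' networks — label cross entropy + manifold coupling to the frozen
#' posterior-mean representations. After the final epoch the two score
#' blocks are fused as `alpha * F_l + (1 - alpha) * t(F_d)` and min-max
#' rescaled to `[0, 1]`.
#'
#' Continuous (gaussian) lncRNA features are globally min-max scaled to
#' `[0, 1]` before training so the sigmoid-bounded decoder can
#' reconstruct them; binary disease features are used as-is.
#'
#' @param Y Binary m x n lncRNA-disease association matrix (rows =
#'   lncRNAs) with at least one known association.
#' @param X_l Continuous lncRNA feature matrix, m rows (e.g. from
#'   [embed_sequences()]).
#' @param X_d Binary disease feature matrix, n rows (e.g. from
#'   [read_gene_feature_table()]).
#' @param config A [train_config()].
#' @param schedule Coupling schedule `function(e, e_n) -> c(beta, gamma)`;
#'   default [schedule_beta_gamma()].
#' @return An object of class `vemlda`: list with fused `scores` (in
#'   `[0, 1]`), per-space blocks `F_l` (m x n) and `F_d` (n x m), trained
#'   `weights`, the two `graphs`, per-epoch loss `history`, `config`, and
#'   the training matrix `Y`.
#' @seealso [predict.vemlda()], [cross_validate()], [synthetic_lda()]
#' @examples
#' dat <- synthetic_lda(synthetic_spec(m = 20, n = 15, r = 2,
#'                                     n_positives = 40, seed = 1))
#' fit <- vemlda(dat$Y, dat$X_l, dat$X_d,
#'               config = train_config(epochs = 20, knn_k = 3, seed = 1))
#' fit
#' @export
vemlda <- function(Y, X_l, X_d, config = train_config(),
                   schedule = schedule_beta_gamma) {
  stop_if_not_matrix(Y, "Y")
  if (!is_binary(Y)) stop("'Y' must be a 0/1 matrix", call. = FALSE)
  if (sum(Y) == 0)
    stop("no known associations: Y is all zeros", call. = FALSE)
  stop_if_not_matrix(X_l, "X_l"); stop_if_not_matrix(X_d, "X_d")
  if (nrow(X_l) != nrow(Y))
    stop("X_l rows must match the lncRNA rows of Y", call. = FALSE)
  if (nrow(X_d) != ncol(Y))
    stop("X_d rows must match the disease columns of Y", call. = FALSE)
  fam_l <- noise_family(X_l) %||% "gaussian"
  fam_d <- noise_family(X_d) %||% "bernoulli"
  if (fam_l != "gaussian" || fam_d != "bernoulli")
    stop("expected gaussian lncRNA features and bernoulli disease features",
         call. = FALSE)
  if (!is_binary(X_d))
    stop("disease features must be 0/1", call. = FALSE)
  X_l <- rescale_features_unit_interval(feature_matrix(unclass(X_l),
                                                       "gaussian"))

  fit <- with_seed(config$seed, {
    state <- em_state_init(Y, X_l, X_d, config, schedule)
    for (e in seq_len(config$epochs)) state <- em_epoch(state, e)
    blocks <- em_predict(state)
    list(state = state, blocks = blocks)
  })
  state <- fit$state
  F_l <- fit$blocks$F_l; F_d <- fit$blocks$F_d
  dimnames(F_l) <- dimnames(Y)
  dimnames(F_d) <- list(colnames(Y), rownames(Y))
  scores <- fuse_and_rescale(F_l, F_d, config$alpha)
  structure(list(call = match.call(),
                 scores = scores, F_l = F_l, F_d = F_d,
                 weights = list(q = state$q, p = state$p),
                 graphs = list(lncrna = state$G_l, disease = state$G_d),
                 history = as.data.frame(do.call(rbind, state$history)),
                 config = config, Y = Y),
            class = "vemlda")
}

#' Fuse the per-space score blocks and rescale to [0, 1]
#'
#' `F = alpha * F_l + (1 - alpha) * t(F_d)`, then min-max rescaled so the
#' smallest score maps to 0 and the largest to 1. Both blocks are
#' low-rank (rank bounded by the hidden width), and by the rank-sum
#' inequality so is their affine combination.
#'
#' @param F_l m x n lncRNA-space scores.
#' @param F_d n x m disease-space scores.
#' @param alpha Fusion weight in (0, 1).
#' @return The fused, rescaled m x n score matrix (attribute
#'   `provenance = "fused"`). A constant fused matrix is returned as all
#'   zeros with a warning.
#' @export
fuse_and_rescale <- function(F_l, F_d, alpha = 0.5) {
  if (!(alpha > 0 && alpha < 1))
    stop("'alpha' must lie strictly in (0, 1)", call. = FALSE)
  if (!identical(dim(F_l), rev(dim(F_d))) && !identical(dim(F_l), dim(t(F_d))))
    stop("'F_d' must be the transpose shape of 'F_l'", call. = FALSE)
  fused <- alpha * F_l + (1 - alpha) * t(F_d)
  rng <- range(fused)
  if (rng[2] > rng[1]) {
    fused <- (fused - rng[1]) / (rng[2] - rng[1])
  } else {
    warning("constant fused score matrix; returning all zeros")
    fused <- fused * 0
  }
  attr(fused, "provenance") <- "fused"
  fused
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single archive holding all weight matrices, the
#' training configuration, and the training association matrix, enough
#' to regenerate predictions.
#'
#' @param fit A fitted `vemlda` object.
#' @param path Checkpoint file path.
#' @return `load_checkpoint` returns the restored `vemlda` object.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "vemlda"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "vemlda")) stop("not a vemlda checkpoint", call. = FALSE)
  fit
}
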