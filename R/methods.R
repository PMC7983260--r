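# S3 methods for fitted models.

#' @export
print.vemlda <- function(x, ...) {
  cfg <- x$config
  cat("Variational-EM graph autoencoder fit\n")
  cat(sprintf("  %d lncRNAs x %d diseases, %d known associations\n",
              nrow(x$Y), ncol(x$Y), sum(x$Y)))
  cat(sprintf("  epochs: %d, hidden: %d, k-NN: %d, alpha: %g, seed: %d\n",
              cfg$epochs, cfg$hidden_dim, cfg$knn_k, cfg$alpha, cfg$seed))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final losses  L_ql %.3f  L_qd %.3f  L_c %.3f  L_pl %.3f  L_pd %.3f\n",
              last$L_ql, last$L_qd, last$L_c, last$L_pl, last$L_pd))
  invisible(x)
}

#' @export
summary.vemlda <- function(object, n_top = 10, ...) {
  sc <- object$scores
  novel <- which(object$Y == 0)
  ord <- novel[order(sc[novel], decreasing = TRUE)]
  top <- utils::head(ord, n_top)
  idx <- arrayInd(top, dim(sc))
  out <- list(
    fit = object,
    top_novel = data.frame(
      lncRNA_id = rownames(sc)[idx[, 1]],
      disease_id = colnames(sc)[idx[, 2]],
      score = sc[top],
      stringsAsFactors = FALSE),
    score_range = range(sc),
    mean_score_known = mean(sc[object$Y == 1]),
    mean_score_unknown = mean(sc[object$Y == 0]))
  class(out) <- "summary.vemlda"
  out
}

#' @export
print.summary.vemlda <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  mean score: known pairs %.3f, unknown pairs %.3f\n",
              x$mean_score_known, x$mean_score_unknown))
  cat("\nTop novel (unknown-pair) predictions:\n")
  print(x$top_novel, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Predicted association scores
#'
#' @param object A fitted `vemlda` model.
#' @param type `"matrix"` for the fused m x n score matrix, `"pairs"`
#'   for a long data frame with one row per (lncRNA, disease) pair
#'   (columns `lncRNA_id`, `disease_id`, `score`, `known_flag`).
#' @param ... Unused.
#' @return A matrix or data frame of scores in `[0, 1]`.
#' @export
predict.vemlda <- function(object, type = c("matrix", "pairs"), ...) {
  type <- match.arg(type)
  if (type == "matrix") return(object$scores)
  data.frame(
    lncRNA_id = rep(rownames(object$scores), times = ncol(object$scores)),
    disease_id = rep(colnames(object$scores), each = nrow(object$scores)),
    score = as.vector(object$scores),
    known_flag = as.integer(as.vector(object$Y)),
    stringsAsFactors = FALSE)
}

#' @export
fitted.vemlda <- function(object, ...) object$scores

#' @export
residuals.vemlda <- function(object, ...) object$Y - object$scores

#' Plot training loss trajectories
#'
#' Draws the per-epoch loss components of both networks on a log scale,
#' plus the beta = gamma coupling ramp.
#'
#' @param x A fitted `vemlda` model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.vemlda <- function(x, ...) {
  h <- x$history
  comp <- c("L_ql", "L_qd", "L_c", "L_pl", "L_pd")
  graphics::matplot(h$epoch, as.matrix(h[comp]), type = "l", lty = 1,
                    log = "y", xlab = "epoch", ylab = "loss (log scale)",
                    col = seq_along(comp), ...)
  graphics::legend("topright", legend = comp, col = seq_along(comp),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
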