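#' k-nearest-neighbour selection matrix
#'
#' For each node, selects the `k` nearest other nodes under the Euclidean
#' metric on feature rows. Distance ties are broken deterministically by
#' ascending node index; a node never selects itself (excluded by index,
#' so duplicate feature rows are legal).
#'
#' @param features Numeric matrix, one row per node.
#' @param k Number of neighbours per node (default 10).
#' @return A p x p binary matrix `C` with `C[i, j] = 1` iff node j is one
#'   of the k nearest neighbours of node i; zero diagonal; each row sums
#'   to k.
#' @export
knn_selection <- function(features, k = 10) {
  stop_if_not_matrix(features, "features")
  p <- nrow(features)
  if (k < 1 || p <= k)
    stop(sprintf("need more nodes (%d) than neighbours (k = %d)", p, k),
         call. = FALSE)
  D <- as.matrix(stats::dist(features))
  diag(D) <- Inf
  C <- matrix(0, p, p)
  idx <- seq_len(p)
  for (i in idx) {
    nb <- order(D[i, ], idx)[seq_len(k)]  # ties -> smaller index first
    C[i, nb] <- 1
  }
  C
}

#' Mutual-neighbour adjacency with self-loops
#'
#' Builds the adjacency matrix `A~ = C^T (*) C + I` (Hadamard product): an
#' edge is present iff the two nodes selected each other, and every node
#' carries a self-loop. The result is symmetric by construction.
#'
#' @param C Binary selection matrix with zero diagonal
#'   (see [knn_selection()]).
#' @return A symmetric p x p binary matrix with unit diagonal.
#' @export
mutual_adjacency <- function(C) {
  stop_if_not_matrix(C, "C")
  if (!is_binary(C)) stop("'C' must be a 0/1 matrix", call. = FALSE)
  if (any(diag(C) != 0))
    stop("'C' must have a zero diagonal (no self-selection)", call. = FALSE)
  A <- t(C) * C
  diag(A) <- 1
  A
}

#' Symmetric degree normalization of an adjacency matrix
#'
#' Computes `D^{-1/2} A~ D^{-1/2}` where `D` is the diagonal degree matrix
#' of `A~`. With self-loops every degree is positive and all eigenvalues
#' of the result lie in `[-1, 1]`.
#'
#' @param A_tilde Nonnegative adjacency matrix with positive row sums.
#' @return The normalized adjacency (symmetric if `A_tilde` is).
#' @export
normalize_adjacency <- function(A_tilde) {
  stop_if_not_matrix(A_tilde, "A_tilde")
  if (any(A_tilde < 0)) stop("adjacency must be nonnegative", call. = FALSE)
  d <- rowSums(A_tilde)
  if (any(d <= 0))
    stop("zero row-sum in adjacency; add self-loops first", call. = FALSE)
  s <- 1 / sqrt(d)
  A_tilde * outer(s, s)
}

#' Build a mutual k-NN graph from node features
#'
#' Convenience wrapper chaining [knn_selection()], [mutual_adjacency()]
#' and [normalize_adjacency()].
#'
#' @param features Numeric matrix, one row per node.
#' @param k Neighbour count (default 10).
#' @return An object of class `knn_graph`: list with `adjacency` (binary,
#'   self-loops), `norm_adjacency` (symmetric normalization), `k`, and
#'   node `ids`.
#' @export
knn_graph <- function(features, k = 10) {
  C <- knn_selection(features, k)
  A <- mutual_adjacency(C)
  structure(list(adjacency = A,
                 norm_adjacency = normalize_adjacency(A),
                 k = k,
                 ids = rownames(features)),
            class = "knn_graph")
}

#' @export
print.knn_graph <- function(x, ...) {
  p <- nrow(x$adjacency)
  n_edges <- (sum(x$adjacency) - p) / 2
  cat(sprintf("Mutual %d-NN graph: %d nodes, %d edges (+ self-loops)\n",
              x$k, p, n_edges))
  invisible(x)
}

#' Export a graph as an edge list
#'
#' Writes one row per undirected edge (excluding self-loops) as a TSV
#' with columns `node_i`, `node_j`.
#'
#' @param graph A `knn_graph`.
#' @param path Output TSV path.
#' @export
write_edge_list <- function(graph, path) {
  A <- graph$adjacency
  diag(A) <- 0
  e <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  ids <- graph$ids %||% as.character(seq_len(nrow(A)))
  utils::write.table(
    data.frame(node_i = ids[e[, 1]], node_j = ids[e[, 2]]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
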