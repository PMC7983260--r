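#' Read a binary lncRNA-disease association matrix
#'
#' Reads a delimited table whose first row holds disease identifiers and
#' whose first column holds lncRNA identifiers; every body cell must be 0
#' or 1 (1 = experimentally supported association).
#'
#' @param path Path to a TSV or CSV file.
#' @param dialect Delimiter: `"auto"` (default) inspects the header line and
#'   accepts tab or comma; otherwise `"tab"` or `"comma"`.
#' @return A numeric m x n matrix of 0/1 with lncRNA ids as rownames and
#'   disease ids as colnames.
#' @export
read_association_matrix <- function(path, dialect = c("auto", "tab", "comma")) {
  tab <- read_id_table(path, match.arg(dialect))
  Y <- validate_binary_body(tab, path)
  if (sum(Y) == 0)
    stop("no known associations: association matrix is all zeros", call. = FALSE)
  Y
}

#' Write an association matrix
#'
#' Inverse of [read_association_matrix()]: tab-separated, one header row of
#' disease ids, one leading column of lncRNA ids.
#'
#' @param Y Binary matrix with dimnames.
#' @param path Output path.
#' @export
write_association_matrix <- function(Y, path) {
  write_id_table(Y, path)
}

#' Read a binary disease-gene feature table
#'
#' Disease node features are binary indicator vectors over a gene panel
#' (1 = the disease is associated with that gene). The returned matrix has
#' `noise_family` `"bernoulli"` so downstream reconstruction uses the
#' cross-entropy loss.
#'
#' @param path Path to a TSV/CSV with diseases as rows and genes as columns.
#' @param dialect See [read_association_matrix()].
#' @return A binary feature matrix with attribute `noise_family = "bernoulli"`.
#' @export
read_gene_feature_table <- function(path, dialect = c("auto", "tab", "comma")) {
  tab <- read_id_table(path, match.arg(dialect))
  X <- validate_binary_body(tab, path)
  feature_matrix(X, "bernoulli")
}

#' Read a numeric feature table
#'
#' General reader for precomputed continuous node features (e.g. sequence
#' embeddings saved to disk).
#'
#' @inheritParams read_gene_feature_table
#' @param noise_family `"gaussian"` (default) for continuous features or
#'   `"bernoulli"` for binary ones.
#' @return A feature matrix with the declared `noise_family` attribute.
#' @export
read_feature_table <- function(path, noise_family = c("gaussian", "bernoulli"),
                               dialect = c("auto", "tab", "comma")) {
  noise_family <- match.arg(noise_family)
  tab <- read_id_table(path, match.arg(dialect))
  if (noise_family == "bernoulli") {
    X <- validate_binary_body(tab, path)
  } else {
    X <- as.matrix(tab)
    storage.mode(X) <- "double"
    if (any(is.na(X) | !is.finite(X))) {
      bad <- which(is.na(X) | !is.finite(X), arr.ind = TRUE)[1, ]
      stop(sprintf("malformed cell at row '%s', column '%s' in %s",
                   rownames(X)[bad[1]], colnames(X)[bad[2]], path),
           call. = FALSE)
    }
  }
  feature_matrix(X, noise_family)
}

#' Write a feature table
#'
#' @param X Feature matrix with dimnames.
#' @param path Output path (tab-separated).
#' @export
write_feature_table <- function(X, path) {
  write_id_table(X, path)
}

#' Tag a matrix as a node feature matrix
#'
#' @param values Numeric matrix, one row per node; rownames are node ids.
#' @param noise_family `"gaussian"` or `"bernoulli"`; declares which
#'   reconstruction likelihood applies to these features.
#' @return `values` with a `noise_family` attribute.
#' @export
feature_matrix <- function(values, noise_family = c("gaussian", "bernoulli")) {
  noise_family <- match.arg(noise_family)
  stop_if_not_matrix(values, "values")
  if (noise_family == "bernoulli" && !is_binary(values))
    stop("bernoulli feature matrix must contain only 0/1 entries", call. = FALSE)
  attr(values, "noise_family") <- noise_family
  values
}

#' Noise family of a feature matrix
#' @param X A feature matrix.
#' @return `"gaussian"`, `"bernoulli"`, or `NULL` if untagged.
#' @export
noise_family <- function(X) attr(X, "noise_family")

#' Drop gene columns with no disease association
#'
#' Removes all-zero columns from a binary disease-gene feature table, so
#' every retained gene is associated with at least one disease. Column
#' order is preserved. Idempotent.
#'
#' @param features Binary feature matrix (`noise_family = "bernoulli"`).
#' @return The reduced feature matrix.
#' @export
drop_empty_gene_columns <- function(features) {
  if (!identical(noise_family(features), "bernoulli"))
    stop("drop_empty_gene_columns() expects bernoulli features", call. = FALSE)
  keep <- colSums(features) > 0
  if (!any(keep))
    stop("all gene columns are empty: no features remain", call. = FALSE)
  feature_matrix(features[, keep, drop = FALSE], "bernoulli")
}

#' Min-max rescale continuous features to [0, 1]
#'
#' A single global affine map sending the matrix minimum to 0 and maximum
#' to 1, so a sigmoid-bounded decoder can reconstruct the features. A
#' constant matrix maps to all zeros.
#'
#' @param features Continuous feature matrix (`noise_family = "gaussian"`).
#' @return The rescaled feature matrix.
#' @export
rescale_features_unit_interval <- function(features) {
  if (!identical(noise_family(features), "gaussian"))
    stop("rescale_features_unit_interval() expects gaussian features",
         call. = FALSE)
  if (any(!is.finite(features)))
    stop("features contain non-finite entries", call. = FALSE)
  rng <- range(features)
  out <- if (rng[2] > rng[1]) (features - rng[1]) / (rng[2] - rng[1])
         else features * 0
  feature_matrix(out, "gaussian")
}

#' Write a prediction table
#'
#' One row per (lncRNA, disease) pair: `lncRNA_id`, `disease_id`, `score`,
#' `known_flag` (1 if the pair was a known association in the training
#' matrix).
#'
#' @param scores m x n score matrix with dimnames.
#' @param Y Binary association matrix used for training (same shape).
#' @param path Output TSV path.
#' @return Invisibly, the data frame written.
#' @export
write_predictions <- function(scores, Y, path) {
  stopifnot(all(dim(scores) == dim(Y)))
  df <- data.frame(
    lncRNA_id = rep(rownames(scores), times = ncol(scores)),
    disease_id = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores),
    known_flag = as.integer(as.vector(Y)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

# ---- shared table plumbing ----

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) stop(sprintf("empty file: %s", path), call. = FALSE)
  if (grepl("\t", header)) "\t"
  else if (grepl(",", header)) ","
  else stop(sprintf("cannot detect delimiter (tab or comma) in %s", path),
            call. = FALSE)
}

read_id_table <- function(path, dialect) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sep <- switch(dialect, auto = detect_delim(path), tab = "\t", comma = ",")
  tab <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  if (nrow(tab) == 0) stop(sprintf("no data rows in %s", path), call. = FALSE)
  if (ncol(tab) < 2) stop(sprintf("no data columns in %s", path), call. = FALSE)
  row_ids <- tab[[1]]
  col_ids <- colnames(tab)[-1]
  if (anyDuplicated(row_ids))
    stop(sprintf("duplicate row identifier '%s' in %s",
                 row_ids[duplicated(row_ids)][1], path), call. = FALSE)
  if (anyDuplicated(col_ids))
    stop(sprintf("duplicate column identifier '%s' in %s",
                 col_ids[duplicated(col_ids)][1], path), call. = FALSE)
  body <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("malformed cell '%s' at row '%s', column '%s' in %s",
                 body[bad[1], bad[2]], row_ids[bad[1]], col_ids[bad[2]], path),
         call. = FALSE)
  }
  dimnames(num) <- list(row_ids, col_ids)
  num
}

validate_binary_body <- function(num, path) {
  if (!is_binary(num)) {
    bad <- which(!(num %in% c(0, 1)))[1]
    idx <- arrayInd(bad, dim(num))
    stop(sprintf("cell at row '%s', column '%s' in %s is not 0/1",
                 rownames(num)[idx[1]], colnames(num)[idx[2]], path),
         call. = FALSE)
  }
  num
}

write_id_table <- function(X, path) {
  stopifnot(!is.null(rownames(X)), !is.null(colnames(X)))
  df <- data.frame(id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
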