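#' Read nucleotide sequences from a FASTA file
#'
#' Multi-line records are supported; sequences may use the DNA or RNA
#' alphabet (U is mapped to T downstream).
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (names = record ids, taken
#'   as the first whitespace-delimited token of each header).
#' @export
read_fasta_records <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop(sprintf("no records in %s", path), call. = FALSE)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence identifiers in FASTA", call. = FALSE)
  seqs
}

# Clean one sequence and return its overlapping k-mers (stride 1).
# Uppercases, maps U->T, and drops k-mers containing characters outside
# {A,C,G,T} (e.g. spanning an N).
sequence_kmers <- function(seq, k) {
  s <- chartr("u", "t", tolower(seq))
  s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  km <- substring(s, starts, starts + k - 1L)
  km[!grepl("[^ACGT]", km)]
}

#' Embed nucleotide sequences as sums of k-mer skip-gram vectors
#'
#' Splits every sequence into overlapping k-mers (stride 1), trains a
#' skip-gram model with negative sampling on the corpus formed by all
#' input sequences, and represents each sequence as the sum of its k-mer
#' vectors. The result is a continuous (`gaussian`) feature matrix with
#' one row per sequence.
#'
#' @param records Named character vector of sequences (see
#'   [read_fasta_records()]).
#' @param k K-mer size (default 3).
#' @param dim Embedding dimension (default 300).
#' @param window Skip-gram context window: pairs are formed with up to
#'   `window` k-mers on each side (default 5).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param epochs Passes over the corpus during skip-gram training.
#' @param negative Negative samples per positive pair.
#' @param learning_rate SGD step size for the skip-gram updates.
#' @return A feature matrix (rows = records, `dim` columns,
#'   `noise_family = "gaussian"`).
#' @export
embed_sequences <- function(records, k = 3, dim = 300, window = 5, seed = 1,
                            epochs = 3, negative = 5, learning_rate = 0.025) {
  stopifnot(k >= 1, dim >= 1, window >= 1, length(records) >= 1)
  if (is.null(names(records)))
    names(records) <- paste0("seq", seq_along(records))
  tokens <- lapply(records, sequence_kmers, k = k)
  empty <- lengths(tokens) == 0
  if (any(empty))
    stop(sprintf("sequences too short to yield a %d-mer: %s",
                 k, paste(names(records)[empty], collapse = ", ")),
         call. = FALSE)

  vocab <- sort(unique(unlist(tokens, use.names = FALSE)))
  ids <- lapply(tokens, function(tk) match(tk, vocab))
  # canonical corpus order (by sequence content), so the trained vectors
  # do not depend on the order records arrive in
  corpus <- ids[order(vapply(records, identity, character(1)))]
  emb <- with_seed(seed,
                   train_skipgram(corpus, length(vocab), dim, window,
                                  epochs, negative, learning_rate))
  rows <- t(vapply(ids, function(i) colSums(emb[i, , drop = FALSE]),
                   numeric(dim)))
  rownames(rows) <- names(records)
  colnames(rows) <- paste0("e", seq_len(dim))
  feature_matrix(rows, "gaussian")
}

# Skip-gram with negative sampling over tokenised sequences.  The
# vocabulary is tiny (4^k k-mers) so plain R loops over (center, context)
# pairs with vectorised dim-length updates are adequate.
train_skipgram <- function(ids, vocab_size, dim, window, epochs, negative,
                           lr0) {
  Win <- matrix(stats::runif(vocab_size * dim, -0.5, 0.5) / dim,
                vocab_size, dim)
  Wout <- matrix(0, vocab_size, dim)
  counts <- tabulate(unlist(ids, use.names = FALSE), nbins = vocab_size)
  noise <- counts^0.75
  noise <- noise / sum(noise)
  for (ep in seq_len(epochs)) {
    lr <- lr0 * (1 - (ep - 1) / epochs)
    for (tk in ids) {
      n <- length(tk)
      for (i in seq_len(n)) {
        lo <- max(1L, i - window); hi <- min(n, i + window)
        ctx <- tk[setdiff(lo:hi, i)]
        if (!length(ctx)) next
        center <- tk[i]
        v <- Win[center, ]
        for (j in ctx) {
          neg <- sample.int(vocab_size, negative, replace = TRUE, prob = noise)
          outs <- c(j, neg)
          lab <- c(1, numeric(negative))
          U <- Wout[outs, , drop = FALSE]
          g <- 1 / (1 + exp(-drop(U %*% v))) - lab
          Wout[outs, ] <- U - lr * tcrossprod(g, v)
          v <- v - lr * drop(crossprod(U, g))
        }
        Win[center, ] <- v
      }
    }
  }
  Win
}
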