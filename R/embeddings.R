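# Word-embedding table and the collocation-neighborhood augmentation that
# enriches medical-concept vectors before the recurrent stack.

#' Construct an embedding table
#'
#' @param vectors numeric matrix, one row per word, with row names;
#'   conventionally 300 columns (pretrained fastText-style vectors).
#' @param fallback vector used for out-of-vocabulary words; default is the
#'   mean of all in-vocabulary vectors.
#' @return object of class \code{embedding_table}: list with
#'   \code{vectors}, \code{dim} and \code{fallback}.
#' @export
embedding_table <- function(vectors, fallback = NULL) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  if (anyDuplicated(rownames(vectors)))
    stop("duplicate words in embedding table", call. = FALSE)
  if (is.null(fallback)) fallback <- colMeans(vectors)
  stopifnot(length(fallback) == ncol(vectors))
  structure(list(vectors = vectors, dim = ncol(vectors),
                 fallback = as.numeric(fallback)),
            class = "embedding_table")
}

#' @exportS3Method base::print
print.embedding_table <- function(x, ...) {
  cat(sprintf("Embedding table: %d words x %d dims\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Look up embedding vectors for tokens
#'
#' Out-of-vocabulary tokens map to the table's fallback vector (by default
#' the average in-vocabulary embedding).
#'
#' @param table an \code{embedding_table}.
#' @param tokens character vector.
#' @return numeric matrix, \code{length(tokens)} rows.
#' @export
lookup_vectors <- function(table, tokens) {
  stopifnot(inherits(table, "embedding_table"))
  idx <- match(tokens, rownames(table$vectors))
  out <- matrix(table$fallback, nrow = length(tokens), ncol = table$dim,
                byrow = TRUE)
  hit <- !is.na(idx)
  if (any(hit)) out[hit, ] <- table$vectors[idx[hit], , drop = FALSE]
  out
}

#' Seeded random embedding table for a vocabulary
#'
#' Generates reproducible Gaussian vectors (sd \code{1/sqrt(dim)}) so the
#' network stacks can be exercised without any pretrained file.
#'
#' @param vocab character vector of words.
#' @param dim embedding dimension (default 300).
#' @param seed RNG seed.
#' @return an \code{embedding_table}.
#' @export
synthetic_embeddings <- function(vocab, dim = 300L, seed = 1L) {
  vocab <- unique(vocab)
  dim <- stopifnot_scalar_int(dim, "dim")
  m <- with_seed(seed, matrix(stats::rnorm(length(vocab) * dim, sd = 1 / sqrt(dim)),
                              length(vocab), dim))
  rownames(m) <- vocab
  embedding_table(m)
}

#' Embed a token sequence with collocation-neighborhood augmentation
#'
#' Non-concept tokens map to their table vector.  A token that is a
#' lexicon concept with a non-empty pruned neighbor set maps to its table
#' vector plus the co-occurrence-weighted average of its neighbors'
#' vectors: for neighbors with weights \eqn{w_i}, the augmentation term is
#' \eqn{\sum_i w_i v_i / \sum_i w_i}.  With an empty neighbor map the
#' result reduces to plain lookup.
#'
#' @param tokens non-empty character vector of normalized tokens.
#' @param table an \code{embedding_table}.
#' @param neighbors a \code{neighbor_sets} (may be empty).
#' @return numeric matrix with one row per token.
#' @export
embed_with_neighborhood <- function(tokens, table, neighbors) {
  if (length(tokens) == 0L) stop("empty token sequence", call. = FALSE)
  X <- lookup_vectors(table, tokens)
  if (length(neighbors) == 0L) return(X)
  hit <- which(tokens %in% names(neighbors))
  for (i in hit) {
    nb <- neighbors[[tokens[i]]]
    if (is.null(nb) || nrow(nb) == 0L) next
    V <- lookup_vectors(table, nb$word)
    w <- nb$weight
    X[i, ] <- X[i, ] + colSums(V * w) / sum(w)
  }
  X
}
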