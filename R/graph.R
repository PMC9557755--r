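# Collocation graph: undirected word-adjacency co-occurrence counts over a
# tokenized training corpus, pruned to each medical concept's strongest
# neighbors.

#' Build a word-adjacency collocation graph
#'
#' Every unique word of the corpus becomes a node; an undirected edge of
#' weight w joins two words that occur adjacently (distance one, in either
#' order) w times across all tweets.  Adjacency never crosses tweet
#' boundaries and self-adjacency of a repeated token is ignored.
#'
#' @param tokens a \code{tokenized_corpus} (or plain list of token
#'   vectors).
#' @return an object of class \code{collocation_graph}: list with
#'   \code{nodes} (character) and \code{edges} (data frame
#'   \code{word_a}, \code{word_b}, \code{weight} with
#'   \code{word_a < word_b}, ordered canonically).
#' @export
build_graph <- function(tokens) {
  tok_list <- if (inherits(tokens, "tokenized_corpus")) tokens$tokens
              else tokens
  if (length(tok_list) == 0L) stop("empty corpus", call. = FALSE)
  nodes <- sort(unique(unlist(tok_list, use.names = FALSE)), method = "radix")
  if (length(nodes) == 0L) stop("empty corpus", call. = FALSE)
  a_all <- character(0); b_all <- character(0)
  for (t in tok_list) {
    if (length(t) < 2L) next
    a <- t[-length(t)]; b <- t[-1L]
    keep <- a != b
    a_all <- c(a_all, a[keep]); b_all <- c(b_all, b[keep])
  }
  if (length(a_all) == 0L) {
    edges <- data.frame(word_a = character(0), word_b = character(0),
                        weight = integer(0), stringsAsFactors = FALSE)
  } else {
    lo <- pmin(a_all, b_all); hi <- pmax(a_all, b_all)
    key <- paste(lo, hi, sep = "\r")
    cnt <- table(key)
    parts <- strsplit(names(cnt), "\r", fixed = TRUE)
    edges <- data.frame(word_a = vapply(parts, `[`, "", 1L),
                        word_b = vapply(parts, `[`, "", 2L),
                        weight = as.integer(cnt), stringsAsFactors = FALSE)
    edges <- edges[order(edges$word_a, edges$word_b, method = "radix"), ]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "collocation_graph")
}

#' @exportS3Method base::print
print.collocation_graph <- function(x, ...) {
  cat(sprintf("Collocation graph: %d nodes, %d edges, total weight %d\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Prune a collocation graph to each concept's top-k neighbors
#'
#' For every lexicon concept present in the graph, retains the k
#' highest-weight adjacent words ("closest" neighbors, closeness being
#' adjacency co-occurrence count).  Ties at the k-th rank are broken by
#' lexicographic word order, so the result is deterministic.  Concepts
#' absent from the graph (including multi-word names, whose parts are
#' separate nodes) get an empty neighbor set.
#'
#' @param graph a \code{collocation_graph}.
#' @param lexicon a \code{drug_lexicon}.
#' @param k maximum neighbors per concept (default 15).
#' @return an object of class \code{neighbor_sets}: named list (one entry
#'   per concept found in the graph) of data frames \code{word},
#'   \code{weight} ordered by descending weight then word; attribute
#'   \code{k}.
#' @export
prune_to_top_k <- function(graph, lexicon, k = 15L) {
  stopifnot(inherits(graph, "collocation_graph"),
            inherits(lexicon, "drug_lexicon"))
  k <- stopifnot_scalar_int(k, "k", min = 1L)
  e <- graph$edges
  concepts <- intersect(lexicon$names, graph$nodes)
  out <- vector("list", length(concepts))
  names(out) <- concepts
  for (cpt in concepts) {
    ia <- e$word_a == cpt; ib <- e$word_b == cpt
    nb <- c(e$word_b[ia], e$word_a[ib])
    w  <- c(e$weight[ia], e$weight[ib])
    ord <- order(-w, nb, method = "radix")
    take <- utils::head(ord, k)
    out[[cpt]] <- data.frame(word = nb[take], weight = w[take],
                             stringsAsFactors = FALSE)
  }
  structure(out, class = "neighbor_sets", k = k)
}

#' @exportS3Method base::print
print.neighbor_sets <- function(x, ...) {
  cat(sprintf("Neighbor sets: %d concepts, k = %d\n",
              length(x), attr(x, "k")))
  invisible(x)
}

#' Write a collocation graph as a tab-separated edge list
#'
#' Columns \code{word_a}, \code{word_b}, \code{weight}, with
#' \code{word_a < word_b} and rows in canonical order.  Isolated nodes are
#' listed with an empty \code{word_b} and weight 0 so the node set round
#' trips.
#'
#' @param graph a \code{collocation_graph}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "collocation_graph"))
  touched <- unique(c(graph$edges$word_a, graph$edges$word_b))
  iso <- setdiff(graph$nodes, touched)
  df <- graph$edges
  if (length(iso))
    df <- rbind(df, data.frame(word_a = iso, word_b = "", weight = 0L,
                               stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a collocation graph written by \code{write_graph}
#'
#' @param path path to the edge-list TSV.
#' @return a \code{collocation_graph}.
#' @export
read_graph <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          fileEncoding = "UTF-8", stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer"))
  iso <- df$word_b == "" | is.na(df$word_b)
  edges <- df[!iso, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$word_a, edges$word_b, df$word_a[iso])),
                method = "radix")
  structure(list(nodes = nodes, edges = edges), class = "collocation_graph")
}

#' Write neighbor sets as TSV (concept, rank, neighbor, weight)
#'
#' @param nbs a \code{neighbor_sets}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_neighbor_sets <- function(nbs, path) {
  stopifnot(inherits(nbs, "neighbor_sets"))
  rows <- lapply(names(nbs), function(cpt) {
    d <- nbs[[cpt]]
    if (nrow(d) == 0L) return(NULL)
    data.frame(concept = cpt, rank = seq_len(nrow(d)),
               neighbor = d$word, weight = d$weight, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(concept = character(0), rank = integer(0),
                     neighbor = character(0), weight = integer(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
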