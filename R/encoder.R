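# Contextual encoder: a transformer sequence classifier over subword
# pieces, with a classification marker pooled into a 2-logit head.  The
# "base" preset mirrors the standard 12-layer/768-dim/12-head uncased
# encoder; the "tiny" preset (2 layers, 64 dim, 2 heads) is the same
# architecture at desk scale, randomly initialized, so the full pipeline
# trains and tests without any pretrained download.

#' Encoder configuration
#'
#' @param preset \code{"tiny"} (2 layers, 64 dim, 2 heads, feed-forward
#'   256, learning rate 1e-3, 8 epochs) or \code{"base"} (12 layers, 768
#'   dim, 12 heads, feed-forward 3072, learning rate 5e-5, 3 epochs).
#'   The base learning rate is a fine-tuning rate; the tiny preset trains
#'   from random initialization and uses a correspondingly larger one.
#' @param layers,hidden_dim,heads,ffn_dim architecture overrides;
#'   \code{hidden_dim} must be divisible by \code{heads}.
#' @param cased keep case? (default \code{FALSE}: text is lowercased
#'   before subword tokenization).
#' @param learning_rate,epochs,batch_size training overrides.
#' @param max_length maximum subword pieces per tweet including the
#'   boundary markers (default 128); longer inputs are truncated with a
#'   warning.
#' @param max_words word-level vocabulary cap for the subword tokenizer;
#'   rarer words decompose into character pieces.
#' @param seed RNG seed.
#' @return an object of class \code{encoder_config}.
#' @export
encoder_config <- function(preset = c("tiny", "base"), layers = NULL,
                           hidden_dim = NULL, heads = NULL, ffn_dim = NULL,
                           cased = FALSE, learning_rate = NULL,
                           epochs = NULL, batch_size = 32L,
                           max_length = 128L, max_words = 2000L, seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "base")
    list(layers = 12L, hidden_dim = 768L, heads = 12L, ffn_dim = 3072L,
         learning_rate = 5e-5, epochs = 3L)
  else
    list(layers = 2L, hidden_dim = 64L, heads = 2L, ffn_dim = 256L,
         learning_rate = 1e-3, epochs = 8L)
  cfg <- list(
    preset = preset,
    layers = stopifnot_scalar_int(layers %||% def$layers, "layers"),
    hidden_dim = stopifnot_scalar_int(hidden_dim %||% def$hidden_dim,
                                      "hidden_dim"),
    heads = stopifnot_scalar_int(heads %||% def$heads, "heads"),
    ffn_dim = stopifnot_scalar_int(ffn_dim %||% def$ffn_dim, "ffn_dim"),
    cased = isTRUE(cased),
    learning_rate = as.numeric(learning_rate %||% def$learning_rate),
    epochs = stopifnot_scalar_int(epochs %||% def$epochs, "epochs", min = 0L),
    batch_size = stopifnot_scalar_int(batch_size, "batch_size"),
    max_length = stopifnot_scalar_int(max_length, "max_length", min = 3L),
    max_words = stopifnot_scalar_int(max_words, "max_words"),
    seed = stopifnot_scalar_int(seed, "seed", min = 0L))
  if (cfg$hidden_dim %% cfg$heads != 0L)
    stop("'hidden_dim' must be divisible by 'heads'", call. = FALSE)
  structure(cfg, class = "encoder_config")
}

## ---- Subword tokenizer ------------------------------------------------

PAD_PIECE <- "[PAD]"; CLS_PIECE <- "[CLS]"; SEP_PIECE <- "[SEP]"
UNK_PIECE <- "[UNK]"

#' Build a subword vocabulary from a tokenized corpus
#'
#' Whole words up to \code{max_words} (by frequency, then alphabetically)
#' become single pieces; every character seen also enters the vocabulary
#' both as a word-initial piece and as a \code{##}-prefixed continuation,
#' so any in-alphabet word decomposes greedily into pieces.
#'
#' @param tokens a \code{tokenized_corpus}.
#' @param max_words word-piece cap.
#' @param cased keep case? (default lowercases).
#' @return character vector of pieces (the id of a piece is its position).
#' @export
build_subword_vocab <- function(tokens, max_words = 2000L, cased = FALSE) {
  words <- unlist(tokens$tokens, use.names = FALSE)
  if (!cased) words <- tolower(words)
  tab <- sort(table(words), decreasing = TRUE)
  keep <- utils::head(names(tab)[order(-as.integer(tab), names(tab))],
                      max_words)
  chars <- sort(unique(unlist(strsplit(names(tab), ""), use.names = FALSE)))
  c(PAD_PIECE, CLS_PIECE, SEP_PIECE, UNK_PIECE,
    sort(unique(c(keep, chars))), paste0("##", chars))
}

# Greedy longest-match decomposition of one word into pieces.
word_to_pieces <- function(word, vocab_set) {
  if (word %in% vocab_set) return(word)
  n <- nchar(word)
  pieces <- character(0)
  i <- 1L
  while (i <= n) {
    found <- NA_character_
    for (j in n:i) {
      cand <- substr(word, i, j)
      if (i > 1L) cand <- paste0("##", cand)
      if (cand %in% vocab_set) { found <- cand; i <- j + 1L; break }
    }
    if (is.na(found)) return(UNK_PIECE)
    pieces <- c(pieces, found)
  }
  pieces
}

#' Subword-tokenize a token sequence
#'
#' Produces the piece sequence \code{[CLS] ... [SEP]} with its (all-ones)
#' attention mask; sequences longer than \code{max_length} are truncated
#' (keeping the trailing separator) with a warning.
#'
#' @param words character vector of word tokens.
#' @param vocab piece vocabulary from \code{\link{build_subword_vocab}}.
#' @param max_length maximum pieces including markers.
#' @param cased keep case?
#' @return list with \code{pieces} (character), \code{ids} (integer
#'   indices into \code{vocab}) and \code{attention_mask}.
#' @export
subword_tokenize <- function(words, vocab, max_length = 128L, cased = FALSE) {
  if (!cased) words <- tolower(words)
  body <- unlist(lapply(words, word_to_pieces, vocab_set = vocab),
                 use.names = FALSE)
  if (length(body) > max_length - 2L) {
    warning(sprintf("input truncated to %d subword pieces", max_length),
            call. = FALSE)
    body <- body[seq_len(max_length - 2L)]
  }
  pieces <- c(CLS_PIECE, body, SEP_PIECE)
  ids <- match(pieces, vocab)
  ids[is.na(ids)] <- match(UNK_PIECE, vocab)
  list(pieces = pieces, ids = ids,
       attention_mask = rep(1L, length(pieces)))
}

#' Reassemble words from subword pieces
#'
#' Drops markers and joins \code{##} continuations; inverse of
#' \code{\link{subword_tokenize}} up to whitespace for in-alphabet text.
#'
#' @param pieces character vector of pieces.
#' @return single string of space-separated words.
#' @export
detokenize_pieces <- function(pieces) {
  body <- pieces[!pieces %in% c(PAD_PIECE, CLS_PIECE, SEP_PIECE)]
  out <- character(0)
  for (p in body) {
    if (startsWith(p, "##") && length(out) > 0L)
      out[length(out)] <- paste0(out[length(out)], substring(p, 3L))
    else out <- c(out, p)
  }
  paste(out, collapse = " ")
}

## ---- Transformer ------------------------------------------------------

sinusoidal_positions <- function(max_len, d) {
  P <- matrix(0, max_len, d)
  pos <- seq_len(max_len)
  for (j in seq_len(d)) {
    k <- (j - 1L) %/% 2L
    ang <- pos / 10000^(2 * k / d)
    P[, j] <- if (j %% 2L == 1L) sin(ang) else cos(ang)
  }
  P
}

encoder_init_params <- function(cfg, vocab_size) {
  with_seed(cfg$seed, {
    p <- list(emb = matrix(stats::rnorm(vocab_size * cfg$hidden_dim,
                                        sd = 0.02),
                           vocab_size, cfg$hidden_dim))
    for (l in seq_len(cfg$layers)) {
      ap <- mha_init(cfg$hidden_dim)
      for (nm in names(ap)) p[[paste0("att", l, "_", nm)]] <- ap[[nm]]
      ln1 <- ln_init(cfg$hidden_dim)
      p[[paste0("ln1_", l, "_g")]] <- ln1$g
      p[[paste0("ln1_", l, "_b")]] <- ln1$b
      p[[paste0("ffn", l, "_W1")]] <- xavier(cfg$hidden_dim, cfg$ffn_dim)
      p[[paste0("ffn", l, "_b1")]] <- numeric(cfg$ffn_dim)
      p[[paste0("ffn", l, "_W2")]] <- xavier(cfg$ffn_dim, cfg$hidden_dim)
      p[[paste0("ffn", l, "_b2")]] <- numeric(cfg$hidden_dim)
      ln2 <- ln_init(cfg$hidden_dim)
      p[[paste0("ln2_", l, "_g")]] <- ln2$g
      p[[paste0("ln2_", l, "_b")]] <- ln2$b
    }
    p$cls_W <- xavier(cfg$hidden_dim, 2L)
    p$cls_b <- numeric(2L)
    p
  })
}

encoder_forward_one <- function(ids, params, cfg, pos, keep_cache = FALSE) {
  n <- length(ids)
  X <- params$emb[ids, , drop = FALSE] + pos[seq_len(n), , drop = FALSE]
  layers <- if (keep_cache) vector("list", cfg$layers) else NULL
  for (l in seq_len(cfg$layers)) {
    ap <- params[grep(paste0("^att", l, "_"), names(params))]
    names(ap) <- sub(paste0("^att", l, "_"), "", names(ap))
    r <- mha_forward(X, ap, cfg$heads)
    l1 <- ln_forward(X + r$out, params[[paste0("ln1_", l, "_g")]],
                     params[[paste0("ln1_", l, "_b")]])
    X1 <- l1$out
    pre <- addbias(X1 %*% params[[paste0("ffn", l, "_W1")]],
                   params[[paste0("ffn", l, "_b1")]])
    act <- pmax(pre, 0)
    Fo <- addbias(act %*% params[[paste0("ffn", l, "_W2")]],
                  params[[paste0("ffn", l, "_b2")]])
    l2 <- ln_forward(X1 + Fo, params[[paste0("ln2_", l, "_g")]],
                     params[[paste0("ln2_", l, "_b")]])
    if (keep_cache)
      layers[[l]] <- list(mha = r$cache, ln1 = l1$cache, X1 = X1,
                          pre = pre, act = act, ln2 = l2$cache)
    X <- l2$out
  }
  logits <- as.vector(X[1L, ] %*% params$cls_W) + params$cls_b
  list(logits = logits,
       cache = if (keep_cache) list(ids = ids, layers = layers, Xout = X)
               else NULL)
}

encoder_backward_one <- function(dlogits, cache, params, cfg) {
  g <- list(cls_W = outer(cache$Xout[1L, ], dlogits), cls_b = dlogits)
  n <- length(cache$ids)
  dX <- matrix(0, n, cfg$hidden_dim)
  dX[1L, ] <- as.vector(params$cls_W %*% dlogits)
  for (l in rev(seq_len(cfg$layers))) {
    lc <- cache$layers[[l]]
    r2 <- ln_backward(dX, lc$ln2, params[[paste0("ln2_", l, "_g")]])
    g[[paste0("ln2_", l, "_g")]] <- r2$dg
    g[[paste0("ln2_", l, "_b")]] <- r2$db
    dsum2 <- r2$dX                       # grad of X1 + FFN(X1)
    W2 <- params[[paste0("ffn", l, "_W2")]]
    g[[paste0("ffn", l, "_W2")]] <- crossprod(lc$act, dsum2)
    g[[paste0("ffn", l, "_b2")]] <- colSums(dsum2)
    dact <- tcrossprod(dsum2, W2)
    dpre <- dact * (lc$pre > 0)
    W1 <- params[[paste0("ffn", l, "_W1")]]
    g[[paste0("ffn", l, "_W1")]] <- crossprod(lc$X1, dpre)
    g[[paste0("ffn", l, "_b1")]] <- colSums(dpre)
    dX1 <- dsum2 + tcrossprod(dpre, W1)
    r1 <- ln_backward(dX1, lc$ln1, params[[paste0("ln1_", l, "_g")]])
    g[[paste0("ln1_", l, "_g")]] <- r1$dg
    g[[paste0("ln1_", l, "_b")]] <- r1$db
    dsum1 <- r1$dX                       # grad of X + MHA(X)
    ap <- params[grep(paste0("^att", l, "_"), names(params))]
    names(ap) <- sub(paste0("^att", l, "_"), "", names(ap))
    rm_ <- mha_backward(dsum1, lc$mha, ap, cfg$heads)
    ga <- rm_$grads
    names(ga) <- paste0("att", l, "_", names(ga))
    g <- acc_grads(g, ga)
    dX <- dsum1 + rm_$dX
  }
  demb <- matrix(0, nrow(params$emb), cfg$hidden_dim)
  for (i in seq_len(n)) demb[cache$ids[i], ] <- demb[cache$ids[i], ] + dX[i, ]
  g$emb <- demb
  g
}

#' Fit the contextual-encoder classifier
#'
#' Builds a subword vocabulary from the training corpus, initializes the
#' transformer (randomly; pretrained weights may be supplied via
#' \code{params}) and trains with Adam and cross-entropy.  Deterministic
#' given \code{config$seed}.
#'
#' @param tokens a labeled \code{tokenized_corpus} (both classes present).
#' @param config an \code{\link{encoder_config}}.
#' @param params optional initial parameter list (e.g. from a previous
#'   fit); must match the architecture and vocabulary.
#' @param vocab optional piece vocabulary to reuse with \code{params}.
#' @param train \code{"all"} (default) fine-tunes every layer;
#'   \code{"head"} trains only the classification head.
#' @param verbose print per-epoch loss.
#' @return object of class \code{encoder_model} with \code{params},
#'   \code{config}, \code{vocab}, \code{pos} and \code{loss}.
#' @export
text_encoder <- function(tokens, config = encoder_config("tiny"),
                         params = NULL, vocab = NULL,
                         train = c("all", "head"), verbose = FALSE) {
  stopifnot(inherits(tokens, "tokenized_corpus"),
            inherits(config, "encoder_config"))
  train <- match.arg(train)
  y <- tokens$label
  if (anyNA(y)) stop("all training tweets must be labeled", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training corpus must contain both classes", call. = FALSE)
  if (is.null(vocab))
    vocab <- build_subword_vocab(tokens, config$max_words, config$cased)
  if (is.null(params)) params <- encoder_init_params(config, length(vocab))
  pos <- sinusoidal_positions(config$max_length, config$hidden_dim)
  ids <- lapply(tokens$tokens, function(w)
    subword_tokenize(w, vocab, config$max_length, config$cased)$ids)
  state <- adam_init(params)
  trainable <- if (train == "head") c("cls_W", "cls_b") else names(params)
  n <- length(ids)
  losses <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- epoch_order(n, config$seed, epoch)
    tot <- 0; nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      fwds <- lapply(ids[idx], encoder_forward_one, params = params,
                     cfg = config, pos = pos, keep_cache = TRUE)
      logits <- do.call(rbind, lapply(fwds, `[[`, "logits"))
      lg <- ce_loss_grad(logits, y[idx])
      grads <- list()
      for (b in seq_along(idx))
        grads <- acc_grads(grads,
                           encoder_backward_one(lg$dlogits[b, ],
                                                fwds[[b]]$cache,
                                                params, config))
      grads <- grads[intersect(names(grads), trainable)]
      st <- adam_step(params, grads, state, config$learning_rate)
      params <- st$params; state <- st$state
      tot <- tot + lg$loss; nb <- nb + 1L
    }
    losses[epoch] <- tot / max(nb, 1L)
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f", epoch, config$epochs,
                      losses[epoch]))
  }
  structure(list(params = params, config = config, vocab = vocab,
                 pos = pos, loss = losses),
            class = c("encoder_model", "ade_model"))
}

#' @exportS3Method base::print
print.encoder_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Contextual encoder (%s): %d layers, %d dim, %d heads, %s\n",
              cfg$preset, cfg$layers, cfg$hidden_dim, cfg$heads,
              if (cfg$cased) "cased" else "uncased"))
  cat(sprintf("  vocab %d pieces; trained %d epochs (final loss %.4f)\n",
              length(x$vocab), cfg$epochs,
              if (cfg$epochs > 0) x$loss[cfg$epochs] else NA))
  invisible(x)
}

#' @exportS3Method base::summary
summary.encoder_model <- function(object, ...) {
  print(object)
  npar <- sum(vapply(object$params, length, 0L))
  cat(sprintf("  %d trainable parameters\n", npar))
  invisible(object)
}

encoder_predict_logits <- function(model, tokens) {
  cfg <- model$config
  out <- matrix(0, length(tokens$tokens), 2L)
  for (i in seq_along(tokens$tokens)) {
    ids <- subword_tokenize(tokens$tokens[[i]], model$vocab,
                            cfg$max_length, cfg$cased)$ids
    out[i, ] <- encoder_forward_one(ids, model$params, cfg, model$pos)$logits
  }
  colnames(out) <- c("non_ade", "ade")
  out
}

#' Predict from a fitted encoder model
#'
#' @inheritParams predict.clapa_model
#' @param object an \code{encoder_model}.
#' @export
predict.encoder_model <- function(object, tokens,
                                  type = c("class", "prob", "logits"), ...) {
  type <- match.arg(type)
  logits_to_output(encoder_predict_logits(object, tokens), type)
}

#' Class logits of the encoder for one raw tweet
#'
#' Normalizes the text (lowercasing under an uncased config), subword
#' tokenizes and runs the transformer.
#'
#' @param model a fitted \code{encoder_model}.
#' @param text single raw tweet string (non-empty).
#' @return numeric length-2 logit vector (non-ADE, ADE).
#' @export
encode_to_logits <- function(model, text) {
  words <- normalize_tweet(text)
  if (length(words) == 0L) stop("text normalizes to nothing", call. = FALSE)
  ids <- subword_tokenize(words, model$vocab, model$config$max_length,
                          model$config$cased)$ids
  encoder_forward_one(ids, model$params, model$config, model$pos)$logits
}
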