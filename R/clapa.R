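# CLAPA: collocated LSTM with attentive pooling and aggregated
# representation.  Token embeddings (augmented with collocation-graph
# neighborhoods for lexicon concepts) feed a 4-layer LSTM stack, then 3
# residual multi-head self-attention blocks, then max pooling concatenated
# with attentive pooling, then a fully connected projection to 2 class
# logits (non-ADE, ADE).

#' CLAPA model configuration
#'
#' Defaults follow the reference setup: 4 LSTM layers over 300-dimensional
#' inputs, 3 multi-head attention blocks, 15 collocation neighbors per
#' concept, learning rate 0.001 with cross-entropy loss.  \code{hidden_dim}
#' defaults to \code{input_dim}; smaller values give desk-scale models for
#' testing.
#'
#' @param lstm_layers number of stacked LSTM layers (default 4).
#' @param input_dim embedding dimension fed to the first layer (default 300).
#' @param hidden_dim LSTM/attention width (default \code{input_dim}); must
#'   be divisible by \code{attention_heads}.
#' @param attention_blocks number of residual multi-head attention blocks
#'   (default 3).
#' @param attention_heads heads per block (default 6).
#' @param neighbor_k collocation neighbors retained per concept (default 15).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs training epochs (default 10).
#' @param batch_size minibatch size (default 32).
#' @param max_length token sequences longer than this are truncated
#'   (default 64).
#' @param seed RNG seed controlling initialization and shuffling.
#' @return an object of class \code{clapa_config}.
#' @export
clapa_config <- function(lstm_layers = 4L, input_dim = 300L,
                         hidden_dim = NULL, attention_blocks = 3L,
                         attention_heads = 6L, neighbor_k = 15L,
                         learning_rate = 0.001, epochs = 10L,
                         batch_size = 32L, max_length = 64L, seed = 1L) {
  cfg <- list(
    lstm_layers = stopifnot_scalar_int(lstm_layers, "lstm_layers"),
    input_dim = stopifnot_scalar_int(input_dim, "input_dim"),
    hidden_dim = stopifnot_scalar_int(hidden_dim %||% input_dim, "hidden_dim"),
    attention_blocks = stopifnot_scalar_int(attention_blocks, "attention_blocks"),
    attention_heads = stopifnot_scalar_int(attention_heads, "attention_heads"),
    neighbor_k = stopifnot_scalar_int(neighbor_k, "neighbor_k"),
    learning_rate = as.numeric(learning_rate),
    epochs = stopifnot_scalar_int(epochs, "epochs", min = 0L),
    batch_size = stopifnot_scalar_int(batch_size, "batch_size"),
    max_length = stopifnot_scalar_int(max_length, "max_length"),
    seed = stopifnot_scalar_int(seed, "seed", min = 0L))
  if (cfg$learning_rate < 0)
    stop("'learning_rate' must be >= 0", call. = FALSE)
  if (cfg$hidden_dim %% cfg$attention_heads != 0L)
    stop("'hidden_dim' must be divisible by 'attention_heads'", call. = FALSE)
  structure(cfg, class = "clapa_config")
}

clapa_init_params <- function(cfg) {
  with_seed(cfg$seed, {
    p <- list()
    d_in <- cfg$input_dim
    for (l in seq_len(cfg$lstm_layers)) {
      lp <- lstm_init(d_in, cfg$hidden_dim)
      p[[paste0("lstm", l, "_W")]] <- lp$W
      p[[paste0("lstm", l, "_b")]] <- lp$b
      d_in <- cfg$hidden_dim
    }
    for (a in seq_len(cfg$attention_blocks)) {
      ap <- mha_init(cfg$hidden_dim)
      for (nm in names(ap)) p[[paste0("att", a, "_", nm)]] <- ap[[nm]]
    }
    p$pool_a <- stats::runif(cfg$hidden_dim, -0.1, 0.1)
    p$out_W <- xavier(2L * cfg$hidden_dim, 2L)
    p$out_b <- numeric(2L)
    p
  })
}

# Forward over a batch of embedded sequences (list of [len_i, input_dim]
# matrices).  Returns logits [B, 2] and, optionally, the caches needed by
# the backward pass.
clapa_forward_batch <- function(Xs, params, cfg, keep_cache = FALSE) {
  B <- length(Xs)
  lens <- vapply(Xs, nrow, 0L)
  if (any(lens == 0L)) stop("empty token sequence", call. = FALSE)
  if (any(vapply(Xs, ncol, 0L) != cfg$input_dim))
    stop(sprintf("input vectors have wrong dimension (expected %d)",
                 cfg$input_dim), call. = FALSE)
  Tn <- max(lens)
  h <- cfg$hidden_dim
  X <- lapply(seq_len(Tn), function(t) {
    M <- matrix(0, B, cfg$input_dim)
    for (b in seq_len(B)) if (t <= lens[b]) M[b, ] <- Xs[[b]][t, ]
    M
  })
  lstm_caches <- vector("list", cfg$lstm_layers)
  for (l in seq_len(cfg$lstm_layers)) {
    r <- lstm_forward(X, params[[paste0("lstm", l, "_W")]],
                      params[[paste0("lstm", l, "_b")]])
    lstm_caches[[l]] <- r$cache
    X <- r$h
  }
  Harr <- array(0, c(Tn, B, h))
  for (t in seq_len(Tn)) Harr[t, , ] <- X[[t]]
  logits <- matrix(0, B, 2L)
  ex_cache <- if (keep_cache) vector("list", B) else NULL
  for (b in seq_len(B)) {
    Hb <- matrix(Harr[seq_len(lens[b]), b, ], nrow = lens[b], ncol = h)
    blocks <- if (keep_cache) vector("list", cfg$attention_blocks) else NULL
    Xb <- Hb
    for (a in seq_len(cfg$attention_blocks)) {
      ap <- params[grep(paste0("^att", a, "_"), names(params))]
      names(ap) <- sub(paste0("^att", a, "_"), "", names(ap))
      r <- mha_forward(Xb, ap, cfg$attention_heads)
      if (keep_cache) blocks[[a]] <- r$cache
      Xb <- Xb + r$out
    }
    am <- apply(Xb, 2L, which.max)
    m <- Xb[cbind(am, seq_len(h))]
    s <- as.vector(Xb %*% params$pool_a)
    w <- exp(s - max(s)); w <- w / sum(w)
    pvec <- colSums(Xb * w)
    feat <- c(m, pvec)
    logits[b, ] <- as.vector(feat %*% params$out_W) + params$out_b
    if (keep_cache)
      ex_cache[[b]] <- list(blocks = blocks, Xb = Xb, am = am, w = w,
                            feat = feat)
  }
  list(logits = logits, lens = lens,
       cache = if (keep_cache) list(lstm = lstm_caches, ex = ex_cache,
                                    Tn = Tn, B = B) else NULL)
}

clapa_backward_batch <- function(dlogits, fwd, params, cfg) {
  B <- fwd$cache$B; Tn <- fwd$cache$Tn; h <- cfg$hidden_dim
  lens <- fwd$lens
  grads <- list()
  dHarr <- array(0, c(Tn, B, h))
  for (b in seq_len(B)) {
    ec <- fwd$cache$ex[[b]]
    dl <- dlogits[b, ]
    grads <- acc_grads(grads, list(out_W = outer(ec$feat, dl),
                                   out_b = dl))
    dfeat <- as.vector(params$out_W %*% dl)
    dm <- dfeat[seq_len(h)]
    dp <- dfeat[(h + 1L):(2L * h)]
    Xb <- ec$Xb
    dXb <- matrix(0, nrow(Xb), h)
    dXb[cbind(ec$am, seq_len(h))] <- dm
    dXb <- dXb + ec$w %o% dp
    q <- as.vector(Xb %*% dp)
    ds <- ec$w * (q - sum(ec$w * q))
    dXb <- dXb + ds %o% params$pool_a
    grads <- acc_grads(grads, list(pool_a = as.vector(crossprod(Xb, ds))))
    for (a in rev(seq_len(cfg$attention_blocks))) {
      ap <- params[grep(paste0("^att", a, "_"), names(params))]
      names(ap) <- sub(paste0("^att", a, "_"), "", names(ap))
      r <- mha_backward(dXb, ec$blocks[[a]], ap, cfg$attention_heads)
      g <- r$grads
      names(g) <- paste0("att", a, "_", names(g))
      grads <- acc_grads(grads, g)
      dXb <- dXb + r$dX
    }
    dHarr[seq_len(lens[b]), b, ] <- dHarr[seq_len(lens[b]), b, ] + dXb
  }
  dH <- lapply(seq_len(Tn), function(t) matrix(dHarr[t, , ], B, h))
  for (l in rev(seq_len(cfg$lstm_layers))) {
    W <- params[[paste0("lstm", l, "_W")]]
    r <- lstm_backward(dH, fwd$cache$lstm[[l]], W)
    grads[[paste0("lstm", l, "_W")]] <- r$dW
    grads[[paste0("lstm", l, "_b")]] <- r$db
    dH <- r$dX
  }
  grads
}

#' Forward pass of the CLAPA network on one embedded sequence
#'
#' @param vectors numeric matrix, one row per token, \code{input_dim}
#'   columns.
#' @param params parameter list from \code{\link{clapa}} (component
#'   \code{params}) or \code{clapa_init_params}.
#' @param config the \code{clapa_config} the parameters were built with.
#' @return numeric length-2 logit vector (non-ADE, ADE).
#' @export
clapa_forward <- function(vectors, params, config) {
  if (is.null(dim(vectors))) vectors <- matrix(vectors, 1L)
  clapa_forward_batch(list(vectors), params, config)$logits[1L, ]
}

# Shared epoch shuffling so that joint models replicating the CLAPA stream
# reproduce standalone training exactly.
epoch_order <- function(n, seed, epoch) with_seed(seed + epoch, sample.int(n))

# Embed + truncate every tweet of a tokenized corpus.
clapa_embed_corpus <- function(tokens, table, neighbors, max_length) {
  lapply(tokens$tokens, function(tk) {
    tk <- utils::head(tk, max_length)
    embed_with_neighborhood(tk, table, neighbors)
  })
}

#' Fit a CLAPA classifier
#'
#' Trains the collocated-LSTM/attentive-pooling network on a labeled
#' tokenized corpus with Adam and cross-entropy loss on the 2-class
#' logits.  Training is deterministic given \code{config$seed}.
#'
#' @param tokens a labeled \code{tokenized_corpus} (labels 0/1, both
#'   classes present).
#' @param embeddings an \code{embedding_table} (dimension must equal
#'   \code{config$input_dim}).
#' @param neighbors a \code{neighbor_sets} from \code{\link{prune_to_top_k}}
#'   (may be an empty set, in which case embeddings are used unaugmented).
#' @param config a \code{\link{clapa_config}}.
#' @param verbose print per-epoch loss (default \code{FALSE}).
#' @return object of class \code{clapa_model} with components
#'   \code{params}, \code{config}, \code{neighbors}, \code{embeddings}
#'   and \code{loss} (mean cross-entropy per epoch).
#' @export
clapa <- function(tokens, embeddings, neighbors, config = clapa_config(),
                  verbose = FALSE) {
  stopifnot(inherits(tokens, "tokenized_corpus"),
            inherits(embeddings, "embedding_table"),
            inherits(config, "clapa_config"))
  y <- tokens$label
  if (anyNA(y)) stop("all training tweets must be labeled", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training corpus must contain both classes", call. = FALSE)
  if (embeddings$dim != config$input_dim)
    stop(sprintf("embedding dimension %d != config input_dim %d",
                 embeddings$dim, config$input_dim), call. = FALSE)
  Xs <- clapa_embed_corpus(tokens, embeddings, neighbors, config$max_length)
  params <- clapa_init_params(config)
  state <- adam_init(params)
  n <- length(Xs)
  losses <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- epoch_order(n, config$seed, epoch)
    tot <- 0; nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      fwd <- clapa_forward_batch(Xs[idx], params, config, keep_cache = TRUE)
      lg <- ce_loss_grad(fwd$logits, y[idx])
      grads <- clapa_backward_batch(lg$dlogits, fwd, params, config)
      st <- adam_step(params, grads, state, config$learning_rate)
      params <- st$params; state <- st$state
      tot <- tot + lg$loss; nb <- nb + 1L
    }
    losses[epoch] <- tot / max(nb, 1L)
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f", epoch, config$epochs,
                      losses[epoch]))
  }
  structure(list(params = params, config = config, neighbors = neighbors,
                 embeddings = embeddings, loss = losses),
            class = c("clapa_model", "ade_model"))
}

#' @exportS3Method base::print
print.clapa_model <- function(x, ...) {
  cfg <- x$config
  cat("CLAPA classifier\n")
  cat(sprintf("  %d LSTM layers (input %d, hidden %d), %d attention blocks (%d heads)\n",
              cfg$lstm_layers, cfg$input_dim, cfg$hidden_dim,
              cfg$attention_blocks, cfg$attention_heads))
  cat(sprintf("  neighbor k = %d; trained %d epochs (final loss %.4f)\n",
              cfg$neighbor_k, cfg$epochs,
              if (cfg$epochs > 0) x$loss[cfg$epochs] else NA))
  invisible(x)
}

#' @exportS3Method base::summary
summary.clapa_model <- function(object, ...) {
  print(object)
  npar <- sum(vapply(object$params, length, 0L))
  cat(sprintf("  %d trainable parameters; %d concepts with neighbor sets\n",
              npar, length(object$neighbors)))
  invisible(object)
}

# Logits for a tokenized corpus under a fitted CLAPA model.
clapa_predict_logits <- function(model, tokens, chunk = 64L) {
  Xs <- clapa_embed_corpus(tokens, model$embeddings, model$neighbors,
                           model$config$max_length)
  out <- matrix(0, length(Xs), 2L)
  for (start in seq(1L, length(Xs), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(Xs))
    out[idx, ] <- clapa_forward_batch(Xs[idx], model$params,
                                      model$config)$logits
  }
  colnames(out) <- c("non_ade", "ade")
  out
}

#' Predict from a fitted CLAPA model
#'
#' @param object a \code{clapa_model}.
#' @param tokens a \code{tokenized_corpus} (labels ignored).
#' @param type \code{"class"} (0/1 labels, argmax of the softmax),
#'   \code{"prob"} (ADE-class probability) or \code{"logits"}
#'   (the 2-column pre-softmax matrix).
#' @param ... unused.
#' @return integer vector, numeric vector, or matrix, by \code{type}.
#' @export
predict.clapa_model <- function(object, tokens,
                                type = c("class", "prob", "logits"), ...) {
  type <- match.arg(type)
  lg <- clapa_predict_logits(object, tokens)
  logits_to_output(lg, type)
}

logits_to_output <- function(lg, type) {
  switch(type,
         logits = lg,
         prob = softmax_probs(lg)[, 2L],
         class = as.integer(max.col(lg, ties.method = "first") == 2L))
}
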