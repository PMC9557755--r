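# baCLAPA: two parallel stacks (CLAPA and the contextual encoder), each
# reduced to 2-class logits; the concatenated 4-vector passes through one
# final fully connected layer (bias, no nonlinearity) to the fused logits,
# and softmax gives the binary decision.

#' Fuse CLAPA and encoder logits through the final fully connected layer
#'
#' \code{z_final = FC([z_clapa ; z_bert])}, mapping 4 values to 2.
#'
#' @param z_clapa,z_bert numeric length-2 logit vectors.
#' @param fc_params list with \code{W} (4 x 2 matrix) and \code{b}
#'   (length-2 bias).
#' @return object of class \code{fused_logits}: list \code{z_clapa},
#'   \code{z_bert}, \code{z_final}, plus \code{prob} (softmax of
#'   \code{z_final}) and \code{class} (argmax, 0/1).
#' @export
fuse <- function(z_clapa, z_bert, fc_params) {
  if (length(z_clapa) != 2L || length(z_bert) != 2L)
    stop("logit inputs must have length 2", call. = FALSE)
  stopifnot(is.matrix(fc_params$W), all(dim(fc_params$W) == c(4L, 2L)),
            length(fc_params$b) == 2L)
  z <- c(z_clapa, z_bert)
  zf <- as.vector(z %*% fc_params$W) + fc_params$b
  p <- as.vector(softmax_probs(zf))
  structure(list(z_clapa = as.numeric(z_clapa), z_bert = as.numeric(z_bert),
                 z_final = zf, prob = p,
                 class = as.integer(which.max(zf) == 2L)),
            class = "fused_logits")
}

#' @exportS3Method base::print
print.fused_logits <- function(x, ...) {
  cat(sprintf("z_clapa = (%.3f, %.3f)  z_bert = (%.3f, %.3f)\n",
              x$z_clapa[1], x$z_clapa[2], x$z_bert[1], x$z_bert[2]))
  cat(sprintf("z_final = (%.3f, %.3f)  P(ADE) = %.3f  class = %d\n",
              x$z_final[1], x$z_final[2], x$prob[2], x$class))
  invisible(x)
}

# The projection that makes the fused head equal to CLAPA alone.
clapa_only_projection <- function()
  list(W = rbind(diag(2), matrix(0, 2, 2)), b = numeric(2L))

#' Fit the baCLAPA fusion model
#'
#' Trains the CLAPA stack, the encoder stack and the fusion layer jointly
#' under a single cross-entropy objective on the fused logits.  Each stack
#' keeps its own optimizer and learning rate; batching, shuffling and the
#' CLAPA initialization replicate a standalone \code{\link{clapa}} fit
#' with the same seed, so freezing the fusion layer to the CLAPA-only
#' projection (\code{fusion = "clapa_only"}) reproduces standalone CLAPA
#' exactly.
#'
#' @param tokens labeled \code{tokenized_corpus} (both classes present).
#' @param embeddings an \code{embedding_table} for the CLAPA stack.
#' @param neighbors a \code{neighbor_sets} for the CLAPA stack.
#' @param clapa_cfg a \code{\link{clapa_config}}; its epochs, batch size
#'   and seed drive the joint loop.
#' @param encoder_cfg an \code{\link{encoder_config}}.
#' @param fusion \code{"trained"} (default) or \code{"clapa_only"}
#'   (fusion layer frozen to the identity projection of the CLAPA logits).
#' @param freeze_encoder keep encoder parameters fixed at initialization
#'   (architectural-independence reading); default \code{FALSE} (joint
#'   end-to-end training).
#' @param verbose print per-epoch loss.
#' @return object of class \code{baclapa_model}.
#' @export
baclapa <- function(tokens, embeddings, neighbors,
                    clapa_cfg = clapa_config(),
                    encoder_cfg = encoder_config("tiny"),
                    fusion = c("trained", "clapa_only"),
                    freeze_encoder = FALSE, verbose = FALSE) {
  stopifnot(inherits(tokens, "tokenized_corpus"))
  if (missing(embeddings) || !inherits(embeddings, "embedding_table"))
    stop("missing resource: embedding table", call. = FALSE)
  if (missing(neighbors) || !inherits(neighbors, "neighbor_sets"))
    stop("missing resource: collocation neighbor sets", call. = FALSE)
  fusion <- match.arg(fusion)
  y <- tokens$label
  if (anyNA(y)) stop("all training tweets must be labeled", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training corpus must contain both classes", call. = FALSE)

  c_par <- clapa_init_params(clapa_cfg)
  vocab <- build_subword_vocab(tokens, encoder_cfg$max_words,
                               encoder_cfg$cased)
  e_par <- encoder_init_params(encoder_cfg, length(vocab))
  pos <- sinusoidal_positions(encoder_cfg$max_length, encoder_cfg$hidden_dim)
  f_par <- if (fusion == "clapa_only") clapa_only_projection()
           else with_seed(clapa_cfg$seed + 424243L,
                          list(W = xavier(4L, 2L), b = numeric(2L)))

  Xs <- clapa_embed_corpus(tokens, embeddings, neighbors,
                           clapa_cfg$max_length)
  ids <- lapply(tokens$tokens, function(w)
    subword_tokenize(w, vocab, encoder_cfg$max_length, encoder_cfg$cased)$ids)

  c_state <- adam_init(c_par)
  e_state <- adam_init(e_par)
  f_state <- adam_init(f_par)
  n <- length(Xs)
  losses <- numeric(clapa_cfg$epochs)
  for (epoch in seq_len(clapa_cfg$epochs)) {
    ord <- epoch_order(n, clapa_cfg$seed, epoch)
    tot <- 0; nb <- 0L
    for (start in seq(1L, n, by = clapa_cfg$batch_size)) {
      idx <- ord[start:min(start + clapa_cfg$batch_size - 1L, n)]
      cf <- clapa_forward_batch(Xs[idx], c_par, clapa_cfg, keep_cache = TRUE)
      ef <- lapply(ids[idx], encoder_forward_one, params = e_par,
                   cfg = encoder_cfg, pos = pos,
                   keep_cache = !freeze_encoder && fusion != "clapa_only")
      zb <- do.call(rbind, lapply(ef, `[[`, "logits"))
      Z <- cbind(cf$logits, zb)
      zf <- addbias(Z %*% f_par$W, f_par$b)
      lg <- ce_loss_grad(zf, y[idx])
      dZ <- tcrossprod(lg$dlogits, f_par$W)
      dzc <- dZ[, 1:2, drop = FALSE]
      dzb <- dZ[, 3:4, drop = FALSE]
      c_grads <- clapa_backward_batch(dzc, cf, c_par, clapa_cfg)
      st <- adam_step(c_par, c_grads, c_state, clapa_cfg$learning_rate)
      c_par <- st$params; c_state <- st$state
      if (!freeze_encoder && fusion != "clapa_only") {
        e_grads <- list()
        for (b in seq_along(idx))
          e_grads <- acc_grads(e_grads,
                               encoder_backward_one(dzb[b, ],
                                                    ef[[b]]$cache,
                                                    e_par, encoder_cfg))
        st <- adam_step(e_par, e_grads, e_state, encoder_cfg$learning_rate)
        e_par <- st$params; e_state <- st$state
      }
      if (fusion == "trained") {
        f_grads <- list(W = crossprod(Z, lg$dlogits),
                        b = colSums(lg$dlogits))
        st <- adam_step(f_par, f_grads, f_state, clapa_cfg$learning_rate)
        f_par <- st$params; f_state <- st$state
      }
      tot <- tot + lg$loss; nb <- nb + 1L
    }
    losses[epoch] <- tot / max(nb, 1L)
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f", epoch, clapa_cfg$epochs,
                      losses[epoch]))
  }
  clapa_part <- structure(list(params = c_par, config = clapa_cfg,
                               neighbors = neighbors,
                               embeddings = embeddings, loss = losses),
                          class = c("clapa_model", "ade_model"))
  encoder_part <- structure(list(params = e_par, config = encoder_cfg,
                                 vocab = vocab, pos = pos, loss = losses),
                            class = c("encoder_model", "ade_model"))
  structure(list(clapa = clapa_part, encoder = encoder_part,
                 fc = f_par, fusion = fusion,
                 freeze_encoder = freeze_encoder, loss = losses),
            class = c("baclapa_model", "ade_model"))
}

#' @exportS3Method base::print
print.baclapa_model <- function(x, ...) {
  cat("baCLAPA: CLAPA + contextual encoder, logit-level fusion\n")
  cat(sprintf("  fusion layer: %s%s\n",
              x$fusion,
              if (x$freeze_encoder) " (encoder frozen)" else ""))
  print(x$clapa)
  print(x$encoder)
  invisible(x)
}

#' @exportS3Method base::summary
summary.baclapa_model <- function(object, ...) {
  print(object)
  invisible(object)
}

baclapa_predict_logits <- function(model, tokens) {
  zc <- clapa_predict_logits(model$clapa, tokens)
  zb <- encoder_predict_logits(model$encoder, tokens)
  zf <- addbias(cbind(zc, zb) %*% model$fc$W, model$fc$b)
  colnames(zf) <- c("non_ade", "ade")
  zf
}

#' Predict from a fitted baCLAPA model
#'
#' @inheritParams predict.clapa_model
#' @param object a \code{baclapa_model}.
#' @export
predict.baclapa_model <- function(object, tokens,
                                  type = c("class", "prob", "logits"), ...) {
  type <- match.arg(type)
  logits_to_output(baclapa_predict_logits(object, tokens), type)
}
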