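# Combination of the two language models.
#
# Approach 1 learns a joint next-word distribution: at every step the
# captioner's word scores and the transformer's scores (discretized onto
# the captioner vocabulary via greedy BPE segmentation and the chain rule)
# are concatenated and pushed through a small feed-forward head whose
# softmax gives the fused distribution.  Approach 2 stacks the models: the
# transformer continues the caption emitted by the attention model.

FUSION_FLOOR <- -1e9

#' Discretize the transformer's next-step distribution onto the word vocabulary
#'
#' Each word receives the log-probability of its greedy BPE segmentation
#' continued from the current transformer context (product of stepwise
#' subword probabilities).  The word-level end token maps to the
#' transformer's end-of-text token; other special tokens get the floor
#' score.  Scores are log-probabilities and are not renormalized.
#'
#' @param lm An `lm_model`.
#' @param ctx_ids 0-based transformer context (non-empty).
#' @param sat_vocab The word vocabulary (`rc_vocab`).
#' @param bpe The `bpe_model` shared with the transformer.
#' @return Numeric vector of length `sat_vocab$size`.
#' @export
align_vocabulary <- function(lm, ctx_ids, sat_vocab, bpe) {
  first_lp <- lm_next_logp(lm, ctx_ids)
  W <- sat_vocab$size
  out <- rep(FUSION_FLOOR, W)
  segs <- attr(sat_vocab, "bpe_segs")
  if (is.null(segs)) {
    segs <- lapply(sat_vocab$id2word, function(w) {
      if (w %in% SPECIAL_TOKENS) NULL else bpe_encode(w, bpe)
    })
  }
  for (i in seq_len(W)) {
    word <- sat_vocab$id2word[i]
    if (word == "<end>") {
      out[i] <- first_lp[bpe$eot_id + 1L]
      next
    }
    ids <- segs[[i]]
    if (is.null(ids) || length(ids) == 0L) next
    sc <- first_lp[ids[1L] + 1L]
    if (length(ids) > 1L) {
      ctx <- c(ctx_ids, ids[1L])
      for (j in 2L:length(ids)) {
        if (length(ctx) >= lm$cfg$block) { sc <- FUSION_FLOOR; break }
        sc <- sc + lm_next_logp(lm, ctx)[ids[j] + 1L]
        ctx <- c(ctx, ids[j])
      }
    }
    out[i] <- sc
  }
  out
}

# Precompute and attach BPE segmentations to a vocabulary (speeds up
# repeated alignment calls).
vocab_with_segs <- function(sat_vocab, bpe) {
  attr(sat_vocab, "bpe_segs") <- lapply(sat_vocab$id2word, function(w) {
    if (w %in% SPECIAL_TOKENS) NULL else bpe_encode(w, bpe)
  })
  sat_vocab
}

#' Create a fusion head
#'
#' One hidden layer mapping the concatenated score vectors (2W) through W
#' ReLU units to W logits.
#'
#' @param W Word vocabulary size.
#' @param seed Initialization seed.
#' @return An object of class `fusion_head`.
#' @export
fusion_head_new <- function(W, seed = 1L) {
  p <- with_local_seed(seed, function() list(
    W1 = ag_param(ag_init_w(2L * W, W)), b1 = ag_param(numeric(W)),
    W2 = ag_param(ag_init_w(W, W)), b2 = ag_param(numeric(W))
  ))
  structure(list(W = as.integer(W), params = p), class = "fusion_head")
}

#' Fuse per-word scores from the two models into a distribution
#'
#' @param sat_scores,lm_scores Numeric vectors of length W
#'   (log-probability scores).
#' @param head A `fusion_head`.
#' @return Probability vector of length W (sums to 1).
#' @export
fuse_next_word <- function(sat_scores, lm_scores, head) {
  if (length(sat_scores) != length(lm_scores)) {
    stop("score vectors must have identical length")
  }
  if (length(sat_scores) != head$W) stop("scores do not match head width")
  v <- lapply(head$params, function(p) p$val)
  x <- matrix(c(sat_scores, lm_scores), 1L)
  hmat <- pmax(x %*% v$W1 + v$b1, 0)
  logits <- hmat %*% v$W2 + v$b2
  logits <- logits - max(logits)
  p <- exp(logits)
  as.vector(p / sum(p))
}

#' Train the fusion head with frozen backbones
#'
#' Teacher-forced next-word cross-entropy: for every position of every
#' caption the captioner scores and the aligned transformer scores are
#' precomputed (both backbones frozen), then only the head is optimized.
#'
#' @param head A `fusion_head` (modified in place; returned).
#' @param sat_model Trained `sat_model` (with vocabulary).
#' @param lm Trained `lm_model` (with BPE).
#' @param samples List of lists with `features` and `caption` as in
#'   [sat_train()].
#' @param epochs,lr,batch_size,seed Optimization settings.
#' @param verbose Print per-epoch loss.
#' @return The head, with per-epoch loss in the `history` attribute.
#' @export
train_fusion_head <- function(head, sat_model, lm, samples, epochs = 30L,
                              lr = 1e-3, batch_size = 64L, seed = 1L,
                              verbose = FALSE) {
  vocab <- vocab_with_segs(sat_model$vocab, lm$bpe)
  X <- list(); y <- integer(0)
  for (s in samples) {
    A <- sat_features(sat_model, s$features)
    ids <- s$caption$ids
    st <- sat_init_state(sat_model, A)
    lm_ctx <- lm$bpe$start_id
    v <- sat_vals(sat_model)
    for (t in seq_len(length(ids) - 1L)) {
      at <- sat_attend(sat_model, A, st$h)
      st <- sat_lstm_step(sat_model, ids[t], st$h, st$c, at$context)
      emb <- v$E[ids[t] + 1L, , drop = FALSE]
      sat_lp <- sat_log_dist(v, sat_model$cfg, st$h, at$context, emb)
      lm_lp <- align_vocabulary(lm, lm_ctx, vocab, lm$bpe)
      X[[length(X) + 1L]] <- c(sat_lp, pmax(lm_lp, -50))
      y <- c(y, ids[t + 1L] + 1L)
      word <- vocab$id2word[ids[t + 1L] + 1L]
      if (!(word %in% SPECIAL_TOKENS)) {
        lm_ctx <- c(lm_ctx, bpe_encode(word, lm$bpe))
      }
    }
  }
  Xm <- do.call(rbind, X)
  n <- nrow(Xm)
  adam <- ag_adam_init(head$params)
  history <- numeric(epochs)
  p <- head$params
  with_local_seed(seed, function() {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        take <- ord[start:min(start + batch_size - 1L, n)]
        ag_reset()
        xb <- ag_const(Xm[take, , drop = FALSE])
        hmat <- ag_relu(ag_add(ag_mm(xb, p$W1), p$b1))
        logits <- ag_add(ag_mm(hmat, p$W2), p$b2)
        loss <- ag_scale(ag_ce_rows(logits, y[take]), 1 / length(take))
        ag_backward(loss)
        adam <<- ag_adam_step(head$params, adam, lr)
        ep_loss <- ep_loss + as.vector(loss$val) * length(take)
      }
      history[ep] <<- ep_loss / n
      if (verbose) message(sprintf("fusion epoch %d/%d  loss %.4f",
                                   ep, epochs, history[ep]))
    }
  })
  attr(head, "history") <- history
  head
}

#' Generate a report with the joint-distribution fusion (Approach 1)
#'
#' Stepwise decoding where each next word is the argmax of the fused
#' distribution; both models advance with the chosen word (the transformer
#' branch can be frozen in place with `advance_lm = FALSE`).
#'
#' @param image Image, feature grid, or feature matrix.
#' @param sat_model Trained `sat_model` with vocabulary.
#' @param lm Trained `lm_model` with BPE.
#' @param head Trained `fusion_head`.
#' @param max_len Maximum words generated.
#' @param advance_lm Feed chosen words back into the transformer context.
#' @return List with `report` (text), `ids`, `tokens`.
#' @export
generate_approach1 <- function(image, sat_model, lm, head, max_len = 50L,
                               advance_lm = TRUE) {
  vocab <- vocab_with_segs(sat_model$vocab, lm$bpe)
  A <- sat_features(sat_model, image)
  v <- sat_vals(sat_model)
  st <- sat_init_state(sat_model, A)
  lm_ctx <- lm$bpe$start_id
  prev <- START_ID
  out <- integer(0)
  for (t in seq_len(max_len)) {
    at <- sat_attend(sat_model, A, st$h)
    st <- sat_lstm_step(sat_model, prev, st$h, st$c, at$context)
    emb <- v$E[prev + 1L, , drop = FALSE]
    sat_lp <- sat_log_dist(v, sat_model$cfg, st$h, at$context, emb)
    lm_lp <- pmax(align_vocabulary(lm, lm_ctx, vocab, lm$bpe), -50)
    pr <- fuse_next_word(sat_lp, lm_lp, head)
    w <- which.max(pr) - 1L
    out <- c(out, w)
    prev <- w
    if (w == END_ID) break
    word <- vocab$id2word[w + 1L]
    if (advance_lm && !(word %in% SPECIAL_TOKENS)) {
      lm_ctx <- c(lm_ctx, bpe_encode(word, lm$bpe))
    }
    if (length(lm_ctx) >= lm$cfg$block - 2L) advance_lm <- FALSE
  }
  tokens <- vocab_decode(out, vocab)
  list(report = paste(tokens, collapse = " "), ids = out, tokens = tokens)
}

#' Generate a report by stacking the models (Approach 2)
#'
#' The captioner decodes first (beam search, `sat_k`); its text seeds the
#' transformer, which continues the report until end-of-text.  The result
#' keeps provenance markers separating the caption seed from the
#' continuation.
#'
#' @param image Image, feature grid, or feature matrix.
#' @param sat_model Trained `sat_model` with vocabulary.
#' @param lm Trained `lm_model` with BPE.
#' @param sat_k Beam width for the captioner (1 = greedy).
#' @param lm_k Beam width for the continuation.
#' @param lm_rank Beam hypothesis rank used as the continuation.
#' @param max_len Maximum caption words.
#' @return List with `report`, `sat_seed`, `lm_continuation`.
#' @export
generate_approach2 <- function(image, sat_model, lm, sat_k = 1L, lm_k = 3L,
                               lm_rank = 2L, max_len = 50L) {
  cap <- if (sat_k <= 1L) greedy_decode(sat_model, image, max_len)
         else beam_decode(sat_model, image, sat_k, max_len)[[1L]]
  tokens <- vocab_decode(cap$ids, sat_model$vocab)
  seed_text <- paste(tokens, collapse = " ")
  if (!nzchar(seed_text)) seed_text <- "."
  cont <- continue_report(lm, seed_text, k = lm_k, rank = lm_rank)
  list(report = cont$report, sat_seed = seed_text,
       lm_continuation = cont$continuation)
}
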