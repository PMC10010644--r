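# Decoder-only transformer language model over BPE subwords.
#
# A stack of pre-norm blocks, each a masked (causal) multi-head
# self-attention sublayer followed by a position-wise feed-forward network,
# with learned positional embeddings and a linear head to subword logits.
# Position t's output depends only on positions <= t.  The model is
# fine-tuned self-supervised on report text (next-token cross-entropy with
# global-norm gradient clipping) and continues a caption seed until it
# emits the end-of-text token.

#' Transformer configuration
#'
#' @param vocab_size BPE vocabulary size.
#' @param layers Number of decoder blocks.
#' @param heads Attention heads (must divide `dim`).
#' @param dim Model width.
#' @param ffn_dim Feed-forward hidden width.
#' @param block Maximum sequence length (context window).
#' @param dropout Dropout probability during training.
#' @param seed Seed for weight initialization.
#' @return A `lm_config` list.
#' @export
lm_config <- function(vocab_size, layers = 2L, heads = 2L, dim = 128L,
                      ffn_dim = 4L * dim, block = 256L, dropout = 0,
                      seed = 1L) {
  if (dim %% heads != 0L) stop("dim must be divisible by heads")
  if (block < 2L) stop("block must be >= 2")
  structure(list(V = as.integer(vocab_size), layers = as.integer(layers),
                 heads = as.integer(heads), d = as.integer(dim),
                 ffn = as.integer(ffn_dim), block = as.integer(block),
                 dropout = dropout, seed = as.integer(seed)),
            class = "lm_config")
}

#' Create a transformer language model
#'
#' @param cfg An [lm_config()].
#' @param bpe Optional `bpe_model` carried for text encode/decode.
#' @return An object of class `lm_model`.
#' @export
lm_new <- function(cfg, bpe = NULL) {
  stopifnot(inherits(cfg, "lm_config"))
  d <- cfg$d
  p <- with_local_seed(cfg$seed, function() {
    out <- list(
      tok = ag_param(ag_init_w(cfg$V, d) * 0.5),
      pos = ag_param(ag_init_w(cfg$block, d) * 0.5),
      lnf_g = ag_param(rep(1, d)), lnf_b = ag_param(numeric(d)),
      head = ag_param(ag_init_w(d, cfg$V)), head_b = ag_param(numeric(cfg$V))
    )
    for (l in seq_len(cfg$layers)) {
      out[[paste0("ln1_g", l)]] <- ag_param(rep(1, d))
      out[[paste0("ln1_b", l)]] <- ag_param(numeric(d))
      out[[paste0("Wq", l)]] <- ag_param(ag_init_w(d, d))
      out[[paste0("Wk", l)]] <- ag_param(ag_init_w(d, d))
      out[[paste0("Wv", l)]] <- ag_param(ag_init_w(d, d))
      out[[paste0("Wo", l)]] <- ag_param(ag_init_w(d, d))
      out[[paste0("bo", l)]] <- ag_param(numeric(d))
      out[[paste0("ln2_g", l)]] <- ag_param(rep(1, d))
      out[[paste0("ln2_b", l)]] <- ag_param(numeric(d))
      out[[paste0("Wf1", l)]] <- ag_param(ag_init_w(d, cfg$ffn))
      out[[paste0("bf1", l)]] <- ag_param(numeric(cfg$ffn))
      out[[paste0("Wf2", l)]] <- ag_param(ag_init_w(cfg$ffn, d))
      out[[paste0("bf2", l)]] <- ag_param(numeric(d))
    }
    out
  })
  structure(list(cfg = cfg, params = p, bpe = bpe), class = "lm_model")
}

#' @export
print.lm_model <- function(x, ...) {
  cat("<lm_model>", x$cfg$layers, "layers,", x$cfg$heads, "heads, dim",
      x$cfg$d, ", block", x$cfg$block, ", vocab", x$cfg$V, "\n")
  invisible(x)
}

#' Token + positional embedding
#'
#' @param model An `lm_model`.
#' @param ids 0-based subword ids (length <= block).
#' @return `(length(ids), dim)` matrix.
#' @export
lm_embed <- function(model, ids) {
  if (length(ids) > model$cfg$block) stop("sequence exceeds block size")
  model$params$tok$val[ids + 1L, , drop = FALSE] +
    model$params$pos$val[seq_along(ids), , drop = FALSE]
}

# Forward graph; returns the (T, V) logits node.
lm_graph <- function(model, ids, training = FALSE) {
  cfg <- model$cfg
  p <- model$params
  T_ <- length(ids)
  if (T_ > cfg$block) stop("sequence exceeds block size")
  if (T_ < 1L) stop("empty sequence")
  x <- ag_add(ag_rows(p$tok, ids + 1L), ag_rows(p$pos, seq_len(T_)))
  x <- ag_dropout(x, cfg$dropout, training)
  dk <- cfg$d %/% cfg$heads
  mask <- matrix(0, T_, T_)
  mask[upper.tri(mask)] <- -1e9
  maskn <- ag_const(mask)
  for (l in seq_len(cfg$layers)) {
    a <- ag_layernorm(x, p[[paste0("ln1_g", l)]], p[[paste0("ln1_b", l)]])
    Q <- ag_mm(a, p[[paste0("Wq", l)]])
    K <- ag_mm(a, p[[paste0("Wk", l)]])
    V <- ag_mm(a, p[[paste0("Wv", l)]])
    heads <- vector("list", cfg$heads)
    for (h in seq_len(cfg$heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      Qh <- ag_cols(Q, cols); Kh <- ag_cols(K, cols)
      Vh <- ag_cols(V, cols)
      att <- ag_softmax_rows(ag_add(ag_scale(ag_mm_t(Qh, Kh), 1 / sqrt(dk)),
                                    maskn))
      heads[[h]] <- ag_mm(att, Vh)
    }
    sa <- ag_add(ag_mm(ag_cbind(heads), p[[paste0("Wo", l)]]),
                 p[[paste0("bo", l)]])
    sa <- ag_dropout(sa, cfg$dropout, training)
    x <- ag_add(x, sa)
    b <- ag_layernorm(x, p[[paste0("ln2_g", l)]], p[[paste0("ln2_b", l)]])
    ff <- ag_add(ag_mm(ag_relu(ag_add(ag_mm(b, p[[paste0("Wf1", l)]]),
                                      p[[paste0("bf1", l)]])),
                       p[[paste0("Wf2", l)]]),
                 p[[paste0("bf2", l)]])
    ff <- ag_dropout(ff, cfg$dropout, training)
    x <- ag_add(x, ff)
  }
  x <- ag_layernorm(x, p$lnf_g, p$lnf_b)
  ag_add(ag_mm(x, p$head), p$head_b)
}

lm_untracked <- function(model, fn) {
  old <- vapply(model$params, function(p) isTRUE(p$tracked), TRUE)
  for (p in model$params) p$tracked <- FALSE
  on.exit({
    for (k in seq_along(model$params)) {
      model$params[[k]]$tracked <- old[[k]]
    }
  })
  fn()
}

#' Causal forward pass: logits for every position
#'
#' @param model An `lm_model`.
#' @param ids 0-based subword ids.
#' @return `(length(ids), V)` logits matrix; row t depends only on
#'   positions <= t.
#' @export
lm_logits <- function(model, ids) {
  lm_untracked(model, function() lm_graph(model, ids)$val)
}

#' Mean next-token cross-entropy of a sequence
#'
#' @param model An `lm_model`.
#' @param ids 0-based ids (length >= 2).
#' @return Nats per predicted token.
#' @export
lm_loss <- function(model, ids) {
  stopifnot(length(ids) >= 2L)
  lg <- lm_logits(model, ids)
  T_ <- length(ids)
  lg <- lg[seq_len(T_ - 1L), , drop = FALSE]
  m <- apply(lg, 1L, max)
  logp <- lg - (m + log(rowSums(exp(lg - m))))
  -mean(logp[cbind(seq_len(T_ - 1L), ids[-1L] + 1L)])
}

#' Fine-tune the transformer as a language model
#'
#' Self-supervised next-token training over fixed-length blocks of the
#' BPE-encoded corpus, with Adam and global gradient-norm clipping.
#'
#' @param model An `lm_model` (modified in place; returned).
#' @param corpus Character vector of report texts, or a list of 0-based id
#'   vectors (already framed).
#' @param epochs Training epochs.
#' @param lr Learning rate.
#' @param grad_clip Global gradient-norm threshold (`0` freezes the model).
#' @param batch_size Documents per optimizer step.
#' @param seed Shuffling/dropout seed.
#' @param verbose Print per-epoch loss.
#' @return The model, with per-epoch mean loss in the `history` attribute.
#' @export
lm_finetune <- function(model, corpus, epochs = 30L, lr = 5e-5,
                        grad_clip = 1.0, batch_size = 4L, seed = 1L,
                        verbose = FALSE) {
  is_text <- is.character(corpus)
  docs <- if (is_text) {
    if (is.null(model$bpe)) stop("text corpus requires model$bpe")
    # raw ids; the start-of-continuation marker is inserted at a sampled
    # split point each epoch so the model learns to continue any prefix
    lapply(corpus, function(tx) bpe_encode(tx, model$bpe))
  } else corpus
  docs <- lapply(docs, function(d) {
    if (length(d) > model$cfg$block - 2L) d[seq_len(model$cfg$block - 2L)]
    else d
  })
  docs <- docs[vapply(docs, length, 1L) >= 1L]
  if (length(docs) == 0) stop("empty corpus")
  frame_doc <- function(d) {
    if (!is_text) return(d)
    cut <- sample.int(length(d) + 1L, 1L) - 1L
    c(if (cut > 0L) d[seq_len(cut)], model$bpe$start_id,
      if (cut < length(d)) d[(cut + 1L):length(d)], model$bpe$eot_id)
  }
  adam <- ag_adam_init(model$params)
  history <- numeric(epochs)
  with_local_seed(seed, function() {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(docs))
      ep_loss <- 0; ep_tok <- 0L
      for (start in seq(1L, length(docs), by = batch_size)) {
        take <- ord[start:min(start + batch_size - 1L, length(docs))]
        ag_reset()
        losses <- list(); ntok <- 0L
        for (i in take) {
          ids <- frame_doc(docs[[i]])
          lg <- lm_graph(model, ids, training = TRUE)
          T_ <- length(ids)
          lg_in <- ag_rows(lg, seq_len(T_ - 1L))
          losses[[length(losses) + 1L]] <-
            ag_ce_rows(lg_in, ids[-1L] + 1L)
          ntok <- ntok + T_ - 1L
        }
        loss <- ag_scale(ag_sum_nodes(losses), 1 / ntok)
        ag_backward(loss)
        adam <<- ag_adam_step(model$params, adam, lr, clip = grad_clip)
        ep_loss <- ep_loss + as.vector(loss$val) * ntok
        ep_tok <- ep_tok + ntok
      }
      history[ep] <<- ep_loss / ep_tok
      if (verbose) {
        message(sprintf("lm epoch %d/%d  loss %.4f", ep, epochs,
                        history[ep]))
      }
    }
  })
  attr(model, "history") <- history
  model
}

# Log-probabilities of the next subword given a 0-based context.
lm_next_logp <- function(model, ctx_ids) {
  lg <- lm_logits(model, ctx_ids)
  row <- lg[nrow(lg), ]
  m <- max(row)
  row - (m + log(sum(exp(row - m))))
}

lm_step_fn <- function(model) {
  function(state, prev_id) {
    ctx <- c(state, prev_id)
    list(logp = lm_next_logp(model, ctx), state = ctx, extra = NULL)
  }
}

#' Continue a report from a caption seed
#'
#' Appends the start-of-continuation token to the seed text and generates
#' with K-beam search until the end-of-text token or the block bound.  The
#' returned continuation is the beam hypothesis of rank `rank` (default 2,
#' the second-best sentence), falling back to the best when fewer
#' hypotheses complete or `k = 1`.
#'
#' @param model An `lm_model` with a `bpe` tokenizer.
#' @param seed_text Non-empty caption text produced upstream.
#' @param k Beam width.
#' @param rank Hypothesis rank to return (1 = best).
#' @param max_new Maximum number of generated subwords; defaults to the
#'   remaining block capacity.
#' @return List with `report` (seed + continuation), `continuation`,
#'   `seed_text`, `ids`.
#' @export
continue_report <- function(model, seed_text, k = 3L, rank = 2L,
                            max_new = NULL) {
  if (is.null(model$bpe)) stop("continue_report requires model$bpe")
  if (!nzchar(trimws(seed_text))) stop("empty seed text")
  seed_ids <- c(bpe_encode(seed_text, model$bpe), model$bpe$start_id)
  if (length(seed_ids) >= model$cfg$block) stop("seed exceeds block size")
  cap <- model$cfg$block - length(seed_ids) - 1L
  if (is.null(max_new)) max_new <- cap else max_new <- min(max_new, cap)
  # beam over continuations; the search is primed so that the first step
  # conditions on the full seed
  init_state <- seed_ids[-length(seed_ids)]
  hyps <- beam_search(lm_step_fn(model), init_state, k, max_new,
                      start_id = seed_ids[length(seed_ids)],
                      end_id = model$bpe$eot_id)
  pick <- min(max(rank, 1L), length(hyps))
  ids <- hyps[[pick]]$ids
  ids <- ids[ids != model$bpe$eot_id]
  continuation <- bpe_decode(ids, model$bpe)
  report <- trimws(paste(seed_text, continuation))
  list(report = report, continuation = continuation,
       seed_text = seed_text, ids = ids)
}

#' Save / load a transformer checkpoint
#' @param model An `lm_model`.
#' @param path RDS file path.
#' @return `lm_load` returns the restored model.
#' @export
lm_save <- function(model, path) {
  saveRDS(list(cfg = unclass(model$cfg),
               params = lapply(model$params, function(p) p$val),
               bpe = if (!is.null(model$bpe))
                 list(merges = model$bpe$merges,
                      id2sym = model$bpe$id2sym)),
          path)
  invisible(path)
}

#' @rdname lm_save
#' @export
lm_load <- function(path) {
  ck <- readRDS(path)
  cfg <- structure(ck$cfg, class = "lm_config")
  bpe <- if (!is.null(ck$bpe)) {
    sym2id <- stats::setNames(seq_along(ck$bpe$id2sym) - 1L, ck$bpe$id2sym)
    structure(list(merges = ck$bpe$merges, id2sym = ck$bpe$id2sym,
                   sym2id = sym2id, start_id = 0L, eot_id = 1L,
                   size = length(ck$bpe$id2sym)),
              class = "bpe_model")
  }
  model <- lm_new(cfg, bpe)
  for (k in names(ck$params)) model$params[[k]]$val <- ck$params[[k]]
  model
}
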