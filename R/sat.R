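# Soft-attention captioner ("show, attend and tell" family).
#
# An LSTM decoder attends over the N = D^2 spatial locations of the encoder
# feature grid.  At step t the attention MLP scores every location from
# (a_i, h_{t-1}), a softmax turns scores into weights alpha_t that sum to 1,
# and the context vector is the weighted sum of location features.  The LSTM
# input is [E z_{t-1}; h_{t-1}; a_hat_t]; the next-word distribution is a
# deep output layer softmax(L_o(L_h h_t + L_a a_hat_t + E z_{t-1})).
# Training is teacher-forced cross-entropy over non-pad positions with
# per-step effective batch sizes; no attention regularizer is used.

#' Configuration for the attention captioner
#'
#' @param vocab_size Word vocabulary size W (including special tokens).
#' @param embed_dim Word embedding dimension m.
#' @param hidden_dim LSTM (and attention) dimension n.
#' @param att_dim Attention MLP width; defaults to `hidden_dim`.
#' @param feat_dim Encoder channel count C.
#' @param ctx_dim Number of leading feature channels used by the attention
#'   MLP and the context vector; defaults to all of them.  When the
#'   encoder appends broadcast global-context channels, restricting the
#'   context to the local channels keeps attention the only route by which
#'   positional evidence reaches the decoder (the init MLPs always see the
#'   full feature mean).
#' @param n_locations Number of spatial locations N = D^2.
#' @param dropout Dropout probability applied before the deep output layer.
#' @param max_len Maximum caption length (framed).
#' @param seed Seed for weight initialization.
#' @return A `sat_config` list.
#' @export
sat_config <- function(vocab_size, embed_dim = 100L, hidden_dim = 512L,
                       att_dim = NULL, feat_dim = 64L, ctx_dim = NULL,
                       n_locations = 49L, dropout = 0.1, max_len = 100L,
                       seed = 1L) {
  if (is.null(att_dim)) att_dim <- hidden_dim
  if (is.null(ctx_dim)) ctx_dim <- feat_dim
  stopifnot(vocab_size > 0, embed_dim > 0, hidden_dim > 0, att_dim > 0,
            feat_dim > 0, n_locations > 0, ctx_dim > 0,
            ctx_dim <= feat_dim)
  structure(list(W = as.integer(vocab_size), m = as.integer(embed_dim),
                 n = as.integer(hidden_dim), att = as.integer(att_dim),
                 C = as.integer(feat_dim), Cc = as.integer(ctx_dim),
                 N = as.integer(n_locations),
                 dropout = dropout, max_len = as.integer(max_len),
                 seed = as.integer(seed)),
            class = "sat_config")
}

#' Build a captioner configuration matched to an encoder
#'
#' Convenience wrapper setting `feat_dim`, `ctx_dim` and `n_locations`
#' from the encoder (global-context channels, when present, are excluded
#' from the attention context).
#'
#' @param encoder An `rc_encoder`.
#' @param vocab_size Word vocabulary size.
#' @param ... Passed to [sat_config()].
#' @return A `sat_config`.
#' @export
sat_config_for <- function(encoder, vocab_size, ...) {
  g <- encoder$cfg$global_channels
  if (is.null(g)) g <- 0L
  sat_config(vocab_size, feat_dim = encoder$cfg$C,
             ctx_dim = encoder$cfg$C - g,
             n_locations = encoder$cfg$D^2, ...)
}

#' Create an attention captioner
#'
#' @param cfg A [sat_config()].
#' @param encoder An encoder from [encoder_new()] whose feature grid matches
#'   `cfg$C` and `cfg$N`; may be `NULL` when the model is driven from
#'   precomputed feature grids.
#' @param vocab The `rc_vocab` the captions are encoded with (stored for
#'   decoding convenience).
#' @return An object of class `sat_model`.
#' @export
sat_new <- function(cfg, encoder = NULL, vocab = NULL) {
  stopifnot(inherits(cfg, "sat_config"))
  if (!is.null(encoder)) {
    stopifnot(encoder$cfg$C == cfg$C, encoder$cfg$D^2 == cfg$N)
  }
  p <- with_local_seed(cfg$seed, function() list(
    E = ag_param(ag_init_w(cfg$W, cfg$m)),
    W_ih = ag_param(ag_init_w(cfg$C, cfg$n)), b_ih = ag_param(numeric(cfg$n)),
    W_ic = ag_param(ag_init_w(cfg$C, cfg$n)), b_ic = ag_param(numeric(cfg$n)),
    U_att = ag_param(ag_init_w(cfg$Cc, cfg$att)),
    V_att = ag_param(ag_init_w(cfg$n, cfg$att)),
    b_att = ag_param(numeric(cfg$att)),
    w_att = ag_param(ag_init_w(cfg$att, 1L)),
    W_lstm = ag_param(ag_init_w(cfg$m + cfg$n + cfg$Cc, 4L * cfg$n)),
    b_lstm = ag_param(numeric(4L * cfg$n)),
    L_h = ag_param(ag_init_w(cfg$n, cfg$m)),
    L_a = ag_param(ag_init_w(cfg$Cc, cfg$m)),
    L_o = ag_param(ag_init_w(cfg$m, cfg$W)),
    b_o = ag_param(numeric(cfg$W))
  ))
  structure(list(cfg = cfg, params = p, encoder = encoder, vocab = vocab),
            class = "sat_model")
}

#' @export
print.sat_model <- function(x, ...) {
  cat("<sat_model> W =", x$cfg$W, " m =", x$cfg$m, " n =", x$cfg$n,
      " C =", x$cfg$C, " N =", x$cfg$N, "\n")
  invisible(x)
}

sat_vals <- function(model) lapply(model$params, function(p) p$val)

# ---- single-step operations (plain matrix math, used in decoding and as
# ---- the public contract mirrored by the training graph) -------------------

#' Initialize the LSTM state from a feature grid
#'
#' Two separate one-layer perceptrons (tanh) applied to the mean location
#' feature vector give h0 and c0.
#'
#' @param model A `sat_model`.
#' @param features `(N, C)` feature matrix.
#' @return List with `h` and `c`, each `1 x n`.
#' @export
sat_init_state <- function(model, features) {
  v <- sat_vals(model)
  mu <- matrix(colMeans(features), 1L)
  list(h = tanh(mu %*% v$W_ih + v$b_ih),
       c = tanh(mu %*% v$W_ic + v$b_ic))
}

#' Attend over feature locations
#'
#' Scores e_i = w' relu(U a_i + V h_prev + b), weights alpha = softmax(e),
#' context = sum_i alpha_i a_i.
#'
#' @param model A `sat_model`.
#' @param features `(N, C)` feature matrix.
#' @param h_prev `1 x n` hidden state.
#' @return List with `alpha` (length N, sums to 1) and `context` (`1 x C`).
#' @export
sat_attend <- function(model, features, h_prev) {
  v <- sat_vals(model)
  loc <- features[, seq_len(model$cfg$Cc), drop = FALSE]
  act <- loc %*% v$U_att +
    matrix(rep(h_prev %*% v$V_att, each = nrow(loc)), nrow(loc)) +
    matrix(rep(v$b_att, each = nrow(loc)), nrow(loc))
  e <- pmax(act, 0) %*% v$w_att
  e <- e - max(e)
  alpha <- as.vector(exp(e) / sum(exp(e)))
  list(alpha = alpha,
       context = matrix(colSums(loc * alpha), 1L))
}

#' One LSTM step
#'
#' Gates `[i, f, o, g]` come from one affine map of the concatenation
#' `[E z_prev; h_prev; context]`; then `c = f*c_prev + i*g`,
#' `h = o*tanh(c)`.
#'
#' @param model A `sat_model`.
#' @param prev_token_id 0-based previous word id.
#' @param h_prev,c_prev `1 x n` state.
#' @param context `1 x C` context vector.
#' @return List with `h` and `c`.
#' @export
sat_lstm_step <- function(model, prev_token_id, h_prev, c_prev, context) {
  v <- sat_vals(model)
  n <- model$cfg$n
  emb <- v$E[prev_token_id + 1L, , drop = FALSE]
  gates <- cbind(emb, h_prev, context) %*% v$W_lstm + v$b_lstm
  i <- 1 / (1 + exp(-gates[, 1:n, drop = FALSE]))
  f <- 1 / (1 + exp(-gates[, (n + 1):(2 * n), drop = FALSE]))
  o <- 1 / (1 + exp(-gates[, (2 * n + 1):(3 * n), drop = FALSE]))
  g <- tanh(gates[, (3 * n + 1):(4 * n), drop = FALSE])
  cc <- f * c_prev + i * g
  list(h = o * tanh(cc), c = cc)
}

#' Next-word probability distribution (deep output layer)
#'
#' @param model A `sat_model`.
#' @param h `1 x n` hidden state.
#' @param context `1 x C` context vector.
#' @param prev_token_id 0-based previous word id.
#' @return Numeric vector of W probabilities summing to 1.
#' @export
sat_output_distribution <- function(model, h, context, prev_token_id) {
  v <- sat_vals(model)
  emb <- v$E[prev_token_id + 1L, , drop = FALSE]
  logits <- (h %*% v$L_h + context %*% v$L_a + emb) %*% v$L_o + v$b_o
  logits <- logits - max(logits)
  p <- exp(logits)
  as.vector(p / sum(p))
}

sat_log_dist <- function(v, cfg, h, context, emb) {
  logits <- (h %*% v$L_h + context %*% v$L_a + emb) %*% v$L_o + v$b_o
  m <- max(logits)
  as.vector(logits - (m + log(sum(exp(logits - m)))))
}

# ---- feature access --------------------------------------------------------

sat_features <- function(model, image_or_grid) {
  if (is.list(image_or_grid) && !is.null(image_or_grid$features)) {
    return(image_or_grid$features)
  }
  if (is.matrix(image_or_grid) &&
      ncol(image_or_grid) == model$cfg$C &&
      nrow(image_or_grid) == model$cfg$N) {
    return(image_or_grid)
  }
  if (is.null(model$encoder)) stop("model has no encoder; pass a feature grid")
  encode_image(model$encoder, image_or_grid)$features
}

# ---- teacher-forced training graph -----------------------------------------

# Build the forward graph for one sorted batch and return the summed
# cross-entropy node plus token count.  `feat_nodes` is a list of ag_nodes,
# one (N, C) per sample, already in decreasing caption length order.
sat_batch_graph <- function(model, feat_nodes, ids, lengths,
                            training = TRUE) {
  cfg <- model$cfg
  p <- model$params
  B <- length(feat_nodes)
  N <- cfg$N
  if (is.unsorted(rev(lengths))) stop("batch must be sorted by decreasing length")
  A2 <- ag_rbind(feat_nodes)                      # (B*N, C)
  A2c <- if (cfg$Cc < cfg$C) ag_cols(A2, seq_len(cfg$Cc)) else A2
  Mmean <- matrix(0, B, B * N)
  for (b in seq_len(B)) Mmean[b, ((b - 1) * N + 1):(b * N)] <- 1 / N
  mu <- ag_mm(ag_const(Mmean), A2)                # (B, C)
  H <- ag_tanh(ag_add(ag_mm(mu, p$W_ih), p$b_ih))
  Cs <- ag_tanh(ag_add(ag_mm(mu, p$W_ic), p$b_ic))
  Ua <- ag_mm(A2c, p$U_att)                       # (B*N, att)
  n <- cfg$n
  losses <- list()
  total <- 0L
  sum_mats <- list()
  Tmax <- max(lengths)
  for (t in seq_len(Tmax - 1L)) {
    bt <- sum(lengths >= t + 1L)
    if (bt == 0L) break
    act <- seq_len(bt * N)
    H_act <- if (bt == nrow(H$val)) H else ag_rows(H, seq_len(bt))
    C_act <- if (bt == nrow(Cs$val)) Cs else ag_rows(Cs, seq_len(bt))
    Ua_act <- if (bt == B) Ua else ag_rows(Ua, act)
    A2_act <- if (bt == B) A2c else ag_rows(A2c, act)
    Vh <- ag_mm(H_act, p$V_att)
    Vh_exp <- ag_rows(Vh, rep(seq_len(bt), each = N))
    e <- ag_mm(ag_relu(ag_add(ag_add(Ua_act, Vh_exp), p$b_att)), p$w_att)
    alphaM <- ag_softmax_rows(ag_regroup(e, N))   # (bt, N)
    alpha <- ag_flatten_rows(alphaM)              # (bt*N, 1)
    key <- as.character(bt)
    if (is.null(sum_mats[[key]])) {
      Ms <- matrix(0, bt, bt * N)
      for (b in seq_len(bt)) Ms[b, ((b - 1) * N + 1):(b * N)] <- 1
      sum_mats[[key]] <- ag_const(Ms)
    }
    ctx <- ag_mm(sum_mats[[key]], ag_mul(A2_act, alpha))  # (bt, C)
    prev <- ids[seq_len(bt), t] + 1L
    Emb <- ag_rows(p$E, prev)
    X <- ag_cbind(list(Emb, H_act, ctx))
    G <- ag_add(ag_mm(X, p$W_lstm), p$b_lstm)
    gi <- ag_sigmoid(ag_cols(G, 1:n))
    gf <- ag_sigmoid(ag_cols(G, (n + 1):(2 * n)))
    go <- ag_sigmoid(ag_cols(G, (2 * n + 1):(3 * n)))
    gg <- ag_tanh(ag_cols(G, (3 * n + 1):(4 * n)))
    Cs <- ag_add(ag_mul(gf, C_act), ag_mul(gi, gg))
    H <- ag_mul(go, ag_tanh(Cs))
    Pin <- ag_add(ag_add(ag_mm(H, p$L_h), ag_mm(ctx, p$L_a)), Emb)
    Pin <- ag_dropout(Pin, cfg$dropout, training)
    logits <- ag_add(ag_mm(Pin, p$L_o), p$b_o)
    targets <- ids[seq_len(bt), t + 1L] + 1L
    losses[[length(losses) + 1L]] <- ag_ce_rows(logits, targets)
    total <- total + bt
  }
  list(loss_sum = ag_sum_nodes(losses), n_tokens = total)
}

#' Teacher-forcing cross-entropy loss for a sorted batch
#'
#' The ground-truth previous word is fed at every step; cross-entropy is
#' accumulated over non-pad positions only using the per-step effective
#' batch size, and the mean over predicted tokens is returned.
#'
#' @param model A `sat_model`.
#' @param features List of `(N, C)` feature matrices (or feature grids), one
#'   per caption.
#' @param ids Padded id matrix from [pad_and_sort()] (0-based ids).
#' @param lengths True lengths in decreasing order.
#' @return Scalar mean cross-entropy (nats per token).
#' @export
sat_tf_loss <- function(model, features, ids, lengths) {
  feat_nodes <- lapply(features, function(f)
    ag_const(sat_features(model, f)))
  ag_reset()
  g <- sat_batch_graph(model, feat_nodes, ids, lengths, training = FALSE)
  as.vector(g$loss_sum$val) / g$n_tokens
}

#' Teacher-forced next-token accuracy
#'
#' @inheritParams sat_tf_loss
#' @return Fraction of non-pad positions whose argmax prediction equals the
#'   ground-truth next token.
#' @export
sat_tf_accuracy <- function(model, features, ids, lengths) {
  hits <- 0L; total <- 0L
  for (b in seq_along(features)) {
    A <- sat_features(model, features[[b]])
    st <- sat_init_state(model, A)
    L <- lengths[b]
    for (t in seq_len(L - 1L)) {
      at <- sat_attend(model, A, st$h)
      st <- sat_lstm_step(model, ids[b, t], st$h, st$c, at$context)
      pr <- sat_output_distribution(model, st$h, at$context, ids[b, t])
      hits <- hits + (which.max(pr) - 1L == ids[b, t + 1L])
      total <- total + 1L
    }
  }
  hits / total
}

#' Teacher-forced attention weights for one caption
#'
#' @param model A `sat_model`.
#' @param features Feature grid or `(N, C)` matrix.
#' @param ids 0-based framed caption ids (vector).
#' @return `(length(ids) - 1) x N` matrix; row t holds alpha_t used while
#'   consuming token t (rows sum to 1).
#' @export
sat_tf_alphas <- function(model, features, ids) {
  A <- sat_features(model, features)
  st <- sat_init_state(model, A)
  L <- length(ids)
  out <- matrix(0, L - 1L, model$cfg$N)
  for (t in seq_len(L - 1L)) {
    at <- sat_attend(model, A, st$h)
    out[t, ] <- at$alpha
    st <- sat_lstm_step(model, ids[t], st$h, st$c, at$context)
  }
  out
}

# ---- training --------------------------------------------------------------

#' Train the attention captioner by teacher forcing
#'
#' @param model A `sat_model` (modified in place; also returned).
#' @param samples List of lists with `features` (grid or `(N, C)` matrix,
#'   or `image` when the model has an encoder) and `caption`
#'   (a `token_sequence`).
#' @param epochs Number of passes over the data.
#' @param batch_size Batch size (each batch is length-sorted internally).
#' @param lr Decoder learning rate (Adam).
#' @param encoder_lr Encoder learning rate; used when `finetune = TRUE`.
#' @param finetune Enable encoder gradient updates (see [set_finetune()]).
#' @param clip Optional global gradient-norm clip.
#' @param seed Seed controlling shuffling and dropout.
#' @param verbose Print per-epoch loss.
#' @return The model, with a `history` attribute (per-epoch mean loss).
#' @export
sat_train <- function(model, samples, epochs = 20L, batch_size = 16L,
                      lr = 1e-3, encoder_lr = lr, finetune = FALSE,
                      clip = NULL, seed = 1L, verbose = FALSE) {
  cfg <- model$cfg
  has_enc <- !is.null(model$encoder)
  if (finetune && !has_enc) stop("finetune requires an encoder")
  if (has_enc) set_finetune(model$encoder, finetune)
  # Precompute: frozen features, or the frozen stem when fine-tuning.
  prep <- lapply(samples, function(s) {
    if (!is.null(s$features)) {
      list(features = sat_features(model, s$features))
    } else if (finetune) {
      list(stem = encoder_stem(model$encoder, s$image))
    } else {
      list(features = encode_image(model$encoder, s$image)$features)
    }
  })
  caps <- lapply(samples, `[[`, "caption")
  dec_adam <- ag_adam_init(model$params)
  enc_params <- if (finetune) model$encoder$params else NULL
  enc_adam <- if (finetune) ag_adam_init(enc_params) else NULL
  nS <- length(samples)
  history <- numeric(epochs)
  with_local_seed(seed, function() {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nS)
      ep_loss <- 0; ep_tok <- 0L
      for (start in seq(1L, nS, by = batch_size)) {
        take <- ord[start:min(start + batch_size - 1L, nS)]
        pb <- pad_and_sort(caps[take])
        sel <- take[pb$perm]
        ag_reset()
        feat_nodes <- lapply(sel, function(i) {
          if (!is.null(prep[[i]]$features)) ag_const(prep[[i]]$features)
          else encoder_graph(model$encoder, prep[[i]]$stem)
        })
        g <- sat_batch_graph(model, feat_nodes, pb$ids, pb$lengths,
                             training = TRUE)
        loss <- ag_scale(g$loss_sum, 1 / g$n_tokens)
        ag_backward(loss)
        dec_adam <<- ag_adam_step(model$params, dec_adam, lr, clip = clip)
        if (finetune) {
          enc_adam <<- ag_adam_step(enc_params, enc_adam, encoder_lr,
                                    clip = clip)
        }
        ep_loss <- ep_loss + as.vector(g$loss_sum$val)
        ep_tok <- ep_tok + g$n_tokens
      }
      history[ep] <<- ep_loss / ep_tok
      if (verbose) {
        message(sprintf("sat epoch %d/%d  loss %.4f", ep, epochs,
                        history[ep]))
      }
    }
  })
  attr(model, "history") <- history
  model
}

# ---- decoding --------------------------------------------------------------

#' Generic length-synchronous K-beam search
#'
#' `step_fn(state, prev_id)` must return `list(logp = <vector of next-token
#' log-probabilities>, state = <new state>)`.  Hypotheses are retired when
#' they emit `end_id`; ties break toward the lower token id.
#'
#' @param step_fn Transition function.
#' @param init_state Initial decoder state.
#' @param k Beam width (>= 1).
#' @param max_len Maximum number of generated tokens.
#' @param start_id,end_id 0-based special token ids.
#' @return List of up to `k` hypotheses, each `list(ids, logp, states)`
#'   ordered by decreasing total log-probability.  `ids` excludes the
#'   leading start token.
#' @export
beam_search <- function(step_fn, init_state, k, max_len, start_id, end_id) {
  if (k < 1) stop("k must be >= 1")
  live <- list(list(ids = integer(0), logp = 0, state = init_state,
                    prev = start_id, trace = list()))
  done <- list()
  for (t in seq_len(max_len)) {
    if (length(live) == 0) break
    cand <- list()
    for (h in live) {
      sr <- step_fn(h$state, h$prev)
      lp <- sr$logp
      ord <- order(-lp, seq_along(lp))[seq_len(min(k, length(lp)))]
      for (w in ord) {
        cand[[length(cand) + 1L]] <-
          list(ids = c(h$ids, w - 1L), logp = h$logp + lp[w],
               state = sr$state, prev = w - 1L,
               trace = c(h$trace, list(sr$extra)))
      }
    }
    scores <- vapply(cand, `[[`, 0, "logp")
    lastid <- vapply(cand, `[[`, 0L, "prev")
    ord <- order(-scores, lastid)
    cand <- cand[ord[seq_len(min(k, length(cand)))]]
    live <- list()
    for (h in cand) {
      if (h$prev == end_id) done[[length(done) + 1L]] <- h
      else live[[length(live) + 1L]] <- h
    }
    if (length(done) >= k) break
  }
  all <- c(done, live)
  all <- all[order(-vapply(all, `[[`, 0, "logp"))]
  all[seq_len(min(k, length(all)))]
}

sat_step_fn <- function(model, A) {
  v <- sat_vals(model)
  cfg <- model$cfg
  function(state, prev_id) {
    at <- sat_attend(model, A, state$h)
    st <- sat_lstm_step(model, prev_id, state$h, state$c, at$context)
    emb <- v$E[prev_id + 1L, , drop = FALSE]
    logp <- sat_log_dist(v, cfg, st$h, at$context, emb)
    list(logp = logp, state = st, extra = at$alpha)
  }
}

#' Greedy caption decoding
#'
#' Emits the argmax word at each step (ties to the lowest id), stopping at
#' the end token or `max_len`; records the attention weights per step for
#' heatmap rendering.
#'
#' @param model A `sat_model`.
#' @param image Image matrix, feature grid, or `(N, C)` feature matrix.
#' @param max_len Maximum generated length.
#' @return List with `ids` (0-based, without start, including end if
#'   reached), `tokens` (if the model holds a vocabulary), `logp`, `alphas`
#'   (matrix, one row per emitted token).
#' @export
greedy_decode <- function(model, image, max_len = 50L) {
  A <- sat_features(model, image)
  fn <- sat_step_fn(model, A)
  st <- sat_init_state(model, A)
  ids <- integer(0); lp <- 0; alphas <- list()
  prev <- START_ID
  state <- st
  for (t in seq_len(max_len)) {
    sr <- fn(state, prev)
    w <- which.max(sr$logp) - 1L
    ids <- c(ids, w); lp <- lp + sr$logp[w + 1L]
    alphas[[t]] <- sr$extra
    state <- sr$state; prev <- w
    if (w == END_ID) break
  }
  out <- list(ids = ids, logp = lp,
              alphas = do.call(rbind, alphas))
  if (!is.null(model$vocab)) {
    out$tokens <- vocab_decode(ids, model$vocab)
  }
  out
}

#' K-beam caption decoding
#'
#' @inheritParams greedy_decode
#' @param k Beam width.
#' @return List of hypotheses as in [beam_search()], each augmented with
#'   `tokens` and `alphas` when available.
#' @export
beam_decode <- function(model, image, k = 3L, max_len = 50L) {
  A <- sat_features(model, image)
  fn <- sat_step_fn(model, A)
  st <- sat_init_state(model, A)
  hyps <- beam_search(fn, st, k, max_len, START_ID, END_ID)
  lapply(hyps, function(h) {
    h$alphas <- do.call(rbind, h$trace)
    if (!is.null(model$vocab)) h$tokens <- vocab_decode(h$ids, model$vocab)
    h
  })
}

# ---- heatmaps --------------------------------------------------------------

bilinear_axis_weights <- function(S, D) {
  Wm <- matrix(0, S, D)
  for (p in seq_len(S)) {
    x <- (p - 0.5) * D / S + 0.5
    i0 <- floor(x)
    fr <- x - i0
    i0c <- min(max(i0, 1L), D)
    i1c <- min(max(i0 + 1L, 1L), D)
    Wm[p, i0c] <- Wm[p, i0c] + (1 - fr)
    Wm[p, i1c] <- Wm[p, i1c] + fr
  }
  Wm
}

#' Render attention weights as image-sized heatmaps
#'
#' Each step's alpha vector is reshaped to the D x D location grid
#' (row-major) and bilinearly upsampled to the image size.  With
#' `rescale = TRUE` each map is rescaled to \[0,1\]; with `rescale = FALSE`
#' maps are normalized to preserve the total attention mass (each map sums
#' to ~1), which is the form used for mask-overlap measurements.
#'
#' @param alphas Matrix with one alpha vector (length D^2) per row, or a
#'   single vector.
#' @param D Side of the location grid.
#' @param image_size Output side in pixels.
#' @param rescale Rescale each map to \[0,1\].
#' @return List of `image_size x image_size` matrices, one per step.
#' @export
attention_heatmap <- function(alphas, D, image_size, rescale = TRUE) {
  if (is.vector(alphas)) alphas <- matrix(alphas, 1L)
  stopifnot(ncol(alphas) == D * D)
  Wax <- bilinear_axis_weights(image_size, D)
  scale <- (D / image_size)^2
  lapply(seq_len(nrow(alphas)), function(t) {
    A <- matrix(alphas[t, ], D, D, byrow = TRUE)
    up <- Wax %*% A %*% t(Wax) * scale
    if (rescale) {
      rng <- range(up)
      if (diff(rng) > 0) (up - rng[1]) / diff(rng) else up * 0
    } else up
  })
}

#' Attention mass inside a lesion mask
#'
#' @param alpha Length-N attention vector.
#' @param mask Logical image-sized matrix.
#' @param D Location grid side.
#' @return Fraction of the (mass-preserving, upsampled) attention inside
#'   the mask.
#' @export
attention_mass_in_mask <- function(alpha, mask, D) {
  mp <- attention_heatmap(alpha, D, nrow(mask), rescale = FALSE)[[1]]
  sum(mp * mask) / sum(mp)
}

#' Save heatmaps as CSV arrays and optional PNG overlays
#'
#' @param maps List of matrices from [attention_heatmap()].
#' @param dir Output directory (created if needed).
#' @param image Optional background image for PNG overlays.
#' @param prefix File name prefix.
#' @return Invisibly, the written file paths.
#' @export
save_heatmaps <- function(maps, dir, image = NULL, prefix = "step") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (t in seq_along(maps)) {
    fp <- file.path(dir, sprintf("%s_%03d.csv", prefix, t))
    utils::write.table(maps[[t]], fp, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, fp)
    if (!is.null(image)) {
      pp <- file.path(dir, sprintf("%s_%03d.png", prefix, t))
      grDevices::png(pp, width = ncol(image), height = nrow(image))
      op <- graphics::par(mar = c(0, 0, 0, 0))
      graphics::image(t(image[nrow(image):1, ]), col = grDevices::gray(0:255 / 255),
                      axes = FALSE, useRaster = TRUE)
      graphics::image(t(maps[[t]][nrow(maps[[t]]):1, ]),
                      col = grDevices::hcl.colors(64, "inferno", alpha = 0.35),
                      add = TRUE, useRaster = TRUE)
      graphics::par(op)
      grDevices::dev.off()
      paths <- c(paths, pp)
    }
  }
  invisible(paths)
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a captioner checkpoint
#'
#' The checkpoint holds decoder and encoder weights, the configuration and
#' a fingerprint of the vocabulary (verified at load time).
#'
#' @param model A `sat_model`.
#' @param path Checkpoint file (RDS).
#' @return `sat_load` returns the restored `sat_model`.
#' @export
sat_save <- function(model, path) {
  ck <- list(cfg = unclass(model$cfg),
             params = sat_vals(model),
             encoder = if (!is.null(model$encoder))
               encoder_export(model$encoder),
             vocab = if (!is.null(model$vocab)) model$vocab$id2word,
             vocab_hash = vocab_fingerprint(model$vocab))
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname sat_save
#' @export
sat_load <- function(path) {
  ck <- readRDS(path)
  cfg <- structure(ck$cfg, class = "sat_config")
  enc <- if (!is.null(ck$encoder)) encoder_import(ck$encoder)
  vocab <- if (!is.null(ck$vocab)) {
    structure(list(word2id = stats::setNames(seq_along(ck$vocab) - 1L,
                                             ck$vocab),
                   id2word = ck$vocab, size = length(ck$vocab)),
              class = "rc_vocab")
  }
  model <- sat_new(cfg, enc, vocab)
  for (k in names(ck$params)) model$params[[k]]$val <- ck$params[[k]]
  if (!identical(vocab_fingerprint(vocab), ck$vocab_hash)) {
    stop("vocabulary fingerprint mismatch in checkpoint")
  }
  model
}

vocab_fingerprint <- function(vocab) {
  if (is.null(vocab)) return(NA_real_)
  s <- paste(vocab$id2word, collapse = "")
  x <- utf8ToInt(s)
  sum(x * (seq_along(x) %% 97 + 1)) %% 2147483647
}
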