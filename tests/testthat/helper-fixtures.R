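# Shared fixtures: a small phantom batch with vocabulary and encoded
# captions, random caption corpora for metric checks, and the Python
# metric oracle bridge.

rc <- asNamespace("raycap")

# Memoized small phantom set (10 samples) reused across tests.
phantom_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- phantom_spec(seed = 3)
    samples <- lapply(0:9, function(i) generate_phantom(spec, i))
    toks <- lapply(samples, function(s) normalize_text(s$report))
    vocab <- build_vocab(toks)
    caps <- lapply(toks, encode_caption, vocab = vocab, max_len = 40)
    cache <<- list(spec = spec, samples = samples, toks = toks,
                   vocab = vocab, caps = caps)
    cache
  }
})

# A tiny untrained captioner over random features (for decode-path tests).
toy_sat <- function(W = 12L, m = 8L, n = 10L, C = 6L, N = 9L, seed = 42L) {
  cfg <- sat_config(W, embed_dim = m, hidden_dim = n, att_dim = n,
                    feat_dim = C, n_locations = N, dropout = 0,
                    seed = seed)
  sat_new(cfg)
}

random_features <- function(N = 9L, C = 6L, seed = 1L) {
  withr::with_seed(seed, matrix(rnorm(N * C), N, C))
}

# Random phantom-flavored caption corpus for metric comparisons.
random_caption_corpus <- function(n, seed = 1L) {
  vocab <- c("no", "acute", "cardiopulmonary", "abnormality", "the",
             "heart", "is", "enlarged", "left", "right", "lung", "shows",
             "an", "area", "of", "increased", "opacity", "patchy", "seen",
             "in", "a", "support", "line", "projects", "over", "chest",
             "device", "focal", "there")
  withr::with_seed(seed, {
    cands <- character(n)
    refs <- vector("list", n)
    for (i in seq_len(n)) {
      cands[i] <- paste(sample(vocab, sample(4:12, 1), replace = TRUE),
                        collapse = " ")
      refs[[i]] <- vapply(seq_len(sample(1:2, 1)), function(j)
        paste(sample(vocab, sample(4:12, 1), replace = TRUE),
              collapse = " "), "")
    }
    list(candidates = cands, references = refs)
  })
}

# Run the independent Python metric oracle on normalized texts.
python_metric_oracle <- function(candidates, references) {
  payload <- jsonlite::toJSON(
    list(candidates = vapply(candidates, function(x)
           paste(normalize_text(x), collapse = " "), ""),
         references = lapply(references, function(rs)
           vapply(rs, function(x) paste(normalize_text(x),
                                        collapse = " "), ""))),
    auto_unbox = FALSE)
  tf <- tempfile(fileext = ".json")
  writeLines(as.character(payload), tf)
  out <- system2("python", testthat::test_path("oracle_metrics.py"),
                 stdin = tf, stdout = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""))
}

# ---- independent brute-force oracles for the decoder equations ----------
# Scalar-loop implementations, kept deliberately naive and separate from
# the package's vectorized forward path.

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

# gates [i, f, o, g] from one affine map of [emb; h_prev; ctx], then
# c = f*c_prev + i*g, h = o*tanh(c)
oracle_lstm_step <- function(W, b, emb, h_prev, c_prev, ctx) {
  x <- c(emb, h_prev, ctx)
  n <- length(h_prev)
  z <- numeric(4 * n)
  for (j in seq_len(4 * n)) {
    acc <- b[j]
    for (k in seq_along(x)) acc <- acc + x[k] * W[k, j]
    z[j] <- acc
  }
  i <- oracle_sigmoid(z[1:n])
  f <- oracle_sigmoid(z[(n + 1):(2 * n)])
  o <- oracle_sigmoid(z[(2 * n + 1):(3 * n)])
  g <- tanh(z[(3 * n + 1):(4 * n)])
  cc <- f * c_prev + i * g
  list(h = o * tanh(cc), c = cc)
}

# e_i = w'relu(U a_i + V h + b); alpha = softmax(e); ctx = sum alpha_i a_i
oracle_attend <- function(U, V, bb, w, A, h) {
  N <- nrow(A)
  e <- numeric(N)
  for (i in seq_len(N)) {
    pre <- numeric(ncol(U))
    for (j in seq_len(ncol(U))) {
      acc <- bb[j]
      for (k in seq_len(ncol(A))) acc <- acc + A[i, k] * U[k, j]
      for (k in seq_along(h)) acc <- acc + h[k] * V[k, j]
      pre[j] <- max(acc, 0)
    }
    e[i] <- sum(pre * w)
  }
  al <- exp(e - max(e)); al <- al / sum(al)
  ctx <- numeric(ncol(A))
  for (k in seq_len(ncol(A))) ctx[k] <- sum(al * A[, k])
  list(alpha = al, context = ctx)
}

# softmax(L_o(L_h h + L_a ctx + emb) + b_o)
oracle_output <- function(L_h, L_a, L_o, b_o, h, ctx, emb) {
  m <- ncol(L_h)
  inner <- numeric(m)
  for (j in seq_len(m)) {
    acc <- emb[j]
    for (k in seq_along(h)) acc <- acc + h[k] * L_h[k, j]
    for (k in seq_along(ctx)) acc <- acc + ctx[k] * L_a[k, j]
    inner[j] <- acc
  }
  W <- ncol(L_o)
  logits <- numeric(W)
  for (j in seq_len(W)) {
    acc <- b_o[j]
    for (k in seq_len(m)) acc <- acc + inner[k] * L_o[k, j]
    logits[j] <- acc
  }
  p <- exp(logits - max(logits))
  p / sum(p)
}
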