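test_that("state initialization is the MLP of the mean location vector", {
  model <- toy_sat()
  # identical location vectors: MLP input is exactly that vector
  v <- matrix(rep(seq_len(6) / 6, each = 9), 9, 6)
  st <- sat_init_state(model, v)
  p <- lapply(model$params, function(x) x$val)
  expect_equal(st$h, tanh(v[1, , drop = FALSE] %*% p$W_ih + p$b_ih))
  # permutation invariance
  A <- random_features(seed = 11)
  st1 <- sat_init_state(model, A)
  st2 <- sat_init_state(model, A[sample(9), ])
  expect_equal(st1$h, st2$h, tolerance = 1e-12)
  expect_equal(st1$c, st2$c, tolerance = 1e-12)
  # zero features with zero biases -> tanh(0) = 0
  model$params$b_ih$val[] <- 0
  st0 <- sat_init_state(model, matrix(0, 9, 6))
  expect_equal(st0$h, matrix(0, 1, 10))
})

test_that("attention weights form a convex combination of location features", {
  model <- toy_sat()
  A <- random_features(seed = 12)
  h <- matrix(rnorm(10), 1)
  at <- sat_attend(model, A, h)
  expect_equal(sum(at$alpha), 1, tolerance = 1e-12)
  expect_true(all(at$alpha >= 0))
  for (k in seq_len(ncol(A))) {
    expect_gte(at$context[k], min(A[, k]) - 1e-12)
    expect_lte(at$context[k], max(A[, k]) + 1e-12)
  }
  # identical rows force uniform attention and the mean as context
  Aeq <- matrix(rep(rnorm(6), each = 9), 9, 6)
  ae <- sat_attend(model, Aeq, h)
  expect_equal(ae$alpha, rep(1 / 9, 9), tolerance = 1e-12)
  expect_equal(as.vector(ae$context), colMeans(Aeq), tolerance = 1e-12)
  # a large score gap makes attention one-hot and context = that location
  model2 <- toy_sat(seed = 5)
  model2$params$U_att$val[] <- 0
  model2$params$V_att$val[] <- 0
  model2$params$b_att$val[] <- 1
  model2$params$w_att$val[] <- 0
  model2$params$U_att$val[1, 1] <- 40
  model2$params$w_att$val[1, 1] <- 1
  A2 <- random_features(seed = 13) * 0.01
  A2[4, 1] <- 1   # location 4 gets score ~40, others ~0
  a2 <- sat_attend(model2, A2, h * 0)
  expect_gt(a2$alpha[4], 0.999)
  expect_equal(as.vector(a2$context), A2[4, ], tolerance = 1e-4)
})

test_that("the LSTM step follows the gate equations (zero-weight closed form and random oracle)", {
  model <- toy_sat()
  for (p in c("W_lstm", "b_lstm")) model$params[[p]]$val[] <- 0
  c_prev <- matrix(rnorm(10), 1)
  st <- sat_lstm_step(model, 3L, matrix(0, 1, 10), c_prev,
                      matrix(0, 1, 6))
  expect_equal(st$c, 0.5 * c_prev, tolerance = 1e-12)
  expect_equal(st$h, 0.5 * tanh(0.5 * c_prev), tolerance = 1e-12)
  st0 <- sat_lstm_step(model, 3L, matrix(1, 1, 10), matrix(0, 1, 10),
                       matrix(1, 1, 6))
  expect_equal(st0$c, matrix(0, 1, 10))  # g = tanh(0) = 0, c_prev = 0
  expect_equal(st0$h, matrix(0, 1, 10))
  # random 4-dim oracle
  m4 <- toy_sat(W = 5L, m = 4L, n = 4L, C = 4L, N = 4L, seed = 9)
  pv <- lapply(m4$params, function(x) x$val)
  emb <- pv$E[2, ]
  h <- rnorm(4); cc <- rnorm(4); ctx <- rnorm(4)
  got <- sat_lstm_step(m4, 1L, matrix(h, 1), matrix(cc, 1),
                       matrix(ctx, 1))
  want <- oracle_lstm_step(pv$W_lstm, as.vector(pv$b_lstm), emb, h, cc,
                           ctx)
  expect_equal(as.vector(got$h), want$h, tolerance = 1e-6)
  expect_equal(as.vector(got$c), want$c, tolerance = 1e-6)
})

test_that("the deep output layer produces a distribution matching direct matrix arithmetic", {
  model <- toy_sat(W = 3L, m = 4L, n = 5L, C = 4L, N = 4L, seed = 77)
  pv <- lapply(model$params, function(x) x$val)
  h <- matrix(rnorm(5), 1); ctx <- matrix(rnorm(4), 1)
  pr <- sat_output_distribution(model, h, ctx, 2L)
  expect_equal(sum(pr), 1, tolerance = 1e-6)
  expect_true(all(pr >= 0))
  want <- oracle_output(pv$L_h, pv$L_a, pv$L_o, as.vector(pv$b_o),
                        as.vector(h), as.vector(ctx), pv$E[3, ])
  expect_equal(pr, want, tolerance = 1e-6)
  # all-zero inputs with zero parameters -> uniform
  for (p in c("L_h", "L_a", "L_o", "b_o", "E")) model$params[[p]]$val[] <- 0
  expect_equal(sat_output_distribution(model, h * 0, ctx * 0, 0L),
               rep(1 / 3, 3))
})

test_that("teacher-forcing loss ignores pads and equals ln W for uniform predictions", {
  model <- toy_sat(W = 12L)
  for (nm in names(model$params)) model$params[[nm]]$val[] <- 0
  feats <- list(random_features(seed = 1), random_features(seed = 2))
  ids <- rbind(c(0L, 5L, 6L, 1L, 2L), c(0L, 7L, 1L, 2L, 2L))
  loss <- sat_tf_loss(model, feats, ids, c(4L, 3L))
  expect_equal(loss, log(12), tolerance = 1e-9)
  # appending pads changes nothing
  ids_pad <- cbind(ids, matrix(2L, 2, 5))
  model2 <- toy_sat(W = 12L, seed = 31)
  l1 <- sat_tf_loss(model2, feats, ids, c(4L, 3L))
  l2 <- sat_tf_loss(model2, feats, ids_pad, c(4L, 3L))
  expect_equal(l1, l2, tolerance = 1e-12)
  expect_error(sat_tf_loss(model2, feats, ids, c(3L, 4L)), "sorted")
})

test_that("training reduces the teacher-forcing loss on a few phantoms", {
  fx <- phantom_fixture()
  enc <- encoder_new(seed = 8)
  imgs <- lapply(fx$samples[1:6], `[[`, "image")
  encoder_set_reference(enc, Reduce(`+`, imgs) / 6)
  cfg <- sat_config_for(enc, fx$vocab$size, embed_dim = 16, hidden_dim = 24,
                        dropout = 0, seed = 8)
  model <- sat_new(cfg, enc, fx$vocab)
  tr <- lapply(1:6, function(i) list(image = imgs[[i]],
                                     caption = fx$caps[[i]]))
  model <- sat_train(model, tr, epochs = 8, batch_size = 3, lr = 3e-3,
                     finetune = FALSE, seed = 1)
  h <- attr(model, "history")
  expect_lt(h[length(h)], h[1])
})

test_that("greedy decoding is deterministic, starts from the start token and matches beam k=1", {
  model <- toy_sat(seed = 100)
  A <- random_features(seed = 3)
  g1 <- greedy_decode(model, A, max_len = 12)
  g2 <- greedy_decode(model, A, max_len = 12)
  expect_identical(g1$ids, g2$ids)
  expect_equal(rowSums(g1$alphas), rep(1, nrow(g1$alphas)),
               tolerance = 1e-9)
  b1 <- beam_decode(model, A, k = 1, max_len = 12)[[1]]
  expect_identical(b1$ids, g1$ids)
  expect_equal(b1$logp, g1$logp, tolerance = 1e-9)
})

test_that("beam search returns the exact top-k of exhaustive enumeration on a toy model", {
  # 3-word toy language: transition table over ids 0..2 (2 = end),
  # 3 steps maximum; step_fn ignores state beyond the previous token
  logp_table <- log(rbind(c(0.2, 0.3, 0.5),    # after start/0
                          c(0.1, 0.4, 0.5),    # after 1
                          c(1, 1, 1) / 3))     # after end (unused)
  step_fn <- function(state, prev) {
    row <- if (prev <= 1) prev + 1 else 3
    list(logp = logp_table[row, ], state = NULL, extra = NULL)
  }
  hyps <- beam_search(step_fn, NULL, k = 2, max_len = 3,
                      start_id = 0L, end_id = 2L)
  # exhaustive enumeration of all sequences up to length 3
  enum <- list()
  for (w1 in 0:2) {
    s1 <- logp_table[1, w1 + 1]
    if (w1 == 2) { enum[[length(enum) + 1]] <- list(ids = 2L, lp = s1); next }
    for (w2 in 0:2) {
      s2 <- s1 + logp_table[w1 + 1, w2 + 1]
      if (w2 == 2) { enum[[length(enum) + 1]] <- list(ids = c(w1, 2L), lp = s2); next }
      for (w3 in 0:2) {
        s3 <- s2 + logp_table[w2 + 1, w3 + 1]
        enum[[length(enum) + 1]] <- list(ids = c(w1, w2, w3), lp = s3)
      }
    }
  }
  lps <- vapply(enum, `[[`, 0, "lp")
  ord <- order(-lps)
  expect_equal(hyps[[1]]$logp, lps[ord[1]], tolerance = 1e-12)
  expect_identical(hyps[[1]]$ids, as.integer(enum[[ord[1]]]$ids))
  expect_equal(hyps[[2]]$logp, lps[ord[2]], tolerance = 1e-12)
  expect_identical(hyps[[2]]$ids, as.integer(enum[[ord[2]]]$ids))
  expect_error(beam_search(step_fn, NULL, k = 0, max_len = 3,
                           start_id = 0L, end_id = 2L), "k must be")
})

test_that("beam top-1 score is never below the greedy score", {
  for (seed in c(4, 9, 23)) {
    model <- toy_sat(seed = seed)
    A <- random_features(seed = seed)
    g <- greedy_decode(model, A, max_len = 10)
    b <- beam_decode(model, A, k = 3, max_len = 10)[[1]]
    expect_gte(b$logp, g$logp - 1e-9)
  }
})

test_that("attention heatmaps upsample with mass preservation and convention", {
  # uniform alpha -> constant map
  maps <- attention_heatmap(rep(1 / 49, 49), D = 7, image_size = 224,
                            rescale = FALSE)
  expect_lt(diff(range(maps[[1]])), 1e-12)
  expect_equal(sum(maps[[1]]), 1, tolerance = 1e-9)
  # one-hot alpha at grid (r=2, c=5) (0-based): maximum inside that block
  al <- rep(0, 49); al[2 * 7 + 5 + 1] <- 1
  m <- attention_heatmap(al, 7, 224, rescale = TRUE)[[1]]
  mx <- which(m == max(m), arr.ind = TRUE)
  expect_true(all(mx[, 1] >= 2 * 32 + 1 & mx[, 1] <= 3 * 32))
  expect_true(all(mx[, 2] >= 5 * 32 + 1 & mx[, 2] <= 6 * 32))
  expect_gte(min(m), 0); expect_lte(max(m), 1)
  # random alphas keep total mass ~1 before rescaling
  withr::with_seed(5, {
    for (i in 1:5) {
      a <- runif(49); a <- a / sum(a)
      mp <- attention_heatmap(a, 7, 224, rescale = FALSE)[[1]]
      expect_equal(sum(mp), 1, tolerance = 1e-3)
    }
  })
})

test_that("checkpoints round-trip weights, config, vocabulary and reference", {
  fx <- phantom_fixture()
  enc <- encoder_new(seed = 4)
  encoder_set_reference(enc, fx$samples[[1]]$image * 0 + 0.3)
  cfg <- sat_config_for(enc, fx$vocab$size, embed_dim = 8, hidden_dim = 12,
                        dropout = 0, seed = 4)
  model <- sat_new(cfg, enc, fx$vocab)
  f <- tempfile(fileext = ".rds")
  sat_save(model, f)
  m2 <- sat_load(f)
  A <- fx$samples[[1]]$image
  expect_identical(greedy_decode(m2, A, 15)$ids,
                   greedy_decode(model, A, 15)$ids)
  expect_identical(m2$vocab$id2word, fx$vocab$id2word)
})
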