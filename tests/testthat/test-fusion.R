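# A small trained world shared by the fusion tests: 6 phantoms, a tiny
# captioner and a tiny transformer over the same text.
fusion_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    fx <- phantom_fixture()
    enc <- encoder_new(seed = 41)
    imgs <- lapply(fx$samples[1:6], `[[`, "image")
    encoder_set_reference(enc, Reduce(`+`, imgs) / 6)
    cfg <- sat_config_for(enc, fx$vocab$size, embed_dim = 16,
                          hidden_dim = 24, dropout = 0, seed = 41)
    sat <- sat_new(cfg, enc, fx$vocab)
    tr <- lapply(1:6, function(i) list(image = imgs[[i]],
                                       caption = fx$caps[[i]]))
    sat <- sat_train(sat, tr, epochs = 10, batch_size = 3, lr = 3e-3,
                     finetune = FALSE, seed = 1)
    texts <- vapply(fx$toks[1:6], paste, "", collapse = " ")
    bpe <- train_bpe(texts, 80)
    lm <- lm_new(lm_config(bpe$size, layers = 2, heads = 2, dim = 32,
                           ffn_dim = 64, block = 128, seed = 7), bpe)
    lm <- lm_finetune(lm, texts, epochs = 15, lr = 3e-3, batch_size = 3,
                      seed = 7)
    cache <<- list(fx = fx, sat = sat, lm = lm, imgs = imgs, tr = tr,
                   texts = texts)
    cache
  }
})

test_that("vocabulary alignment follows the stepwise chain rule of the transformer", {
  w <- fusion_world()
  vocab <- rc$vocab_with_segs(w$sat$vocab, w$lm$bpe)
  ctx <- w$lm$bpe$start_id
  scores <- align_vocabulary(w$lm, ctx, vocab, w$lm$bpe)
  first_lp <- rc$lm_next_logp(w$lm, ctx)
  segs <- attr(vocab, "bpe_segs")
  one_tok <- which(vapply(segs, function(s) length(s) == 1L, TRUE))
  for (i in utils::head(one_tok, 5)) {
    expect_equal(scores[i], first_lp[segs[[i]][1] + 1L], tolerance = 1e-12)
  }
  multi <- which(vapply(segs, function(s) length(s) > 1L, TRUE))
  if (length(multi) > 0) {
    i <- multi[1]
    ids <- segs[[i]]
    want <- first_lp[ids[1] + 1L]
    cc <- c(ctx, ids[1])
    for (j in 2:length(ids)) {
      want <- want + rc$lm_next_logp(w$lm, cc)[ids[j] + 1L]
      cc <- c(cc, ids[j])
    }
    expect_equal(scores[i], want, tolerance = 1e-10)
  }
  # special tokens (other than <end>) get the floor
  expect_lt(scores[3], -1e8)  # <pad>
  expect_equal(scores[2], first_lp[w$lm$bpe$eot_id + 1L])  # <end> -> eot
})

test_that("a uniform transformer distribution gives equal scores to single-token words", {
  w <- fusion_world()
  lm0 <- lm_new(lm_config(w$lm$bpe$size, layers = 1, heads = 1, dim = 16,
                          ffn_dim = 16, block = 64, seed = 1), w$lm$bpe)
  # zero the head: logits constant -> uniform next-token distribution
  lm0$params$head$val[] <- 0
  lm0$params$head_b$val[] <- 0
  vocab <- rc$vocab_with_segs(w$sat$vocab, w$lm$bpe)
  sc <- align_vocabulary(lm0, lm0$bpe$start_id, vocab, lm0$bpe)
  segs <- attr(vocab, "bpe_segs")
  one_tok <- which(vapply(segs, function(s) length(s) == 1L, TRUE))
  expect_lt(diff(range(sc[one_tok])), 1e-12)
})

test_that("the fusion head outputs a distribution and an identity-like head reproduces the captioner", {
  W <- 10L
  head <- fusion_head_new(W, seed = 2)
  sat_sc <- log(runif(W)); lm_sc <- log(runif(W))
  pr <- fuse_next_word(sat_sc, lm_sc, head)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  expect_true(all(pr >= 0))
  expect_error(fuse_next_word(sat_sc, lm_sc[1:5], head), "identical length")
  # pass-through construction: hidden = sat + B (ReLU inactive floor),
  # output = hidden - B  => logits equal sat scores
  B <- 100
  head$params$W1$val[] <- 0
  head$params$W1$val[cbind(1:W, 1:W)] <- 1
  head$params$b1$val[] <- B
  head$params$W2$val[] <- 0
  head$params$W2$val[cbind(1:W, 1:W)] <- 1
  head$params$b2$val[] <- -B
  pr2 <- fuse_next_word(sat_sc, lm_sc, head)
  want <- exp(sat_sc) / sum(exp(sat_sc))
  expect_equal(pr2, want, tolerance = 1e-6)
  # permutation equivariance of that construction
  perm <- sample(W)
  pr3 <- fuse_next_word(sat_sc[perm], lm_sc[perm], head)
  expect_equal(pr3, pr2[perm], tolerance = 1e-9)
})

test_that("approach 1 with a captioner-only head reproduces greedy decoding and stays in vocabulary", {
  w <- fusion_world()
  W <- w$sat$vocab$size
  head <- fusion_head_new(W, seed = 3)
  head$params$W1$val[] <- 0
  head$params$W1$val[cbind(1:W, 1:W)] <- 1   # zero weights on the lm half
  head$params$b1$val[] <- 100
  head$params$W2$val[] <- 0
  head$params$W2$val[cbind(1:W, 1:W)] <- 1
  head$params$b2$val[] <- -100
  img <- w$imgs[[2]]
  out <- generate_approach1(img, w$sat, w$lm, head, max_len = 25)
  g <- greedy_decode(w$sat, img, max_len = 25)
  expect_identical(out$ids, g$ids)
  expect_true(all(out$ids >= 0 & out$ids < W))
  out2 <- generate_approach1(img, w$sat, w$lm, head, max_len = 25)
  expect_identical(out2$ids, out$ids)
})

test_that("approach 2 output begins with the captioner's text verbatim", {
  w <- fusion_world()
  for (i in c(1, 3)) {
    res <- generate_approach2(w$imgs[[i]], w$sat, w$lm, sat_k = 1,
                              lm_k = 2)
    expect_identical(substr(res$report, 1, nchar(res$sat_seed)),
                     res$sat_seed)
    expect_identical(res$report,
                     trimws(paste(res$sat_seed, res$lm_continuation)))
  }
})

test_that("training the fusion head decreases its loss with frozen backbones", {
  w <- fusion_world()
  head <- fusion_head_new(w$sat$vocab$size, seed = 5)
  samples <- lapply(1:4, function(i)
    list(features = encode_image(w$sat$encoder, w$imgs[[i]])$features,
         caption = w$fx$caps[[i]]))
  head <- train_fusion_head(head, w$sat, w$lm, samples, epochs = 8,
                            lr = 1e-2, seed = 5)
  h <- attr(head, "history")
  expect_lt(h[length(h)], h[1])
})
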