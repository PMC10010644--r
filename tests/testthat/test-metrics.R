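test_that("BLEU is 1 for identical pairs and clips repeated n-grams", {
  b <- bleu("the heart is enlarged", list("the heart is enlarged"))
  expect_equal(unname(b), rep(1, 4))
  # candidate longer than the reference: no brevity penalty, so BLEU-1 is
  # exactly the clipped unigram precision 1/4
  b2 <- bleu("the the the the", list("the cat"))
  expect_equal(unname(b2[1]), 0.25)
  expect_error(bleu(character(0), list()), "empty")
})

test_that("BLEU-n uses n-grams up to order n (corpus level)", {
  cands <- c("a b c d", "e f g h")
  refs <- list(c("a b c d"), c("e f x h"))
  b <- bleu(cands, refs)
  # order 1: 7/8 match; order 2: 4/6; order 3: 2/4; order 4: 1/2
  expect_equal(unname(b[1]), 7 / 8)
  expect_equal(unname(b[2]), sqrt(7 / 8 * 4 / 6))
  expect_equal(unname(b[4]), (7 / 8 * 4 / 6 * 2 / 4 * 1 / 2)^(1 / 4))
})

test_that("ROUGE-L follows the beta-weighted LCS F formula", {
  expect_equal(rouge_l("x y z", list("x y z")), 1)
  expect_equal(rouge_l("a b", list("c d")), 0)
  beta <- 1.2
  p <- 2 / 3; r <- 1
  want <- (1 + beta^2) * p * r / (r + beta^2 * p)
  expect_equal(rouge_l("a b c", list("a c")), want, tolerance = 1e-6)
  # max over references
  expect_equal(rouge_l("a b c", list(c("z z z", "a b c"))), 1)
})

test_that("CIDEr scores identity at 10 and disjoint candidates at 0", {
  cands <- c("the heart is enlarged today",
             "patchy opacity in the left lung",
             "no acute cardiopulmonary abnormality seen",
             "a support device line overlies the chest")
  refs <- lapply(cands, function(x) x)
  expect_equal(cider(cands, refs), 10, tolerance = 1e-6)
  # a candidate sharing no n-gram with its references scores 0, so the
  # corpus mean drops from 10 to 3*10/4
  cands2 <- cands
  cands2[2] <- "completely unrelated words here now"
  expect_equal(cider(cands2, refs), 7.5, tolerance = 1e-6)
  expect_warning(cider("a b", list("a b")), "single-sample")
})

test_that("geometric-mean BLEU is the fourth root of the product", {
  expect_equal(gm_bleu(c(1, 1, 1, 1)), 1)
  expect_equal(gm_bleu(c(0.5, 0.5, 0.5, 0.5)), 0.5)
  expect_equal(gm_bleu(c(0.9, 0.4, 0, 0.2)), 0)
  expect_equal(gm_bleu(c(0.8, 0.6, 0.4, 0.2)),
               (0.8 * 0.6 * 0.4 * 0.2)^0.25)
})

test_that("clinical-efficacy metrics pool micro counts with the stated conventions", {
  labs <- c("edema", "effusion")
  # 2 samples x 2 labels pooling to TP=1, FP=1, FN=1, TN=1:
  # s1: gen {edema}, ref {edema}   -> edema TP, effusion TN
  # s2: gen {effusion}, ref {edema} -> edema FN, effusion FP
  ce <- ce_metrics(c("edema", "effusion x"), c("edema", "edema y"), labs)
  expect_equal(unname(ce), c(0.5, 0.5, 0.5, 0.5))
  gen <- c("edema is present", "no findings")
  all_good <- ce_metrics(gen, gen, labs)
  expect_equal(unname(all_good), c(1, 1, 1, 1))
  # generated and references mention no labels at all
  none <- ce_metrics("clear lungs", "normal study", labs)
  expect_equal(unname(none), c(1, 0, 0, 0))
  expect_error(ce_metrics("a", "b", character(0)), "empty label")
})

test_that("metrics are invariant to sample order", {
  cc <- random_caption_corpus(12, seed = 31)
  perm <- sample(12)
  expect_equal(bleu(cc$candidates, cc$references),
               bleu(cc$candidates[perm], cc$references[perm]))
  expect_equal(rouge_l(cc$candidates, cc$references),
               rouge_l(cc$candidates[perm], cc$references[perm]))
  expect_equal(cider(cc$candidates, cc$references),
               cider(cc$candidates[perm], cc$references[perm]),
               tolerance = 1e-12)
})

test_that("corrupting a matched token never increases BLEU-1", {
  withr::with_seed(8, {
    for (rep in 1:10) {
      ref <- paste(sample(letters[1:6], 6, replace = TRUE), collapse = " ")
      cand <- ref
      toks <- strsplit(cand, " ")[[1]]
      toks[sample(6, 1)] <- "zzz"
      worse <- paste(toks, collapse = " ")
      expect_lte(bleu(worse, list(ref))[1], bleu(cand, list(ref))[1])
    }
  })
})

test_that("metric_report assembles a one-row tibble with CE columns", {
  cc <- random_caption_corpus(6, seed = 5)
  mr <- metric_report(cc$candidates, cc$references,
                      labels = c("opacity_left", "none"),
                      reference_texts = vapply(cc$references, `[`, "", 1))
  expect_s3_class(mr, "tbl_df")
  expect_equal(nrow(mr), 1)
  expect_true(all(c("bleu1", "rouge_l", "cider", "gm_bleu",
                    "ce_accuracy") %in% names(mr)))
  expect_equal(mr$gm_bleu,
               gm_bleu(unlist(mr[1, c("bleu1", "bleu2", "bleu3", "bleu4")])))
})
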