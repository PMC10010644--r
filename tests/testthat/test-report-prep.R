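test_that("report assembly concatenates sections and excludes empty reports", {
  expect_identical(assemble_report("No acute disease.", ""),
                   "No acute disease.")
  expect_identical(assemble_report("A.", "B."), "A. B.")
  expect_true(is_excluded(assemble_report("", "")))
  expect_true(is_excluded(assemble_report("   ", "\t")))
  expect_false(is_excluded(assemble_report("x", "")))
})

test_that("normalization lowercases, strips non-alphanumerics and is idempotent", {
  expect_identical(normalize_text("No Pneumothorax."),
                   c("no", "pneumothorax"))
  expect_identical(normalize_text("X-ray #2"), c("xray", "2"))
  expect_identical(normalize_text(""), character(0))
  expect_identical(normalize_text("..."), character(0))
  for (txt in c("Heart is ENLARGED!!", "a-b c_d 4x4", "  spaced   out ")) {
    once <- normalize_text(txt)
    expect_identical(normalize_text(paste(once, collapse = " ")), once)
  }
})

test_that("abbreviation expansion is single-pass and cyclic dictionaries are rejected", {
  map <- list(sob = c("shortness", "of", "breath"),
              ap = "anteroposterior")
  expect_identical(expand_abbreviations("sob", map),
                   c("shortness", "of", "breath"))
  expect_identical(expand_abbreviations(c("ap", "view"), map),
                   c("anteroposterior", "view"))
  expect_identical(expand_abbreviations(c("a", "b"), list()), c("a", "b"))
  # produced tokens are not re-expanded
  map2 <- list(a = c("b", "x"), b = "y")
  expect_identical(expand_abbreviations("a", map2), c("b", "x"))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("sob\tshortness of breath", "ap\tanteroposterior"), tsv)
  loaded <- load_abbreviations(tsv)
  expect_identical(loaded$sob, c("shortness", "of", "breath"))
  writeLines(c("a\tb c", "b\ta"), tsv)
  expect_error(load_abbreviations(tsv), "cyclic")
})

test_that("the shipped abbreviation dictionary loads and expands", {
  path <- system.file("extdata", "abbreviations.tsv", package = "raycap")
  expect_true(nzchar(path))
  map <- load_abbreviations(path)
  expect_gte(length(map), 15)
  expect_identical(expand_abbreviations("sob", map),
                   c("shortness", "of", "breath"))
})

test_that("label prefixing places labels before the report with a period delimiter", {
  expect_identical(prepend_labels("cardiomegaly", "heart is enlarged"),
                   "cardiomegaly . heart is enlarged")
  expect_identical(prepend_labels(character(0), "r"), "r")
  two <- prepend_labels(c("edema", "effusion"), "lungs are wet")
  toks <- normalize_text(two)
  expect_identical(toks[1:2], c("edema", "effusion"))
  expect_true(match("lungs", toks) > match("effusion", toks))
})

test_that("vocabulary construction orders by frequency then lexicographically with stable specials", {
  v <- build_vocab(c(rep("a", 3), "b"), min_freq = 2)
  expect_identical(v$id2word[1:4],
                   c("<start>", "<end>", "<pad>", "<unk>"))
  expect_true("a" %in% v$id2word)
  expect_false("b" %in% v$id2word)
  expect_identical(vocab_encode("b", v), 3L)     # unk id
  v1 <- build_vocab(c("z", "z", "m", "m", "k"), min_freq = 1)
  expect_identical(v1$id2word[5:7], c("m", "z", "k"))
  expect_identical(build_vocab(c("x", "y", "x")),
                   build_vocab(c("x", "y", "x")))
  expect_error(build_vocab(character(0)), "empty")
  # JSON round trip preserves ids
  f <- tempfile(fileext = ".json")
  vocab_save(v1, f)
  expect_identical(vocab_load(f)$word2id, v1$word2id)
})

test_that("encode/decode round-trips in-vocabulary token lists", {
  fx <- phantom_fixture()
  for (tk in fx$toks[1:5]) {
    seqq <- encode_caption(tk, fx$vocab, max_len = 60)
    expect_identical(seqq$ids[1], 0L)
    expect_identical(seqq$ids[length(seqq$ids)], 1L)
    expect_identical(vocab_decode(seqq$ids, fx$vocab), tk)
  }
  long <- encode_caption(rep("no", 50), fx$vocab, max_len = 10)
  expect_identical(long$length, 10L)
  expect_error(encode_caption("x", fx$vocab, max_len = 1), "max_len")
})

test_that("pad_and_sort orders by decreasing length with stable ties and pads with the pad id", {
  mk <- function(n) structure(list(ids = c(0L, rep(5L, n - 2L), 1L),
                                   length = n), class = "token_sequence")
  pb <- pad_and_sort(list(mk(3), mk(5), mk(2)))
  expect_identical(pb$lengths, c(5L, 3L, 2L))
  expect_identical(pb$perm, c(2L, 1L, 3L))   # 0-based [1, 0, 2]
  expect_identical(pb$ids[3, 3:5], rep(2L, 3))
  same <- pad_and_sort(list(mk(4), mk(4), mk(4)))
  expect_identical(same$perm, 1:3)           # stable for ties
})

test_that("effective batch sizes count active sequences at each step", {
  expect_identical(effective_batch_sizes(c(5, 3, 2)), c(3L, 3L, 2L, 1L, 1L))
  expect_identical(effective_batch_sizes(c(2, 2)), c(2L, 2L))
})
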