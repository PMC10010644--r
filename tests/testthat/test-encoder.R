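test_that("default encoder yields a (49, 64) feature grid with row-major locations", {
  enc <- encoder_new(seed = 1)
  img <- matrix(runif(224 * 224), 224, 224)
  grid <- encode_image(enc, img)
  expect_s3_class(grid, "feature_grid")
  expect_equal(dim(grid$features), c(49, 64))
  expect_equal(grid$D, 7)
  expect_true(all(is.finite(grid$features)))
  # shape errors name the expected shape
  expect_error(encode_image(enc, matrix(0, 100, 100)), "\\(1, 224, 224\\)")
  expect_error(encode_image(enc, img + 5), "\\[0, 1\\]")
  # (1, S, S) array form accepted
  arr <- array(img, dim = c(1, 224, 224))
  arr[1, , ] <- img
  expect_equal(encode_image(enc, arr)$features, grid$features)
})

test_that("adaptive pooling of a constant feature field yields identical location vectors", {
  # translation invariance holds for the pooling contract; the desk CNN
  # additionally carries an explicit positional code in its last block
  const_fn <- function(img) array(0.7, dim = c(14, 14, 8))
  enc <- encoder_new("vgg16", feature_fn = const_fn)
  grid <- encode_image(enc, matrix(0.5, 224, 224))
  expect_lt(max(apply(grid$features, 2, function(col) diff(range(col)))),
            1e-10)
  # the desk CNN's constant-image features depend on position only:
  # feeding two different constant images shifts features uniformly
  enc2 <- encoder_new(seed = 2)
  g1 <- encode_image(enc2, matrix(0.5, 224, 224))$features
  g2 <- encode_image(enc2, matrix(0.5, 224, 224))$features
  expect_identical(g1, g2)
})

test_that("named large backbones expose their documented channel counts", {
  expect_equal(backbone_channels("densenet121"), 1024)
  expect_equal(backbone_channels("vgg16"), 512)
  expect_equal(backbone_channels("resnet101"), 2048)
  fake_densenet <- function(img) array(runif(14 * 14 * 1024),
                                       dim = c(14, 14, 1024))
  enc <- encoder_new("densenet121", feature_fn = fake_densenet)
  expect_equal(enc$C, 1024)
  grid <- encode_image(enc, matrix(runif(224^2), 224, 224))
  expect_equal(dim(grid$features), c(49, 1024))
  expect_error(encoder_new("densenet121"), "feature_fn")
})

test_that("adaptive pooling output shape is invariant to conv-map resolution", {
  f7 <- function(img) array(1, dim = c(14, 14, 8))
  f14 <- function(img) array(1, dim = c(28, 28, 8))
  e1 <- encoder_new("vgg16", feature_fn = f7)
  e2 <- encoder_new("vgg16", feature_fn = f14)
  img <- matrix(0.3, 224, 224)
  expect_equal(dim(encode_image(e1, img)$features), c(49, 8))
  expect_equal(dim(encode_image(e2, img)$features), c(49, 8))
})

test_that("flatten/unflatten follow the row-major location convention", {
  D <- 2; C <- 3
  arr <- array(seq_len(D * D * C), dim = c(D, D, C))
  fl <- flatten_features(arr)
  # row i of fl is location ((i-1) div D, (i-1) mod D): order (0,0),(0,1),(1,0),(1,1)
  expect_equal(fl[1, ], arr[1, 1, ])
  expect_equal(fl[2, ], arr[1, 2, ])
  expect_equal(fl[3, ], arr[2, 1, ])
  expect_equal(fl[4, ], arr[2, 2, ])
  expect_equal(unflatten_features(fl, D), arr)
  # one-hot attention over location index 3 (0-based) lights block (1,1)
  maps <- attention_heatmap(c(0, 0, 0, 1), D = 2, image_size = 8,
                            rescale = TRUE)
  mx <- which(maps[[1]] == max(maps[[1]]), arr.ind = TRUE)
  expect_true(all(mx[, 1] >= 5) && all(mx[, 2] >= 5))
})

test_that("the fine-tune toggle gates encoder parameter updates", {
  fx <- phantom_fixture()
  enc <- encoder_new(seed = 5)
  cfg <- sat_config_for(enc, fx$vocab$size, embed_dim = 8, hidden_dim = 12,
                        dropout = 0, seed = 5)
  model <- sat_new(cfg, enc, fx$vocab)
  tr <- lapply(1:4, function(i) list(image = fx$samples[[i]]$image,
                                     caption = fx$caps[[i]]))
  before <- lapply(enc$params, function(p) p$val)
  sat_train(model, tr, epochs = 1, batch_size = 4, lr = 1e-2,
            finetune = FALSE, seed = 1)
  after_frozen <- lapply(enc$params, function(p) p$val)
  expect_identical(before, after_frozen)
  sat_train(model, tr, epochs = 1, batch_size = 4, lr = 1e-2,
            encoder_lr = 1e-2, finetune = TRUE, seed = 1)
  after_tuned <- lapply(enc$params, function(p) p$val)
  expect_gt(max(abs(after_tuned$W3 - before$W3)), 0)
  # toggling back restores frozen behavior
  set_finetune(enc, FALSE)
  sat_train(model, tr, epochs = 1, batch_size = 4, lr = 1e-2,
            finetune = FALSE, seed = 2)
  expect_identical(lapply(enc$params, function(p) p$val), after_tuned)
})

test_that("reference subtraction removes the shared template response", {
  fx <- phantom_fixture()
  enc <- encoder_new(seed = 6)
  imgs <- lapply(fx$samples, `[[`, "image")
  encoder_set_reference(enc, Reduce(`+`, imgs) / length(imgs))
  F <- sapply(imgs, function(im) as.vector(encode_image(enc, im)$features))
  enc0 <- encoder_new(seed = 6)
  F0 <- sapply(imgs, function(im) as.vector(encode_image(enc0, im)$features))
  # relative cross-sample variation increases once anatomy is subtracted
  rel <- function(M) mean(apply(M, 1, sd)) / mean(abs(M))
  expect_gt(rel(F), rel(F0))
})

test_that("label pretraining reduces classification loss on the phantom set", {
  fx <- phantom_fixture()
  enc <- encoder_new(seed = 7)
  imgs <- lapply(fx$samples, `[[`, "image")
  encoder_set_reference(enc, Reduce(`+`, imgs) / length(imgs))
  pre <- lapply(fx$samples, function(s) list(image = s$image,
                                             labels = s$labels))
  enc <- encoder_pretrain(enc, pre, fx$spec$catalogue, epochs = 15,
                          batch_size = 5, lr = 2e-3, seed = 1)
  h <- attr(enc, "history")
  expect_lt(h[length(h)], h[1])
})
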