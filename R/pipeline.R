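# Orchestration: configuration profiles, corpus preparation, training with
# geometric-mean-BLEU model selection, two-approach generation, evaluation
# and attention-localization measurement.

#' Pipeline configuration
#'
#' Two named profiles are provided.  `"paper"` carries the full-scale
#' training hyperparameters (captioner: 70 epochs, batch 16, embedding 100,
#' attention/decoder width 512, dropout 0.1, encoder/decoder learning rates
#' 4e-7 / 3e-7; transformer: 30 epochs, batch 4, lr 5e-5, block 1024,
#' gradient clip 1.0) and refuses to run without a real image/report corpus.
#' `"desk"` is an explicitly scaled-down profile for the phantom corpus that
#' completes on one CPU.
#'
#' @param seed Master seed for data, splits and initialization.
#' @param out_dir Directory for artifacts (created if needed).
#' @param profile `"desk"` or `"paper"`.
#' @param n_phantoms Number of phantom samples (desk profile).
#' @param dataset_path Path to a real image store (paper profile only).
#' @param ... Overrides for individual fields.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("raycap_run_"),
                       profile = c("desk", "paper"), n_phantoms = 200L,
                       dataset_path = NULL, ...) {
  profile <- match.arg(profile)
  base <- if (profile == "paper") {
    list(sat = list(epochs = 70L, batch = 16L, embed = 100L, hidden = 512L,
                    dropout = 0.1, lr_enc = 4e-7, lr_dec = 3e-7,
                    eval_every = 5L, beam_k = 3L, max_len = 100L),
         lm = list(epochs = 30L, batch = 4L, lr = 5e-5, clip = 1.0,
                   block = 1024L, layers = 4L, heads = 4L, dim = 256L,
                   merges = 4000L),
         fusion = list(epochs = 30L, lr = 1e-3, n_train = 200L),
         fractions = c(0.75, 0.2475, 0.0025))
  } else {
    list(sat = list(epochs = 18L, batch = 16L, embed = 48L, hidden = 96L,
                    dropout = 0.0, lr_enc = 1e-3, lr_dec = 1e-3,
                    eval_every = 6L, beam_k = 3L, max_len = 40L),
         lm = list(epochs = 12L, batch = 4L, lr = 3e-3, clip = 1.0,
                   block = 256L, layers = 2L, heads = 2L, dim = 64L,
                   merges = 120L),
         fusion = list(epochs = 40L, lr = 1e-2, n_train = 40L),
         fractions = c(0.75, 0.15, 0.10))
  }
  cfg <- utils::modifyList(
    c(list(seed = as.integer(seed), out_dir = out_dir, profile = profile,
           n_phantoms = as.integer(n_phantoms),
           dataset_path = dataset_path, finetune = TRUE), base),
    list(...))
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' The file may set any field accepted by [run_config()] (`seed`,
#' `profile`, `n_phantoms`, `out_dir`, and the `sat`/`lm`/`fusion`
#' sub-sections); unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seed", "out_dir", "profile", "n_phantoms", "dataset_path",
             "finetune", "sat", "lm", "fusion", "fractions")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

config_fingerprint <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  x <- utf8ToInt(s)
  sum(x * (seq_along(x) %% 89 + 1)) %% 2147483647
}

#' Select the best checkpoint by validation geometric-mean BLEU
#'
#' @param history Numeric vector of per-evaluation gm-BLEU values.
#' @return 1-based index of the maximum (ties resolve to the earliest).
#' @export
select_best_checkpoint <- function(history) {
  if (length(history) == 0) stop("empty metric history")
  which.max(history)
}

#' Prepare the caption corpus from a report table
#'
#' Applies section assembly (with the empty-report exclusion rule),
#' normalization, optional abbreviation expansion and label prefixing, then
#' builds the vocabulary and encodes the captions.
#'
#' @param reports Tibble from [read_reports()].
#' @param abbrev Optional abbreviation map from [load_abbreviations()].
#' @param min_freq Vocabulary frequency cutoff.
#' @param max_len Maximum caption length.
#' @param prefix_labels Prepend the label tokens to each caption.
#' @return List with `vocab`, `captions` (list of `token_sequence`),
#'   `texts` (the label-prefixed report texts), `kept` (row indices that
#'   survived exclusion).
#' @export
prepare_corpus <- function(reports, abbrev = NULL, min_freq = 1L,
                           max_len = 100L, prefix_labels = TRUE) {
  texts <- character(0); kept <- integer(0)
  toks <- list()
  for (i in seq_len(nrow(reports))) {
    body <- assemble_report(reports$impression[i], reports$findings[i])
    if (is_excluded(body)) next
    if (prefix_labels) {
      body <- prepend_labels(label_token(reports$labels[[i]]), body)
    }
    tk <- normalize_text(body)
    if (!is.null(abbrev)) tk <- expand_abbreviations(tk, abbrev)
    kept <- c(kept, i)
    texts <- c(texts, paste(tk, collapse = " "))
    toks[[length(toks) + 1L]] <- tk
  }
  vocab <- build_vocab(toks, min_freq = min_freq)
  captions <- lapply(toks, encode_caption, vocab = vocab,
                     max_len = max_len)
  list(vocab = vocab, captions = captions, texts = texts, kept = kept)
}

#' Measure attention localization against lesion masks
#'
#' For phantoms carrying exactly one lesion, teacher-forces the ground
#' truth caption and measures the attention mass inside the lesion mask at
#' the step where the pathology word (the label token naming the lesion)
#' is predicted, against the uniform baseline (the mask's area fraction).
#' That step is the one where the image alone determines the word: later
#' mentions of the pathology are largely predictable from the preceding
#' text.
#'
#' @param model Trained `sat_model` with vocabulary.
#' @param spec The [phantom_spec()] the samples come from.
#' @param indices 0-based phantom indices to evaluate.
#' @param encoder Encoder used for features (defaults to the model's).
#' @return Tibble with one row per usable sample: `sample_id`, `kind`,
#'   `mass_in_mask`, `area_fraction`.
#' @export
evaluate_localization <- function(model, spec, indices, encoder = NULL) {
  enc <- if (is.null(encoder)) model$encoder else encoder
  D <- as.integer(round(sqrt(model$cfg$N)))
  rows <- list()
  for (ix in indices) {
    s <- generate_phantom(spec, ix)
    if (length(s$labels) != 1L || identical(s$labels, "none")) next
    kind <- s$labels[1L]
    toks <- normalize_text(s$report)
    seqq <- encode_caption(toks, model$vocab, max_len = model$cfg$max_len)
    pos <- match(label_token(kind), toks)
    if (is.na(pos)) next
    # ids: <start> tok1 ...; alpha row t is the attention used when
    # predicting caption token t
    feats <- encode_image(enc, s$image)$features
    al <- sat_tf_alphas(model, feats, seqq$ids)
    if (pos > nrow(al)) next
    mask <- s$masks[[kind]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_id = s$sample_id, kind = kind,
      mass_in_mask = attention_mass_in_mask(al[pos, ], mask, D),
      area_fraction = mean(mask))
  }
  do.call(rbind, rows)
}

#' Run the full pipeline: simulate, prepare, train, generate, evaluate
#'
#' Stages write their artifacts under `cfg$out_dir`; a stage whose
#' configuration fingerprint matches a previous run is skipped and its
#' artifact reloaded.
#'
#' @param cfg A [run_config()].
#' @param verbose Print stage progress.
#' @return List with `metrics` (tibble, one row per generation approach),
#'   `localization` (tibble), `paths`, and the trained models.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$profile == "paper" && is.null(cfg$dataset_path)) {
    stop("the 'paper' profile needs a real dataset (dataset_path); ",
         "desk-scale phantom runs use profile = 'desk'")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  fp <- config_fingerprint(cfg)
  paths <- list(images = file.path(cfg$out_dir, "images.h5"),
                reports = file.path(cfg$out_dir, "reports.jsonl"),
                manifest = file.path(cfg$out_dir, "manifest.txt"),
                stamp = file.path(cfg$out_dir, "config.stamp"),
                sat = file.path(cfg$out_dir, "sat.rds"),
                lm = file.path(cfg$out_dir, "lm.rds"))
  cached <- file.exists(paths$stamp) &&
    identical(readLines(paths$stamp), as.character(fp))

  # -- simulate ---------------------------------------------------------
  spec <- phantom_spec(seed = cfg$seed)
  if (!cached || !file.exists(paths$images)) {
    say("stage simulate: %d phantoms", cfg$n_phantoms)
    generate_dataset(spec, cfg$n_phantoms, paths$images, paths$reports,
                     paths$manifest)
  } else say("stage simulate: cached")
  reports <- read_reports(paths$reports)

  # -- prepare ----------------------------------------------------------
  say("stage prepare")
  prep <- prepare_corpus(reports, max_len = cfg$sat$max_len)
  split <- split_dataset(reports$sample_id[prep$kept],
                         fractions = cfg$fractions, seed = cfg$seed)
  row_of <- stats::setNames(seq_along(prep$kept),
                            reports$sample_id[prep$kept])
  idx_of <- stats::setNames(prep$kept, reports$sample_id[prep$kept])

  # -- features ---------------------------------------------------------
  encoder <- encoder_new(D = 7L, image_size = spec$image_size,
                         seed = cfg$seed)
  images <- read_image_store(paths$images)
  train_idx <- vapply(split$train, function(sid) idx_of[[sid]], 1L)
  ref <- apply(images[, , train_idx, drop = FALSE], c(1, 2), mean)
  encoder_set_reference(encoder, ref)
  say("stage train-sat")
  scfg <- sat_config_for(encoder, vocab_size = prep$vocab$size,
                         embed_dim = cfg$sat$embed,
                         hidden_dim = cfg$sat$hidden,
                         dropout = cfg$sat$dropout,
                         max_len = cfg$sat$max_len, seed = cfg$seed)
  sat <- sat_new(scfg, encoder, prep$vocab)
  mk_samples <- function(ids) lapply(ids, function(sid) {
    list(image = images[, , idx_of[[sid]]],
         caption = prep$captions[[row_of[[sid]]]])
  })
  train_samples <- mk_samples(split$train)
  val_ids <- utils::head(split$val, 25L)
  val_samples <- mk_samples(val_ids)

  # train in segments, keeping the checkpoint with the best validation
  # geometric-mean BLEU
  seg <- cfg$sat$eval_every
  n_seg <- ceiling(cfg$sat$epochs / seg)
  gm_hist <- numeric(0)
  best <- NULL
  for (sgi in seq_len(n_seg)) {
    eps <- min(seg, cfg$sat$epochs - (sgi - 1L) * seg)
    sat <- sat_train(sat, train_samples, epochs = eps,
                     batch_size = cfg$sat$batch, lr = cfg$sat$lr_dec,
                     encoder_lr = cfg$sat$lr_enc, finetune = cfg$finetune,
                     seed = cfg$seed + sgi, verbose = verbose)
    val_caps <- vapply(val_samples, function(s) {
      paste(greedy_decode(sat, s$image, cfg$sat$max_len)$tokens,
            collapse = " ")
    }, "")
    val_refs <- lapply(val_ids, function(sid)
      prep$texts[row_of[[sid]]])
    gm <- gm_bleu(bleu(val_caps, val_refs))
    gm_hist <- c(gm_hist, gm)
    say("  segment %d/%d  val gm-BLEU %.3f", sgi, n_seg, gm)
    if (is.null(best) || gm > best$gm) {
      best <- list(gm = gm, params = sat_vals(sat),
                   enc = encoder_export(encoder))
    }
  }
  if (!is.null(best)) {
    for (k in names(best$params)) sat$params[[k]]$val <- best$params[[k]]
    for (k in names(best$enc$params)) {
      encoder$params[[k]]$val <- best$enc$params[[k]]
    }
  }
  sat_save(sat, paths$sat)

  # -- train-lm ---------------------------------------------------------
  say("stage train-lm")
  train_texts <- prep$texts[vapply(split$train, function(sid)
    row_of[[sid]], 1L)]
  bpe <- train_bpe(train_texts, cfg$lm$merges)
  lcfg <- lm_config(vocab_size = bpe$size, layers = cfg$lm$layers,
                    heads = cfg$lm$heads, dim = cfg$lm$dim,
                    block = cfg$lm$block, seed = cfg$seed)
  lm <- lm_new(lcfg, bpe)
  lm <- lm_finetune(lm, train_texts, epochs = cfg$lm$epochs,
                    lr = cfg$lm$lr, grad_clip = cfg$lm$clip,
                    batch_size = cfg$lm$batch, seed = cfg$seed,
                    verbose = verbose)
  lm_save(lm, paths$lm)

  # -- train-fusion -----------------------------------------------------
  say("stage train-fusion")
  head_ <- fusion_head_new(prep$vocab$size, seed = cfg$seed)
  fus_samples <- lapply(
    utils::head(train_samples, cfg$fusion$n_train), function(s) {
      list(features = encode_image(encoder, s$image)$features,
           caption = s$caption)
    })
  head_ <- train_fusion_head(head_, sat, lm, fus_samples,
                             epochs = cfg$fusion$epochs,
                             lr = cfg$fusion$lr, seed = cfg$seed)

  # -- generate + evaluate ---------------------------------------------
  say("stage generate/evaluate")
  test_ids <- split$test
  if (length(test_ids) == 0L) test_ids <- utils::head(split$val, 10L)
  gen <- lapply(test_ids, function(sid) {
    img <- images[, , idx_of[[sid]]]
    sat_cap <- paste(greedy_decode(sat, img, cfg$sat$max_len)$tokens,
                     collapse = " ")
    a2 <- generate_approach2(img, sat, lm, sat_k = 1L,
                             lm_k = cfg$sat$beam_k)
    a1 <- generate_approach1(img, sat, lm, head_,
                             max_len = cfg$sat$max_len)
    tibble::tibble(sample_id = sid, sat = sat_cap, approach1 = a1$report,
                   approach2 = a2$report, sat_seed = a2$sat_seed,
                   lm_continuation = a2$lm_continuation)
  })
  gen <- do.call(rbind, gen)
  refs <- lapply(test_ids, function(sid) prep$texts[row_of[[sid]]])
  ref_texts <- vapply(refs, `[[`, "", 1L)
  labs <- setdiff(spec$catalogue, character(0))
  mk_row <- function(cand, name) {
    mr <- metric_report(cand, refs, labels = labs,
                        reference_texts = ref_texts)
    tibble::tibble(model = name, mr)
  }
  metrics <- rbind(mk_row(gen$sat, "sat"),
                   mk_row(gen$approach1, "approach1"),
                   mk_row(gen$approach2, "approach2"))

  heldout <- (cfg$n_phantoms):(cfg$n_phantoms + 49L)
  loc <- evaluate_localization(sat, spec, heldout)
  writeLines(as.character(fp), paths$stamp)
  list(metrics = metrics, localization = loc, generated = gen,
       paths = paths, sat = sat, lm = lm, fusion_head = head_,
       gm_history = gm_hist, split = split)
}
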