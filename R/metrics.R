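# Caption evaluation metrics.
#
# BLEU-1..4 are corpus-level clipped n-gram precisions with a brevity
# penalty ("BLEU-n" uses n-grams up to order n); ROUGE-L is the
# LCS-based F-measure with the captioning convention beta = 1.2 (max over
# references, mean over samples); CIDEr is the TF-IDF-weighted n-gram
# cosine consensus with count clipping and a Gaussian length penalty
# (sigma = 6), scaled to [0, 10].  Clinical-efficacy metrics compare the
# label terms extracted from generated and reference reports, pooled over
# all (sample, label) pairs (micro-averaging).  All metrics tokenize with
# the same normalize_text() used in training.

metric_tokens <- function(x) {
  if (is.list(x)) lapply(x, function(e) {
    if (is.character(e) && length(e) == 1L) normalize_text(e) else
      as.character(e)
  })
  else lapply(x, normalize_text)
}

ngram_counts <- function(tokens, n) {
  if (length(tokens) < n) return(integer(0))
  grams <- vapply(seq_len(length(tokens) - n + 1L), function(i)
    paste(tokens[i:(i + n - 1L)], collapse = " "), "")
  c(table(grams))
}

#' Corpus-level BLEU-1..4
#'
#' @param candidates Character vector (one candidate per sample) or list of
#'   token vectors.
#' @param references List with one element per sample, each a character
#'   vector of one or more reference texts (or a list of token vectors).
#' @param max_n Highest n-gram order.
#' @return Numeric vector `bleu1..bleu<max_n>`, where BLEU-n uses n-grams
#'   up to order n.
#' @export
bleu <- function(candidates, references, max_n = 4L) {
  if (length(candidates) == 0) stop("empty candidate set")
  stopifnot(length(candidates) == length(references))
  cand <- metric_tokens(candidates)
  refs <- lapply(references, function(rr) {
    if (is.character(rr)) lapply(rr, normalize_text) else rr
  })
  num <- numeric(max_n); den <- numeric(max_n)
  c_len <- 0; r_len <- 0
  for (i in seq_along(cand)) {
    ct <- cand[[i]]
    c_len <- c_len + length(ct)
    rlens <- vapply(refs[[i]], length, 1L)
    # effective reference length: closest to the candidate, ties -> shorter
    r_len <- r_len + rlens[order(abs(rlens - length(ct)), rlens)][1L]
    for (n in seq_len(max_n)) {
      cc <- ngram_counts(ct, n)
      den[n] <- den[n] + sum(cc)
      if (length(cc) == 0) next
      maxref <- integer(length(cc))
      names(maxref) <- names(cc)
      for (rt in refs[[i]]) {
        rc <- ngram_counts(rt, n)
        hit <- intersect(names(cc), names(rc))
        maxref[hit] <- pmax(maxref[hit], rc[hit])
      }
      num[n] <- num[n] + sum(pmin(cc, maxref))
    }
  }
  p <- ifelse(den > 0, num / den, 0)
  bp <- if (c_len > r_len) 1 else exp(1 - r_len / max(c_len, 1))
  out <- numeric(max_n)
  for (n in seq_len(max_n)) {
    out[n] <- if (any(p[seq_len(n)] == 0)) 0 else
      bp * exp(mean(log(p[seq_len(n)])))
  }
  stats::setNames(out, paste0("bleu", seq_len(max_n)))
}

lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
                     else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' ROUGE-L (LCS F-measure, beta = 1.2)
#'
#' @inheritParams bleu
#' @param beta Recall weight of the F-measure.
#' @return Mean over samples of the max-over-references F score.
#' @export
rouge_l <- function(candidates, references, beta = 1.2) {
  cand <- metric_tokens(candidates)
  refs <- lapply(references, function(rr) {
    if (is.character(rr)) lapply(rr, normalize_text) else rr
  })
  scores <- vapply(seq_along(cand), function(i) {
    ct <- cand[[i]]
    max(vapply(refs[[i]], function(rt) {
      l <- lcs_length(ct, rt)
      if (l == 0) return(0)
      prec <- l / length(ct)
      rec <- l / length(rt)
      (1 + beta^2) * prec * rec / (rec + beta^2 * prec)
    }, 0))
  }, 0)
  mean(scores)
}

#' CIDEr consensus metric
#'
#' TF-IDF n-gram vectors (n = 1..4) over the reference corpus, clipped
#' cosine similarity per reference with a Gaussian length penalty
#' (`sigma`), averaged over references and n, scaled by 10.
#'
#' @inheritParams bleu
#' @param sigma Length-penalty width in tokens.
#' @return Mean per-sample score in \[0, 10\].
#' @export
cider <- function(candidates, references, sigma = 6) {
  cand <- metric_tokens(candidates)
  refs <- lapply(references, function(rr) {
    if (is.character(rr)) lapply(rr, normalize_text) else rr
  })
  N <- length(cand)
  if (N < 2) warning("single-sample corpus: IDF is degenerate")
  max_n <- 4L
  # document frequency over reference sets
  df <- lapply(seq_len(max_n), function(n) new.env(parent = emptyenv()))
  for (i in seq_len(N)) {
    for (n in seq_len(max_n)) {
      seen <- unique(unlist(lapply(refs[[i]], function(rt)
        names(ngram_counts(rt, n)))))
      for (g in seen) {
        df[[n]][[g]] <- (if (is.null(df[[n]][[g]])) 0 else df[[n]][[g]]) + 1
      }
    }
  }
  logN <- log(N)
  vecs <- function(tokens) {
    lapply(seq_len(max_n), function(n) {
      cc <- ngram_counts(tokens, n)
      if (length(cc) == 0) return(numeric(0))
      idf <- vapply(names(cc), function(g) {
        d <- df[[n]][[g]]
        logN - log(max(if (is.null(d)) 0 else d, 1))
      }, 0)
      cc * idf
    })
  }
  scores <- vapply(seq_len(N), function(i) {
    vh <- vecs(cand[[i]])
    nh <- vapply(vh, function(v) sqrt(sum(v^2)), 0)
    per_ref <- vapply(refs[[i]], function(rt) {
      vr <- vecs(rt)
      nr <- vapply(vr, function(v) sqrt(sum(v^2)), 0)
      delta <- length(cand[[i]]) - length(rt)
      val <- numeric(max_n)
      for (n in seq_len(max_n)) {
        if (length(vh[[n]]) == 0 || length(vr[[n]]) == 0) next
        common <- intersect(names(vh[[n]]), names(vr[[n]]))
        if (length(common) == 0 || nh[n] == 0 || nr[n] == 0) next
        val[n] <- sum(pmin(vh[[n]][common], vr[[n]][common]) *
                        vr[[n]][common]) / (nh[n] * nr[n])
      }
      mean(val) * exp(-delta^2 / (2 * sigma^2))
    }, 0)
    mean(per_ref) * 10
  }, 0)
  mean(scores)
}

#' Geometric mean of the four BLEU scores
#'
#' Used for model selection: the checkpoint with the highest geometric-mean
#' BLEU on validation is kept.
#'
#' @param b Numeric vector of four BLEU values.
#' @return Fourth root of the product (0 if any component is 0).
#' @export
gm_bleu <- function(b) {
  stopifnot(length(b) == 4L, all(b >= 0))
  if (any(b == 0)) return(0)
  exp(mean(log(b)))
}

#' Micro-averaged clinical-efficacy metrics
#'
#' A binary label-presence vector is extracted from each text by exact
#' matching of label-vocabulary tokens after normalization; TP/FP/FN/TN are
#' pooled over all (sample, label) pairs.  Zero-denominator conventions
#' return 0.
#'
#' @param generated,reference Character vectors of reports (same length).
#' @param label_vocabulary Closed set of label terms.
#' @return Named numeric vector: `accuracy`, `precision`, `recall`, `f1`.
#' @export
ce_metrics <- function(generated, reference, label_vocabulary) {
  if (length(label_vocabulary) == 0) stop("empty label vocabulary")
  stopifnot(length(generated) == length(reference))
  labs <- label_token(label_vocabulary)
  present <- function(text) labs %in% normalize_text(text)
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(generated)) {
    g <- present(generated[i]); r <- present(reference[i])
    tp <- tp + sum(g & r); fp <- fp + sum(g & !r)
    fn <- fn + sum(!g & r); tn <- tn + sum(!g & !r)
  }
  total <- tp + fp + fn + tn
  acc <- if (total > 0) (tp + tn) / total else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

#' Full metric report as a one-row tibble
#'
#' @inheritParams bleu
#' @param labels Optional label vocabulary for clinical-efficacy metrics.
#' @param reference_texts Reference reports used for label extraction
#'   (defaults to the first reference of each sample).
#' @return One-row tibble with `bleu1..bleu4`, `rouge_l`, `cider`,
#'   `gm_bleu` and, when labels are given, the four CE columns.
#' @export
metric_report <- function(candidates, references, labels = NULL,
                          reference_texts = NULL) {
  b <- bleu(candidates, references)
  out <- tibble::tibble(bleu1 = b[1], bleu2 = b[2], bleu3 = b[3],
                        bleu4 = b[4],
                        rouge_l = rouge_l(candidates, references),
                        cider = cider(candidates, references),
                        gm_bleu = gm_bleu(b))
  if (!is.null(labels)) {
    if (is.null(reference_texts)) {
      reference_texts <- vapply(references, function(r) r[[1L]], "")
    }
    ce <- ce_metrics(candidates, reference_texts, labels)
    out$ce_accuracy <- ce["accuracy"]
    out$ce_precision <- ce["precision"]
    out$ce_recall <- ce["recall"]
    out$ce_f1 <- ce["f1"]
  }
  out
}
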