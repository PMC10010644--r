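# Byte-pair-encoding subword tokenizer for the transformer side.
#
# Greedy merge learning over a word-frequency table: each step merges the
# most frequent adjacent symbol pair (ties broken lexicographically) and
# stops early once no pair occurs at least twice.  Words carry an
# end-of-word marker so subwords are position-aware, and unseen characters
# fall back to byte symbols, so encoding never produces an unknown token.

BPE_EOW <- "</w>"
BPE_START <- "<s>"       # start-of-continuation
BPE_EOT <- "<eot>"       # end-of-text

bpe_byte_symbols <- function() sprintf("<0x%02X>", 0:255)

bpe_word_to_symbols <- function(word) {
  chars <- strsplit(word, "")[[1]]
  chars[length(chars)] <- paste0(chars[length(chars)], BPE_EOW)
  chars
}

# Replace all adjacent occurrences of pair (a, b) by the merged symbol.
bpe_apply_merge <- function(symbols, a, b, merged) {
  n <- length(symbols)
  if (n < 2) return(symbols)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    if (i < n && symbols[i] == a && symbols[i + 1L] == b) {
      out <- c(out, merged)
      i <- i + 2L
    } else {
      out <- c(out, symbols[i])
      i <- i + 1L
    }
  }
  out
}

#' Train a byte-pair-encoding model
#'
#' @param corpus Character vector of texts.
#' @param num_merges Maximum number of merges to learn (>= 0).  Learning
#'   stops early when no adjacent pair occurs at least twice.
#' @return A `bpe_model` with the ordered merge list and the subword-to-id
#'   map (special tokens, byte-fallback symbols, characters, merges).
#' @export
#' @examples
#' m <- train_bpe("aaab aaab", 4)
#' m$merges[[1]]  # first merge is the most frequent pair
train_bpe <- function(corpus, num_merges) {
  corpus <- corpus[nzchar(trimws(corpus))]
  if (length(corpus) == 0) stop("empty corpus")
  if (num_merges < 0) stop("num_merges must be >= 0")
  words <- unlist(strsplit(trimws(corpus), "\\s+"), use.names = FALSE)
  wtab <- table(words)
  wfreq <- as.integer(wtab)
  wsyms <- lapply(names(wtab), bpe_word_to_symbols)
  merges <- list()
  for (step in seq_len(num_merges)) {
    # count adjacent pairs weighted by word frequency
    counts <- new.env(parent = emptyenv())
    for (w in seq_along(wsyms)) {
      s <- wsyms[[w]]
      if (length(s) < 2) next
      for (i in seq_len(length(s) - 1L)) {
        key <- paste0(s[i], "\t", s[i + 1L])
        counts[[key]] <- (if (is.null(counts[[key]])) 0L
                          else counts[[key]]) + wfreq[w]
      }
    }
    keys <- ls(counts)
    if (length(keys) == 0) break
    vals <- vapply(keys, function(k) counts[[k]], 0L)
    best <- max(vals)
    if (best < 2L) break
    cand <- sort(keys[vals == best])[1]  # lexicographic tie-break
    pair <- strsplit(cand, "\t", fixed = TRUE)[[1]]
    merged <- paste0(pair[1], pair[2])
    merges[[length(merges) + 1L]] <- c(pair, merged)
    wsyms <- lapply(wsyms, bpe_apply_merge, a = pair[1], b = pair[2],
                    merged = merged)
  }
  chars <- sort(unique(unlist(lapply(names(wtab), bpe_word_to_symbols))))
  merged_syms <- vapply(merges, `[`, "", 3L)
  id2sym <- c(BPE_START, BPE_EOT, bpe_byte_symbols(), chars, merged_syms)
  id2sym <- id2sym[!duplicated(id2sym)]
  sym2id <- stats::setNames(seq_along(id2sym) - 1L, id2sym)
  structure(list(merges = merges, id2sym = id2sym, sym2id = sym2id,
                 start_id = 0L, eot_id = 1L, size = length(id2sym)),
            class = "bpe_model")
}

#' @export
print.bpe_model <- function(x, ...) {
  cat("<bpe_model>", length(x$merges), "merges,", x$size, "subwords\n")
  invisible(x)
}

# Segment one word into subword symbols by applying merges in learned order.
bpe_segment_word <- function(word, model) {
  s <- bpe_word_to_symbols(word)
  for (m in model$merges) {
    if (length(s) < 2) break
    s <- bpe_apply_merge(s, m[1], m[2], m[3])
  }
  s
}

# Map symbols to ids, byte-fallback for symbols outside the vocabulary.
bpe_syms_to_ids <- function(syms, model) {
  out <- integer(0)
  for (sym in syms) {
    id <- unname(model$sym2id[sym])
    if (!is.na(id)) {
      out <- c(out, id)
    } else {
      # unseen character(s): emit byte symbols, then the bare EOW if present
      had_eow <- endsWith(sym, BPE_EOW)
      core <- if (had_eow) substr(sym, 1L, nchar(sym) - nchar(BPE_EOW))
              else sym
      bytes <- as.integer(charToRaw(core))
      out <- c(out, unname(model$sym2id[sprintf("<0x%02X>", bytes)]))
      if (had_eow) out <- c(out, model$sym2id[["<0x20>"]])
    }
  }
  as.integer(out)
}

#' Encode text as BPE subword ids
#'
#' Whitespace-split words are segmented by the learned merges; characters
#' outside the training set are emitted as byte-fallback symbols, so no
#' unknown token is ever produced.
#'
#' @param text Character string.
#' @param model A `bpe_model`.
#' @param add_specials Frame the ids with the start-of-continuation /
#'   end-of-text specials (used for language-model training).
#' @return Integer vector of 0-based subword ids.
#' @export
bpe_encode <- function(text, model, add_specials = FALSE) {
  words <- unlist(strsplit(trimws(text), "\\s+"), use.names = FALSE)
  words <- words[nzchar(words)]
  ids <- unlist(lapply(words, function(w)
    bpe_syms_to_ids(bpe_segment_word(w, model), model)), use.names = FALSE)
  if (is.null(ids)) ids <- integer(0)
  if (add_specials) ids <- c(model$start_id, ids, model$eot_id)
  as.integer(ids)
}

#' Decode BPE subword ids back to text
#'
#' Inverse of [bpe_encode()] up to whitespace normalization: subwords are
#' concatenated, end-of-word markers become single spaces and byte-fallback
#' symbols are reassembled into characters.  Special tokens are dropped.
#'
#' @param ids Integer vector of 0-based subword ids.
#' @param model A `bpe_model`.
#' @return Character string.
#' @export
bpe_decode <- function(ids, model) {
  syms <- model$id2sym[ids + 1L]
  syms <- syms[!(syms %in% c(BPE_START, BPE_EOT))]
  out_bytes <- raw(0)
  for (sym in syms) {
    if (grepl("^<0x[0-9A-F]{2}>$", sym)) {
      out_bytes <- c(out_bytes, as.raw(strtoi(substr(sym, 4L, 5L), 16L)))
    } else {
      had_eow <- endsWith(sym, BPE_EOW)
      core <- if (had_eow) substr(sym, 1L, nchar(sym) - nchar(BPE_EOW))
              else sym
      out_bytes <- c(out_bytes, charToRaw(core))
      if (had_eow) out_bytes <- c(out_bytes, charToRaw(" "))
    }
  }
  trimws(rawToChar(out_bytes))
}

#' Serialize / load a BPE model as JSON
#' @param model A `bpe_model`.
#' @param path File path.
#' @return `bpe_load` returns the `bpe_model`.
#' @export
bpe_save <- function(model, path) {
  jsonlite::write_json(list(merges = model$merges, id2sym = model$id2sym),
                       path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname bpe_save
#' @export
bpe_load <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  merges <- lapply(obj$merges, function(m) unlist(m))
  id2sym <- unlist(obj$id2sym)
  sym2id <- stats::setNames(seq_along(id2sym) - 1L, id2sym)
  structure(list(merges = merges, id2sym = id2sym, sym2id = sym2id,
                 start_id = 0L, eot_id = 1L, size = length(id2sym)),
            class = "bpe_model")
}
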