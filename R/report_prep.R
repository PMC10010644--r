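# Radiology report preprocessing for the word-level (captioner) side:
# section assembly with the empty-report exclusion rule, token
# normalization, abbreviation expansion, label prefixing, vocabulary
# construction and caption encoding with length-sorted batching support.

#' Sentinel returned for reports with both sections empty
#' @export
EXCLUDED <- structure("EXCLUDED", class = "rc_excluded")

#' Assemble a report from its impression and findings sections
#'
#' The caption target is the concatenation of the two sections; a report
#' whose sections are both empty (after whitespace stripping) is excluded
#' from the corpus.
#'
#' @param impression,findings Character strings (may be empty).
#' @return The concatenated text, or the [EXCLUDED] sentinel.
#' @export
#' @examples
#' assemble_report("No acute disease.", "")
#' is_excluded(assemble_report("", ""))
assemble_report <- function(impression, findings) {
  parts <- trimws(c(impression, findings))
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) return(EXCLUDED)
  paste(parts, collapse = " ")
}

#' Test for the exclusion sentinel
#' @param x Result of [assemble_report()].
#' @return Logical.
#' @export
is_excluded <- function(x) inherits(x, "rc_excluded")

#' Normalize report text into tokens
#'
#' Whitespace tokenization, lowercasing, removal of non-alphanumeric
#' characters inside tokens (hyphens deleted, digits kept); empty tokens are
#' dropped.  Idempotent.
#'
#' @param text Character string.
#' @return Character vector of tokens.
#' @export
#' @examples
#' normalize_text("No Pneumothorax.")
#' normalize_text("X-ray #2")
normalize_text <- function(text) {
  if (length(text) == 0 || !nzchar(trimws(text))) return(character(0))
  toks <- strsplit(tolower(text), "\\s+")[[1]]
  toks <- gsub("[^a-z0-9]", "", toks)
  toks[nzchar(toks)]
}

#' Expand abbreviations in a token stream
#'
#' Single pass: each token matching a dictionary key is replaced by its
#' expansion; produced tokens are never re-expanded.
#'
#' @param tokens Character vector of normalized tokens.
#' @param abbrev_map Named list mapping a token to a character vector of
#'   expansion tokens (as from [load_abbreviations()]).
#' @return Character vector of tokens.
#' @export
expand_abbreviations <- function(tokens, abbrev_map) {
  if (length(abbrev_map) == 0 || length(tokens) == 0) return(tokens)
  out <- lapply(tokens, function(tk) {
    hit <- abbrev_map[[tk]]
    if (is.null(hit)) tk else hit
  })
  unlist(out, use.names = FALSE)
}

#' Load an abbreviation dictionary from a two-column TSV file
#'
#' Column 1 is the abbreviation token, column 2 its space-separated
#' expansion.  Keys and expansions are normalized; a cyclic dictionary (a
#' key reachable from its own expansion) is rejected at load time even
#' though expansion itself is single-pass.
#'
#' @param path TSV file path.
#' @return Named list of expansion token vectors.
#' @export
load_abbreviations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  map <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t")[[1]]
    if (length(fields) < 2) stop("malformed abbreviation line: ", ln)
    key <- normalize_text(fields[1])
    if (length(key) != 1) stop("abbreviation key must be one token: ",
                               fields[1])
    map[[key]] <- normalize_text(fields[2])
  }
  # cycle check over keys reachable through expansions
  keys <- names(map)
  visit <- function(k, stack) {
    if (k %in% stack) stop("cyclic abbreviation dictionary at: ", k)
    for (nxt in intersect(map[[k]], keys)) visit(nxt, c(stack, k))
  }
  for (k in keys) visit(k, character(0))
  map
}

#' Prepend label tokens to a report
#'
#' Emulates label-prefixed ground-truth reports: the label tokens are placed
#' before the text, delimited by a period token.  An empty label list
#' returns the report unchanged.
#'
#' @param labels Character vector of label tokens (ordered).
#' @param report_text Report text.
#' @return Character string.
#' @export
#' @examples
#' prepend_labels("cardiomegaly", "heart is enlarged")
prepend_labels <- function(labels, report_text) {
  if (length(labels) == 0) return(report_text)
  paste(paste(labels, collapse = " "), ".", report_text)
}

SPECIAL_TOKENS <- c("<start>", "<end>", "<pad>", "<unk>")
START_ID <- 0L; END_ID <- 1L; PAD_ID <- 2L; UNK_ID <- 3L

#' Build a word vocabulary from a token corpus
#'
#' Tokens with corpus frequency at least `min_freq` receive ids after the
#' four special tokens (`<start>`=0, `<end>`=1, `<pad>`=2, `<unk>`=3), in
#' frequency-descending then lexicographic order; rarer tokens encode to
#' `<unk>`.
#'
#' @param corpus A character vector of tokens, or a list of token vectors.
#' @param min_freq Minimum frequency for inclusion.
#' @return An object of class `rc_vocab`.
#' @export
build_vocab <- function(corpus, min_freq = 1L) {
  if (is.list(corpus)) corpus <- unlist(corpus, use.names = FALSE)
  if (length(corpus) == 0) stop("empty corpus")
  tab <- table(corpus)
  keep <- tab[tab >= min_freq]
  ord <- order(-as.integer(keep), names(keep))
  words <- names(keep)[ord]
  id2word <- c(SPECIAL_TOKENS, words)
  word2id <- stats::setNames(seq_along(id2word) - 1L, id2word)
  structure(list(word2id = word2id, id2word = id2word,
                 size = length(id2word)),
            class = "rc_vocab")
}

#' @export
print.rc_vocab <- function(x, ...) {
  cat("<rc_vocab>", x$size, "tokens (4 special)\n")
  invisible(x)
}

#' Map tokens to vocabulary ids
#' @param tokens Character vector.
#' @param vocab An `rc_vocab`.
#' @return Integer vector of 0-based ids (`<unk>` for out-of-vocabulary).
#' @export
vocab_encode <- function(tokens, vocab) {
  ids <- unname(vocab$word2id[tokens])
  ids[is.na(ids)] <- UNK_ID
  as.integer(ids)
}

#' Map vocabulary ids back to tokens
#' @param ids Integer vector of 0-based ids.
#' @param vocab An `rc_vocab`.
#' @param strip_special Drop start/end/pad tokens.
#' @return Character vector of tokens.
#' @export
vocab_decode <- function(ids, vocab, strip_special = TRUE) {
  toks <- vocab$id2word[ids + 1L]
  if (strip_special) {
    toks <- toks[!(ids %in% c(START_ID, END_ID, PAD_ID))]
  }
  toks
}

#' Serialize / load a vocabulary as JSON
#' @param vocab An `rc_vocab`.
#' @param path File path.
#' @return `vocab_load` returns the `rc_vocab`.
#' @export
vocab_save <- function(vocab, path) {
  jsonlite::write_json(list(id2word = vocab$id2word), path,
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname vocab_save
#' @export
vocab_load <- function(path) {
  id2word <- jsonlite::fromJSON(path)$id2word
  word2id <- stats::setNames(seq_along(id2word) - 1L, id2word)
  structure(list(word2id = word2id, id2word = id2word,
                 size = length(id2word)),
            class = "rc_vocab")
}

#' Encode a token list as a framed caption sequence
#'
#' Frames the ids with start/end and truncates to at most `max_len` ids in
#' total (tokens beyond `max_len - 2` are dropped).
#'
#' @param tokens Character vector of tokens.
#' @param vocab An `rc_vocab`.
#' @param max_len Maximum sequence length including the frame (>= 2).
#' @return A `token_sequence` list with `ids` (0-based) and `length`.
#' @export
encode_caption <- function(tokens, vocab, max_len = 100L) {
  if (max_len < 2) stop("max_len must be >= 2")
  ids <- vocab_encode(tokens, vocab)
  if (length(ids) > max_len - 2L) ids <- ids[seq_len(max_len - 2L)]
  ids <- c(START_ID, ids, END_ID)
  structure(list(ids = as.integer(ids), length = length(ids)),
            class = "token_sequence")
}

#' Pad a batch of caption sequences and sort by decreasing length
#'
#' Rows of the returned matrix are padded with the pad id and ordered by
#' decreasing true length (stable for ties), matching the batching scheme
#' where per-time-step effective batch sizes shrink as shorter captions
#' finish.
#'
#' @param seqs List of `token_sequence` objects.
#' @return List with `ids` (matrix, one row per sequence), `lengths`
#'   (decreasing), `perm` (1-based indices into the original batch) such
#'   that `ids[i, ] == pad(seqs[[perm[i]]])`.
#' @export
pad_and_sort <- function(seqs) {
  lens <- as.integer(vapply(seqs, function(s) as.numeric(s$length), 1))
  perm <- order(lens, decreasing = TRUE)
  maxlen <- max(lens)
  ids <- matrix(PAD_ID, length(seqs), maxlen)
  for (i in seq_along(perm)) {
    s <- seqs[[perm[i]]]
    ids[i, seq_len(s$length)] <- s$ids
  }
  list(ids = ids, lengths = lens[perm], perm = perm)
}

#' Effective batch size at each time step
#'
#' For decreasing lengths, the number of sequences still active at step
#' `s` is `#\{length >= s\}`; pad positions are never processed.
#'
#' @param lengths Integer vector of true lengths (any order).
#' @return Integer vector of length `max(lengths)`.
#' @export
#' @examples
#' effective_batch_sizes(c(5, 3, 2))  # 3 3 2 1 1
effective_batch_sizes <- function(lengths) {
  vapply(seq_len(max(lengths)),
         function(s) sum(lengths >= s), 1L)
}
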