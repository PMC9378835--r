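#' Read and write labeled post corpora
#'
#' A corpus is a data frame with columns `id` (unique non-empty strings),
#' `label` (one of green/amber/red/crisis, or `NA` for unlabeled posts) and
#' `text`.  Two interchange formats are supported: JSONL (one object per
#' line with fields `"id"`, `"label"`, `"text"`) and 3-column TSV with a
#' header line.
#'
#' @param path File path.
#' @return `read_corpus_*`: the corpus data frame. `write_corpus_*`: `path`,
#'   invisibly.
#' @name corpus_io
NULL

validate_corpus <- function(corpus) {
  stopifnot(is.data.frame(corpus), all(c("id", "text") %in% names(corpus)))
  corpus$id <- as.character(corpus$id)
  corpus$text <- as.character(corpus$text)
  if (any(!nzchar(corpus$id)) || anyDuplicated(corpus$id)) {
    stop("post ids must be non-empty and unique", call. = FALSE)
  }
  if (is.null(corpus$label)) corpus$label <- NA_character_
  corpus$label <- as.character(as_triage_factor(corpus$label))
  corpus[c("id", "label", "text")]
}

#' @rdname corpus_io
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  validate_corpus(data.frame(
    id = vapply(recs, function(r) as.character(r$id %||% ""), ""),
    label = vapply(recs, function(r) as.character(r$label %||% NA_character_), ""),
    text = vapply(recs, function(r) as.character(r$text %||% ""), "")))
}

#' @rdname corpus_io
#' @param corpus Corpus data frame.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  corpus <- validate_corpus(corpus)
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    rec <- list(id = corpus$id[i], text = corpus$text[i])
    if (!is.na(corpus$label[i])) rec$label <- corpus$label[i]
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname corpus_io
#' @export
read_corpus_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  df$label[!nzchar(df$label %||% character(nrow(df)))] <- NA_character_
  validate_corpus(df)
}

#' @rdname corpus_io
#' @export
write_corpus_tsv <- function(corpus, path) {
  corpus <- validate_corpus(corpus)
  corpus$label[is.na(corpus$label)] <- ""
  utils::write.table(corpus, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Replace links with the URL marker
#'
#' Every `http://`, `https://` or `www.`-prefixed substring, up to the next
#' whitespace, is replaced by the single token `URL`.
#'
#' @param text Character vector.
#' @return Character vector with links replaced.
#' @export
#' @examples
#' replace_links("help me http://a.example/x now")
replace_links <- function(text) {
  gsub("(https?://|www\\.)\\S*", URL_TOKEN, text, perl = TRUE)
}

# Regex covering the Unicode emoji blocks (BMP symbol ranges + SMP emoji).
emoji_regex <- function() {
  "[\u2600-\u27bf\u2b00-\u2bff\ufe0f\U0001f000-\U0001f0ff\U0001f300-\U0001faff]"
}

#' Extract emoji occurrences from text
#'
#' Finds every codepoint in the Unicode emoji blocks plus any configured
#' ASCII emoticons.
#'
#' @param text Character vector.
#' @param emoticons Character vector of ASCII emoticons matched as fixed
#'   strings (e.g. `":("`).
#' @return Character vector of occurrences, in no particular order.
#' @export
extract_emojis <- function(text, emoticons = character()) {
  hits <- regmatches(text, gregexpr(emoji_regex(), text, perl = TRUE))
  out <- unlist(hits, use.names = FALSE)
  for (e in emoticons) {
    n <- vapply(gregexpr(e, text, fixed = TRUE),
                function(m) if (m[1] == -1L) 0L else length(m), 0L)
    out <- c(out, rep(e, sum(n)))
  }
  out
}

#' Assign emoji polarities from a labeled corpus
#'
#' Emojis occurring only in urgent-class posts (red, crisis) are negative;
#' only in non-urgent posts (green, amber), positive; in both, neutral.
#' Emojis absent from the corpus are not in the map.
#'
#' @param corpus Labeled corpus data frame (see [corpus_io]).
#' @param emoticons ASCII emoticons also treated as emojis.
#' @return Named character vector mapping emoji to
#'   `"negative"`/`"positive"`/`"neutral"`.
#' @export
assign_emoji_polarity <- function(corpus, emoticons = character()) {
  corpus <- validate_corpus(corpus)
  corpus <- corpus[!is.na(corpus$label), , drop = FALSE]
  if (nrow(corpus) == 0L) {
    stop("emoji polarity needs at least one labeled post", call. = FALSE)
  }
  urgent <- corpus$label %in% urgent_levels()
  in_urgent <- unique(extract_emojis(corpus$text[urgent], emoticons))
  in_nonurg <- unique(extract_emojis(corpus$text[!urgent], emoticons))
  all_emo <- union(in_urgent, in_nonurg)
  pol <- ifelse(all_emo %in% in_urgent & all_emo %in% in_nonurg, "neutral",
                ifelse(all_emo %in% in_urgent, "negative", "positive"))
  stats::setNames(pol, all_emo)
}

#' Substitute emojis with polarity marker tokens
#'
#' Each emoji in the polarity map is replaced by the corresponding reserved
#' token (`EMO_NEG`, `EMO_POS`, `EMO_NEU`), surrounded by spaces so it
#' tokenizes on its own.  Emojis not in the map are left for
#' [filter_chars()] to drop.
#'
#' @param text Character vector.
#' @param polarity_map Map from [assign_emoji_polarity()].
#' @return Character vector with marker tokens in place of mapped emojis.
#' @export
substitute_emojis <- function(text, polarity_map) {
  if (length(polarity_map) == 0L) return(text)
  # longest-first so multi-character emoticons are replaced before subsets
  ord <- order(-nchar(names(polarity_map)))
  for (i in ord) {
    marker <- EMO_TOKENS[[polarity_map[[i]]]]
    text <- gsub(names(polarity_map)[i], paste0(" ", marker, " "), text,
                 fixed = TRUE)
  }
  text
}

#' Remove characters outside the retained inventory
#'
#' Keeps ASCII letters, digits, punctuation and whitespace; everything else
#' (undecodable symbols, emojis not substituted beforehand) is removed.
#'
#' @param text Character vector (emoji substitution already applied).
#' @return Filtered character vector.
#' @export
filter_chars <- function(text) {
  gsub("[^A-Za-z0-9[:punct:][:space:]]", "", text, perl = TRUE)
}

# Punctuation set split into standalone tokens. Underscore is excluded so the
# reserved EMO_* markers survive tokenization intact.
PUNCT_SPLIT_REGEX <- "([!\"#$%&'()*+,\\-./:;<=>?@\\[\\\\\\]^`{|}~])"

# Lowercased whitespace/punctuation tokenization; reserved markers kept as-is.
tokenize_text <- function(text) {
  text <- gsub(PUNCT_SPLIT_REGEX, " \\1 ", text, perl = TRUE)
  toks <- strsplit(trimws(text), "\\s+", perl = TRUE)
  lapply(toks, function(t) {
    t <- t[nzchar(t)]
    keep <- t %in% reserved_tokens()
    t[!keep] <- tolower(t[!keep])
    t
  })
}

#' Tokenize a post and pad or truncate to a fixed length
#'
#' Applies emoji substitution (if a polarity map is given), character
#' filtering, lowercased whitespace/punctuation tokenization, then right-pads
#' with `PAD` to length `n` or keeps the first `n` tokens.  Stop words are
#' retained throughout.
#'
#' @param text A single string, links already replaced via [replace_links()].
#' @param n Target sequence length (>= 1).
#' @param polarity_map Optional emoji polarity map.
#' @return List with `tokens` (character vector of length `n`) and `n_i`
#'   (number of non-pad tokens, capped at `n`).
#' @export
#' @examples
#' tokenize_and_pad("I am fine", n = 5)
tokenize_and_pad <- function(text, n, polarity_map = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("sequence length n must be >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(polarity_map)) text <- substitute_emojis(text, polarity_map)
  toks <- tokenize_text(filter_chars(text))[[1]]
  n_i <- min(length(toks), n)
  toks <- if (length(toks) >= n) toks[seq_len(n)] else
    c(toks, rep(PAD_TOKEN, n - length(toks)))
  list(tokens = toks, n_i = n_i)
}

#' Preprocess a corpus into padded token sequences
#'
#' Runs the full pipeline on every post: link replacement, emoji polarity
#' substitution, character filtering, tokenization, padding/truncation to
#' `n` tokens.  When `polarity_map` is `NULL` it is derived from the labeled
#' posts of this corpus via [assign_emoji_polarity()]; pass a map computed on
#' the training corpus when preprocessing held-out data.
#'
#' @param corpus Corpus data frame (see [corpus_io]).
#' @param n Sequence length (default 100).
#' @param polarity_map Optional precomputed emoji polarity map.
#' @param emoticons ASCII emoticons treated as emojis.
#' @return A `tokenized_corpus`: list with `ids`, `labels` (factor, `NA` for
#'   unlabeled), `tokens` (character matrix, posts x n), `n_i` (integer
#'   vector), `n`, and the `polarity_map` used.
#' @export
preprocess_corpus <- function(corpus, n = 100L, polarity_map = NULL,
                              emoticons = character()) {
  corpus <- validate_corpus(corpus)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("sequence length n must be >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  text <- replace_links(corpus$text)
  if (is.null(polarity_map)) {
    polarity_map <- if (all(is.na(corpus$label))) stats::setNames(character(), character())
                    else assign_emoji_polarity(corpus, emoticons)
  }
  text <- substitute_emojis(text, polarity_map)
  toks <- tokenize_text(filter_chars(text))
  n_i <- pmin(lengths(toks), n)
  mat <- matrix(PAD_TOKEN, nrow = nrow(corpus), ncol = n)
  for (i in seq_along(toks)) {
    k <- n_i[i]
    if (k > 0L) mat[i, seq_len(k)] <- toks[[i]][seq_len(k)]
  }
  structure(list(ids = corpus$id, labels = as_triage_factor(corpus$label),
                 tokens = mat, n_i = as.integer(n_i), n = n,
                 polarity_map = polarity_map),
            class = "tokenized_corpus")
}

#' @export
print.tokenized_corpus <- function(x, ...) {
  cat(sprintf("<tokenized_corpus> %d posts, n = %d (median true length %d)\n",
              length(x$ids), x$n, as.integer(stats::median(x$n_i))))
  if (!all(is.na(x$labels))) print(table(x$labels, useNA = "ifany"))
  invisible(x)
}

# Subset a tokenized corpus by post index.
subset_tokenized <- function(tc, idx) {
  structure(list(ids = tc$ids[idx], labels = tc$labels[idx],
                 tokens = tc$tokens[idx, , drop = FALSE],
                 n_i = tc$n_i[idx], n = tc$n, polarity_map = tc$polarity_map),
            class = "tokenized_corpus")
}
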