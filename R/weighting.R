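#' Per-category word-class frequencies
#'
#' For every semantic word class `l` and triage category `c`, computes
#' `TF(l, c)`: the fraction of non-pad tokens in category-`c` posts that
#' match class `l`.  A token matching several classes counts once for each;
#' pad tokens are excluded from both numerator and denominator.
#'
#' @param corpus A `tokenized_corpus` from [preprocess_corpus()]; every post
#'   must be labeled.
#' @param lexicon A [liwc_lexicon()].  Classes flagged non-semantic via
#'   [mark_descriptive()] are excluded.
#' @return A `class_frequency_table`: list with `tf` (matrix, classes x 4
#'   categories, values in `[0, 1]`), `classes` (data.frame of the semantic
#'   classes), `categories` and `token_totals` (non-pad token count per
#'   category).
#' @export
compute_class_frequencies <- function(corpus, lexicon) {
  stopifnot(inherits(corpus, "tokenized_corpus"),
            inherits(lexicon, "liwc_lexicon"))
  if (length(corpus$ids) == 0L || all(is.na(corpus$labels))) {
    stop("class frequencies need a labeled, non-empty corpus", call. = FALSE)
  }
  if (anyNA(corpus$labels)) {
    stop("every post must be labeled for class-frequency computation",
         call. = FALSE)
  }
  classes <- lexicon$classes[lexicon$classes$semantic, , drop = FALSE]
  cats <- triage_levels()
  L <- nrow(classes)

  tokmat <- corpus$tokens
  nonpad <- tokmat != PAD_TOKEN
  # category of every token occurrence (recycled down columns by row)
  tok_cat <- matrix(as.integer(corpus$labels), nrow = nrow(tokmat),
                    ncol = ncol(tokmat))
  toks <- tokmat[nonpad]
  cat_of <- tok_cat[nonpad]

  uniq <- unique(toks)
  hit <- match_tokens(lexicon, uniq)
  # occurrence counts of each unique token per category
  cnt <- matrix(0, nrow = length(uniq), ncol = 4L)
  tab <- table(factor(toks, levels = uniq), factor(cat_of, levels = 1:4))
  cnt[] <- as.numeric(tab)

  # unique-token x class membership incidence, then counts by matrix product
  memb <- matrix(0, nrow = length(uniq), ncol = L)
  if (L > 0L) {
    for (i in seq_along(uniq)) {
      at <- match(hit[[i]], classes$id)
      at <- at[!is.na(at)]
      if (length(at)) memb[i, at] <- 1
    }
  }
  tf <- t(memb) %*% cnt
  dimnames(tf) <- list(classes$name, cats)
  totals <- colSums(cnt)
  empty <- totals == 0
  if (any(empty)) {
    warning(sprintf("categor%s with zero tokens: %s",
                    if (sum(empty) > 1) "ies" else "y",
                    paste(cats[empty], collapse = ", ")), call. = FALSE)
  }
  tf <- sweep(tf, 2, pmax(totals, 1), "/")
  structure(list(tf = tf, classes = classes, categories = cats,
                 token_totals = stats::setNames(totals, cats)),
            class = "class_frequency_table")
}

#' Word-class discriminability ranking
#'
#' Normalizes every class's frequency row by its peak over the four
#' categories, `TF'(l, c) = TF(l, c) / max_c TF(l, c)`, and scores each class
#' by the spread of the normalized row:
#' `delta_l = sqrt(sum_c (TF'(l, c) - mu_l)^2)` with `mu_l` the mean of the
#' four normalized values.  (The sum of squared deviations is deliberately
#' not divided by the category count; dividing would rescale every `delta_l`
#' by the same factor, leaving the ranking unchanged but altering the
#' attention weights downstream.)  The `k` classes with the largest `delta`
#' are selected as linguistic features; ties break by ascending class id.
#' Classes absent from the corpus (all-zero rows) have undefined spread and
#' are never selected; their `delta` is reported as 0.
#'
#' @param freq A `class_frequency_table` from [compute_class_frequencies()].
#' @param k Number of classes to select (>= 1).  Values larger than the
#'   number of eligible classes select all of them with a warning.
#' @return A `class_discriminability`: list with `tf_norm`, `mu`, `sd`
#'   (named by class), `selected` (integer class ids, ranked by descending
#'   `delta`), `k`, and `classes`.
#' @export
discriminability <- function(freq, k) {
  stopifnot(inherits(freq, "class_frequency_table"))
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("k must be a single integer >= 1", call. = FALSE)
  }
  k <- as.integer(k)
  tf <- freq$tf
  peak <- apply(tf, 1, max)
  nonzero <- peak > 0
  tfn <- tf
  tfn[nonzero, ] <- tf[nonzero, , drop = FALSE] / peak[nonzero]
  mu <- rowMeans(tfn)
  sd <- sqrt(rowSums((tfn - mu)^2))
  sd[!nonzero] <- 0
  mu[!nonzero] <- 0

  ids <- freq$classes$id
  eligible <- which(nonzero)
  if (k > length(eligible)) {
    warning(sprintf("k = %d exceeds the %d classes present in the corpus; selecting all",
                    k, length(eligible)), call. = FALSE)
    k <- max(length(eligible), 0L)
  }
  ord <- eligible[order(-sd[eligible], ids[eligible])]
  selected <- ids[ord[seq_len(min(k, length(ord)))]]
  structure(list(tf_norm = tfn, mu = stats::setNames(mu, rownames(tf)),
                 sd = stats::setNames(sd, rownames(tf)),
                 selected = selected, k = k, classes = freq$classes),
            class = "class_discriminability")
}

#' @export
print.class_discriminability <- function(x, ...) {
  cat(sprintf("<class_discriminability> %d classes, %d selected (k = %d)\n",
              length(x$sd), length(x$selected), x$k))
  sel <- x$classes$name[match(x$selected, x$classes$id)]
  cat("top classes:", paste(utils::head(sel, 10), collapse = ", "), "\n")
  invisible(x)
}

# delta values of the selected classes, named by class id.
selected_deltas <- function(disc) {
  idx <- match(disc$selected, disc$classes$id)
  stats::setNames(disc$sd[idx], disc$selected)
}

#' Per-word attention weights
#'
#' A token whose matched classes intersect the selected set receives
#' `a = exp(delta*) / sum(exp(delta_selected)) + 1`, where `delta*` is the
#' largest `delta` among the token's selected classes (max rule for
#' multi-class words).  Tokens matching no selected class -- including
#' out-of-lexicon tokens and the reserved markers -- receive weight exactly
#' 1.  Weights therefore lie in `[1, 2)`, with 1 attained exactly by
#' unmatched tokens.
#'
#' @param lexicon A [liwc_lexicon()].
#' @param disc A `class_discriminability` from [discriminability()].
#' @param vocabulary Character vector of tokens to weight.
#' @return A `word_weight_table`: named numeric vector of weights over
#'   `vocabulary`.
#' @export
word_weights <- function(lexicon, disc, vocabulary) {
  stopifnot(inherits(lexicon, "liwc_lexicon"),
            inherits(disc, "class_discriminability"))
  if (length(disc$selected) == 0L) {
    stop("no selected classes: cannot derive word weights", call. = FALSE)
  }
  deltas <- selected_deltas(disc)
  denom <- sum(exp(deltas))
  uniq <- unique(vocabulary)
  hits <- match_tokens(lexicon, uniq)
  w_uniq <- vapply(hits, function(ids) {
    d <- deltas[as.character(intersect(ids, disc$selected))]
    if (length(d) == 0L) 1 else exp(max(d)) / denom + 1
  }, 0)
  structure(stats::setNames(w_uniq[match(vocabulary, uniq)], vocabulary),
            class = "word_weight_table")
}

#' @export
print.word_weight_table <- function(x, ...) {
  cat(sprintf("<word_weight_table> %d tokens, %d weighted above 1 (max %.5f)\n",
              length(x), sum(x > 1), if (length(x)) max(x) else NA_real_))
  invisible(x)
}

#' Per-post linguistic feature vector
#'
#' `LGF(l, p) = (1 / n_i) * sum_j 1_l(t_j)`: the fraction of the post's
#' non-pad tokens matching selected class `l`.  Posts with no tokens yield
#' the all-zero vector with a warning.
#'
#' @param corpus A `tokenized_corpus`.
#' @param lexicon A [liwc_lexicon()].
#' @param disc A `class_discriminability`.
#' @return Numeric matrix, posts x selected classes (columns named by class
#'   name, in ranked order), values in `[0, 1]`.
#' @export
lgf_features <- function(corpus, lexicon, disc) {
  stopifnot(inherits(corpus, "tokenized_corpus"),
            inherits(disc, "class_discriminability"))
  sel <- disc$selected
  selnames <- disc$classes$name[match(sel, disc$classes$id)]
  npost <- length(corpus$ids)
  out <- matrix(0, nrow = npost, ncol = length(sel),
                dimnames = list(corpus$ids, selnames))
  if (any(corpus$n_i == 0L)) {
    warning("post(s) with zero tokens yield all-zero linguistic features",
            call. = FALSE)
  }
  uniq <- unique(as.vector(corpus$tokens))
  hits <- match_tokens(lexicon, uniq)
  # unique-token x selected-class membership
  memb <- matrix(0, nrow = length(uniq), ncol = length(sel))
  for (i in seq_along(uniq)) {
    hit <- intersect(hits[[i]], sel)
    if (length(hit)) memb[i, match(hit, sel)] <- 1
  }
  tokidx <- matrix(match(corpus$tokens, uniq), nrow = npost)
  for (p in seq_len(npost)) {
    k <- corpus$n_i[p]
    if (k == 0L) next
    rows <- tokidx[p, seq_len(k)]
    out[p, ] <- colSums(memb[rows, , drop = FALSE]) / k
  }
  out
}

#' Export the discriminability ranking as TSV
#'
#' One row per semantic class: name, raw `TF` per category, `delta`, and the
#' selected flag, sorted by descending `delta`.
#'
#' @param freq A `class_frequency_table`.
#' @param disc The matching `class_discriminability`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_discriminability_tsv <- function(freq, disc, path) {
  df <- data.frame(class_id = disc$classes$id, class_name = disc$classes$name,
                   freq$tf, delta = unname(disc$sd),
                   selected = disc$classes$id %in% disc$selected,
                   check.names = FALSE)
  df <- df[order(-df$delta, df$class_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
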