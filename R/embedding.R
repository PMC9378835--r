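#' Embedding matrices
#'
#' An `embedding_matrix` is a list with `vocab` (ordered token vector,
#' reserved markers included), `vectors` (numeric matrix, `|V| x d`, rows
#' named by token) and `d`.  Tokens absent from the vocabulary are looked up
#' as the reserved `UNK` row.
#'
#' @name embedding_matrix
NULL

new_embedding <- function(vocab, vectors) {
  stopifnot(length(vocab) == nrow(vectors), all(is.finite(vectors)))
  rownames(vectors) <- vocab
  structure(list(vocab = vocab, vectors = vectors, d = ncol(vectors)),
            class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d tokens x %d dims\n", length(x$vocab), x$d))
  invisible(x)
}

# Vocabulary of a tokenized corpus: reserved markers first, then corpus
# tokens by decreasing frequency (ties alphabetical) for a stable order.
corpus_vocabulary <- function(corpus) {
  toks <- corpus$tokens[corpus$tokens != PAD_TOKEN]
  tab <- sort(table(toks), decreasing = TRUE)
  nm <- names(tab)[order(-as.integer(tab), names(tab))]
  c(unname(reserved_tokens()), setdiff(nm, reserved_tokens()))
}

#' Random Gaussian embeddings
#'
#' Initializes every vocabulary row with i.i.d. `Normal(0, 1)` entries: the
#' word-vector matrix of the traditional-CNN baseline.
#'
#' @param vocabulary Character vector of tokens (reserved markers are added
#'   if missing).
#' @param d Embedding dimension (>= 1).
#' @param seed Integer seed; the same seed reproduces the same matrix.
#' @return An `embedding_matrix`.
#' @export
random_gaussian_embeddings <- function(vocabulary, d, seed) {
  stopifnot(d >= 1)
  vocab <- c(setdiff(unname(reserved_tokens()), vocabulary), vocabulary)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  new_embedding(vocab, matrix(stats::rnorm(length(vocab) * d),
                              nrow = length(vocab), ncol = as.integer(d)))
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Train skip-gram word embeddings on a corpus
#'
#' A native skip-gram trainer with negative sampling: for every (center,
#' context) pair within the window, the center's input vector and the
#' context's output vector are pushed together while vectors of negative
#' samples (drawn from the unigram distribution raised to 3/4) are pushed
#' apart.  Updates are applied in aggregated mini-batches with a linearly
#' decaying learning rate.  Training is single-threaded and fully
#' deterministic given `seed`.
#'
#' Tokens occurring fewer than `min_count` times fall back to seeded
#' Gaussian rows, as do the reserved markers absent from the corpus.
#'
#' @param corpus A `tokenized_corpus` (pad tokens are skipped).
#' @param d Embedding dimension (>= 2).
#' @param seed Integer seed.
#' @param window Maximum context offset (default 5).
#' @param epochs Passes over the corpus (default 5).
#' @param negative Negative samples per pair (default 5).
#' @param lr Initial learning rate (default 0.025).
#' @param min_count Frequency floor below which tokens keep their Gaussian
#'   initialization (default 1 = train every token).
#' @param batch Pairs per aggregated update (default 1024).
#' @return An `embedding_matrix` (the input vectors).
#' @export
train_word2vec <- function(corpus, d, seed, window = 5L, epochs = 5L,
                           negative = 5L, lr = 0.025, min_count = 1L,
                           batch = 1024L) {
  stopifnot(inherits(corpus, "tokenized_corpus"), d >= 2)
  if (length(corpus$ids) == 0L) stop("empty corpus", call. = FALSE)
  d <- as.integer(d)
  vocab <- corpus_vocabulary(corpus)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  E_in <- matrix(stats::rnorm(length(vocab) * d) / d, length(vocab), d)
  E_out <- matrix(0, length(vocab), d)

  # sentences as vocab-id sequences
  sent <- lapply(seq_along(corpus$ids), function(i) {
    k <- corpus$n_i[i]
    if (k == 0L) return(integer())
    match(corpus$tokens[i, seq_len(k)], vocab)
  })
  freq <- tabulate(unlist(sent, use.names = FALSE), nbins = length(vocab))
  trainable <- freq >= min_count

  # (center, context) pairs within the fixed symmetric window
  centers <- integer(); contexts <- integer()
  pair_chunks <- lapply(sent, function(s) {
    n <- length(s)
    if (n < 2L) return(NULL)
    off <- seq_len(min(window, n - 1L))
    ctr <- unlist(lapply(off, function(o) s[seq_len(n - o)]), use.names = FALSE)
    ctx <- unlist(lapply(off, function(o) s[(1L + o):n]), use.names = FALSE)
    # symmetric: each pair in both directions
    cbind(c(ctr, ctx), c(ctx, ctr))
  })
  pairs <- do.call(rbind, pair_chunks)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    warning("corpus has no co-occurrence pairs; returning Gaussian vectors",
            call. = FALSE)
    return(new_embedding(vocab, matrix(stats::rnorm(length(vocab) * d),
                                       length(vocab), d)))
  }
  keep <- trainable[pairs[, 1]] & trainable[pairs[, 2]]
  pairs <- pairs[keep, , drop = FALSE]

  # negative-sampling table: unigram^(3/4)
  pneg <- freq^0.75
  pneg[!trainable] <- 0
  cum <- cumsum(pneg / sum(pneg))

  npair <- nrow(pairs)
  total_steps <- epochs * npair
  done <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(npair)
    for (start in seq(1L, npair, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, npair)]
      B <- length(idx)
      ctr <- pairs[idx, 1]; ctx <- pairs[idx, 2]
      neg <- findInterval(stats::runif(B * negative), cum) + 1L
      step <- lr * max(1e-4, 1 - done / total_steps)

      ctr_rep <- c(ctr, rep(ctr, negative))
      out_ids <- c(ctx, neg)
      lab <- c(rep(1, B), rep(0, B * negative))
      Vin <- E_in[ctr_rep, , drop = FALSE]
      Vout <- E_out[out_ids, , drop = FALSE]
      g <- (lab - stats::plogis(rowSums(Vin * Vout))) * step
      dIn <- rowsum(g * Vout, ctr_rep)
      dOut <- rowsum(g * Vin, out_ids)
      rin <- as.integer(rownames(dIn)); rout <- as.integer(rownames(dOut))
      E_in[rin, ] <- E_in[rin, ] + dIn
      E_out[rout, ] <- E_out[rout, ] + dOut
      done <- done + B
    }
  }
  # frequency-floor fallback: untouched tokens get Gaussian rows
  if (any(!trainable)) {
    E_in[!trainable, ] <- stats::rnorm(sum(!trainable) * d)
  }
  new_embedding(vocab, E_in)
}

#' Look up the word-vector matrix of a token sequence
#'
#' Row `j` of the result is the vocabulary row of token `j`; tokens absent
#' from the vocabulary map to the reserved `UNK` row.
#'
#' @param emb An `embedding_matrix`.
#' @param tokens Character vector of tokens.
#' @return Numeric matrix, `length(tokens) x d`.
#' @export
embedding_lookup <- function(emb, tokens) {
  stopifnot(inherits(emb, "embedding_matrix"))
  idx <- match(tokens, emb$vocab)
  idx[is.na(idx)] <- match(UNK_TOKEN, emb$vocab)
  out <- emb$vectors[idx, , drop = FALSE]
  rownames(out) <- tokens
  out
}

#' Read and write embeddings in word2vec text format
#'
#' The format is a header line `"<count> <dim>"` followed by one
#' `"token v1 ... vd"` line per token.
#'
#' @param path File path.
#' @return `read_word2vec`: an `embedding_matrix`.  `write_word2vec`:
#'   `path`, invisibly.
#' @name word2vec_io
NULL

#' @rdname word2vec_io
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr)) {
    stop(sprintf("%s: malformed word2vec header", path), call. = FALSE)
  }
  parts <- strsplit(lines[-1][seq_len(hdr[1])], " ", fixed = TRUE)
  vocab <- vapply(parts, `[[`, "", 1L)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  new_embedding(vocab, vec)
}

#' @rdname word2vec_io
#' @param emb An `embedding_matrix`.
#' @export
write_word2vec <- function(emb, path) {
  stopifnot(inherits(emb, "embedding_matrix"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(emb$vocab), emb$d), con)
  body <- vapply(seq_along(emb$vocab), function(i) {
    paste(c(emb$vocab[i], format(emb$vectors[i, ], digits = 17,
                                 scientific = FALSE, trim = TRUE)),
          collapse = " ")
  }, "")
  writeLines(body, con)
  invisible(path)
}
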