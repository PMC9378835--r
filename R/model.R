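#' Initialize attention-CNN parameters
#'
#' Per window size `h` in `H`: a kernel matrix `W[[h]]` of shape
#' `(h * d) x m` (each column one filter, small Gaussian init) and a zero
#' bias vector of length `m`; a dense layer `V` (`4 x K`, `K = |H| * m`)
#' and zero dense bias.  The convolution activation is the logistic sigmoid
#' and the feature maps are max-pooled over positions before the dense
#' softmax layer.
#'
#' @param d Embedding dimension.
#' @param H Integer vector of window sizes (default `c(2, 3, 5, 7)`).
#' @param m Filters per window size (default 48).
#' @param seed Integer seed for the Gaussian initialization.
#' @param init_sd SD of the initial weights (default 0.1).
#' @return A `cnn_params` list with `W`, `b`, `V`, `vb`, `H`, `m`, `d`.
#' @export
init_cnn_params <- function(d, H = c(2L, 3L, 5L, 7L), m = 48L, seed = 1L,
                            init_sd = 0.1) {
  stopifnot(length(H) >= 1L, all(H >= 1L), m >= 1L, d >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  H <- as.integer(H); m <- as.integer(m); d <- as.integer(d)
  W <- lapply(H, function(h) matrix(stats::rnorm(h * d * m, sd = init_sd),
                                    nrow = h * d, ncol = m))
  b <- lapply(H, function(h) numeric(m))
  K <- length(H) * m
  structure(list(W = stats::setNames(W, paste0("h", H)),
                 b = stats::setNames(b, paste0("h", H)),
                 V = matrix(stats::rnorm(4L * K, sd = init_sd), 4L, K),
                 vb = numeric(4L), H = H, m = m, d = d),
            class = "cnn_params")
}

# Dense-only parameters for the averaged-embedding baseline.
init_dense_params <- function(d, seed = 1L, init_sd = 0.1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  structure(list(V = matrix(stats::rnorm(4L * d, sd = init_sd), 4L, d),
                 vb = numeric(4L), d = as.integer(d)),
            class = "dense_params")
}

#' Scale word vectors by attention weights
#'
#' Builds the weighted matrix `M` whose row `i` is `a_i` times row `i` of
#' `X`.  With all weights 1 (an out-of-lexicon-only post) `M` equals `X`.
#'
#' @param X Numeric matrix `n x d` of word vectors.
#' @param a Numeric vector of length `n` of per-token weights.
#' @return The weighted matrix `M`.
#' @export
attention_weight <- function(X, a) {
  if (!is.matrix(X) || length(a) != nrow(X)) {
    stop("a must have one weight per row of X", call. = FALSE)
  }
  X * as.numeric(a)
}

# Unfold M (n x d) into sliding windows of h rows: (n - h + 1) x (h * d).
unfold_windows <- function(M, h) {
  n <- nrow(M); P <- n - h + 1L
  do.call(cbind, lapply(seq_len(h), function(t) M[t:(t + P - 1L), , drop = FALSE]))
}

#' Convolution feature maps for one window size
#'
#' Each filter slides a window of `h` rows over the weighted word-vector
#' matrix: position `j` of filter `f` is
#' `sigmoid(<w_f, M[j:(j+h-1), ]> + b_f)` with the logistic sigmoid as
#' activation.
#'
#' @param M Numeric matrix `n x d`.
#' @param W Kernel matrix `(h * d) x m`.
#' @param b Bias vector of length `m`.
#' @param h Window size (requires `n >= h`).
#' @return Feature-map matrix `(n - h + 1) x m`.
#' @export
conv_features <- function(M, W, b, h) {
  if (nrow(M) < h) {
    warning(sprintf("post of length %d shorter than window %d: window skipped",
                    nrow(M), h), call. = FALSE)
    return(NULL)
  }
  U <- unfold_windows(M, h)
  stats::plogis(sweep(U %*% W, 2L, b, "+"))
}

#' Max-over-time pooling
#'
#' One value per filter: the maximum activation over all positions of its
#' feature map, concatenated across window sizes in fixed (window, filter)
#' order.
#'
#' @param maps List of feature-map matrices (positions x filters); `NULL`
#'   entries (skipped windows) are dropped.
#' @return Numeric vector of pooled activations.
#' @export
max_pool <- function(maps) {
  maps <- Filter(Negate(is.null), maps)
  if (length(maps) == 0L) {
    stop("post shorter than every convolution window: nothing to pool",
         call. = FALSE)
  }
  unlist(lapply(maps, function(S) apply(S, 2L, max)), use.names = FALSE)
}

softmax <- function(z) {
  if (is.matrix(z)) {
    z <- z - apply(z, 1L, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    e <- exp(z - max(z))
    e / sum(e)
  }
}

#' Forward pass of the attention CNN for one post
#'
#' lookup -> attention weighting -> per-window convolution -> max pooling ->
#' dense softmax.  Dropout is an inference no-op.  Tokens absent from the
#' embedding vocabulary map to the reserved `UNK` row; pad tokens keep
#' weight 1.
#'
#' @param tokens Character vector: the post's padded token sequence (or a
#'   list as returned by [tokenize_and_pad()]).
#' @param emb An `embedding_matrix`.
#' @param weights A `word_weight_table` (tokens absent from the table get
#'   weight 1).
#' @param params A `cnn_params`.
#' @return Named numeric probability 4-vector over [triage_levels()]
#'   (non-negative, sums to 1).
#' @export
forward_post <- function(tokens, emb, weights, params) {
  stopifnot(inherits(params, "cnn_params"))
  if (is.list(tokens)) tokens <- tokens$tokens
  X <- embedding_lookup(emb, tokens)
  a <- token_weights(weights, tokens)
  M <- attention_weight(X, a)
  maps <- lapply(seq_along(params$H), function(i) {
    conv_features(M, params$W[[i]], params$b[[i]], params$H[i])
  })
  Fvec <- max_pool(maps)
  stats::setNames(softmax(as.numeric(params$V %*% Fvec + params$vb)),
                  triage_levels())
}

# Weight lookup with default 1 for tokens missing from the table.
token_weights <- function(weights, tokens) {
  if (is.null(weights)) return(rep(1, length(tokens)))
  a <- unclass(weights)[tokens]
  a[is.na(a)] <- 1
  unname(a)
}

#' Forward pass of the comparison baselines
#'
#' `fasttext_avg`: the post's non-pad word vectors are averaged and fed to a
#' dense softmax layer (`params` must be a dense parameter list with
#' `V` of shape `4 x d`).  `cnn_random` / `cnn_word2vec`: the convolutional
#' forward pass with every attention weight forced to 1 (the two variants
#' differ only in how `emb` was built).
#'
#' @param tokens Padded token sequence (or [tokenize_and_pad()] output).
#' @param emb An `embedding_matrix`.
#' @param params A `cnn_params` (CNN variants) or dense parameter list
#'   (`fasttext_avg`).
#' @param variant One of `"fasttext_avg"`, `"cnn_random"`, `"cnn_word2vec"`.
#' @return Named probability 4-vector.
#' @export
baseline_forward <- function(tokens, emb, params,
                             variant = c("fasttext_avg", "cnn_random",
                                         "cnn_word2vec")) {
  variant <- match.arg(variant)
  if (is.list(tokens)) tokens <- tokens$tokens
  if (variant == "fasttext_avg") {
    nonpad <- tokens != PAD_TOKEN
    X <- embedding_lookup(emb, tokens[nonpad])
    Fvec <- if (nrow(X) == 0L) numeric(params$d) else colMeans(X)
    return(stats::setNames(softmax(as.numeric(params$V %*% Fvec + params$vb)),
                           triage_levels()))
  }
  forward_post(tokens, emb, weights = NULL, params = params)
}

#' Predict triage categories for a corpus
#'
#' Batched forward pass of a trained model (see [train_liwcnn()]) with
#' dropout disabled.
#'
#' @param object A `liwcnn_model`.
#' @param corpus A `tokenized_corpus` preprocessed with the model's sequence
#'   length (its `polarity_map` should be the model's).
#' @param ... Unused.
#' @return List with `labels` (factor of predicted categories) and `probs`
#'   (matrix, posts x 4).
#' @export
predict.liwcnn_model <- function(object, corpus, ...) {
  stopifnot(inherits(corpus, "tokenized_corpus"))
  if (corpus$n != object$config$n) {
    stop(sprintf("corpus preprocessed with n = %d but model expects n = %d",
                 corpus$n, object$config$n), call. = FALSE)
  }
  Tid <- token_id_matrix(corpus, object$emb$vocab)
  probs <- model_forward_ids(Tid, object, dropout_mask = NULL)$probs
  rownames(probs) <- corpus$ids
  colnames(probs) <- triage_levels()
  list(labels = factor(triage_levels()[max.col(probs, ties.method = "first")],
                       levels = triage_levels()),
       probs = probs)
}

# Map a tokenized corpus to vocab ids (missing tokens -> UNK).
token_id_matrix <- function(corpus, vocab) {
  idx <- match(corpus$tokens, vocab)
  idx[is.na(idx)] <- match(UNK_TOKEN, vocab)
  matrix(idx, nrow = nrow(corpus$tokens), ncol = ncol(corpus$tokens))
}

#' Save or load a model checkpoint
#'
#' A checkpoint is a single self-describing RDS archive holding the
#' parameters, vocabulary, embedding matrix, word-weight table, training
#' history and configuration, with a `version` field.
#'
#' @param model A `liwcnn_model`.
#' @param path File path.
#' @return `save_checkpoint`: `path`, invisibly. `load_checkpoint`: the
#'   model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "liwcnn_model"))
  saveRDS(model, path, version = 3L)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "liwcnn_model") || is.null(model$version)) {
    stop(sprintf("%s is not a liwcnn checkpoint", path), call. = FALSE)
  }
  model
}

#' @export
print.liwcnn_model <- function(x, ...) {
  cat(sprintf("<liwcnn_model> variant = %s, d = %d, n = %d, selected iteration %d\n",
              x$variant, x$config$d, x$config$n, x$best_iteration))
  if (!is.null(x$history) && nrow(x$history) > 0L) {
    i <- which(x$history$iteration == x$best_iteration)
    cat(sprintf("validation accuracy at selection: %.4f\n",
                x$history$val_acc[i][1]))
  }
  invisible(x)
}
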