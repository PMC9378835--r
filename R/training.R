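#' Training configuration
#'
#' Defaults follow the model's standard hyper-parameters: 128-dimensional
#' word vectors, learning rate 0.001 (Adam), window sizes `{2, 3, 5, 7}`,
#' 48 filters per window, batch size 50, dropout 0.1 on the pooled vector,
#' L2 coefficient 0.1 on kernel and dense weights, top-k = 28 word classes
#' and sequence length `n = 100`.  `max_iterations` counts mini-batch steps;
#' the returned model is the parameter snapshot at the validation-accuracy
#' peak (see [select_best_iteration()]).
#'
#' @param d Word-vector dimension.
#' @param learning_rate Adam learning rate.
#' @param H Convolution window sizes.
#' @param batch_size Posts per mini-batch.
#' @param dropout Dropout rate on the pooled vector, in `[0, 1)`.
#' @param kernels_per_window Filters per window size.
#' @param lambda L2 regularization coefficient (>= 0).
#' @param max_iterations Total mini-batch steps.
#' @param eval_every Record history (and validation accuracy) every this
#'   many iterations.
#' @param k Word classes selected by [discriminability()].
#' @param n Sequence length for preprocessing.
#' @param seed Master seed; every random choice in training derives from it.
#' @param variant One of `"liwc_cnn"`, `"cnn_random"`, `"cnn_word2vec"`,
#'   `"fasttext_avg"`.
#' @param val_fraction Share of the corpus held out for validation
#'   (default 0.1, i.e. a 90/10 split).
#' @param update_embeddings Fine-tune embeddings during training (default
#'   `TRUE`); the PAD row stays frozen at zero either way.
#' @param w2v_epochs,w2v_window,w2v_negative Skip-gram training options for
#'   the word2vec-initialized variants.
#' @param emoticons ASCII emoticons treated as emojis in preprocessing.
#' @return A `train_config` list.
#' @export
train_config <- function(d = 128L, learning_rate = 0.001,
                         H = c(2L, 3L, 5L, 7L), batch_size = 50L,
                         dropout = 0.1, kernels_per_window = 48L,
                         lambda = 0.1, max_iterations = 600L,
                         eval_every = 20L, k = 28L, n = 100L, seed = 1L,
                         variant = c("liwc_cnn", "cnn_random",
                                     "cnn_word2vec", "fasttext_avg"),
                         val_fraction = 0.1, update_embeddings = TRUE,
                         w2v_epochs = 5L, w2v_window = 5L, w2v_negative = 5L,
                         emoticons = character()) {
  variant <- match.arg(variant)
  cfg <- list(d = as.integer(d), learning_rate = learning_rate,
              H = as.integer(H), batch_size = as.integer(batch_size),
              dropout = dropout,
              kernels_per_window = as.integer(kernels_per_window),
              lambda = lambda, max_iterations = as.integer(max_iterations),
              eval_every = as.integer(eval_every), k = as.integer(k),
              n = as.integer(n), seed = as.integer(seed), variant = variant,
              val_fraction = val_fraction,
              update_embeddings = isTRUE(update_embeddings),
              w2v_epochs = as.integer(w2v_epochs),
              w2v_window = as.integer(w2v_window),
              w2v_negative = as.integer(w2v_negative),
              emoticons = emoticons)
  with(cfg, stopifnot(d >= 1, learning_rate > 0, all(H >= 1), batch_size >= 1,
                      dropout >= 0, dropout < 1, kernels_per_window >= 1,
                      lambda >= 0, max_iterations >= 1, eval_every >= 1,
                      k >= 1, n >= 1, val_fraction > 0, val_fraction < 1))
  structure(cfg, class = "train_config")
}

#' Reduced-size configuration for synthetic-corpus experiments
#'
#' The standard-sized network is larger than the synthetic corpora need:
#' the demonstration configuration keeps every structural choice (Adam at
#' learning rate 0.001, batch 50, dropout 0.1, lambda 0.1, sigmoid
#' convolution, max pooling, validation-peak selection, 600 iterations) but
#' uses 32-dimensional vectors, windows `{2, 3}` with 16 filters each and
#' sequence length 100, which trains in well under a minute on one CPU and
#' is ample for the planted-signal generator's vocabulary.
#'
#' @param seed Master seed.
#' @param variant Model variant (see [train_config()]).
#' @param ... Overrides passed on to [train_config()].
#' @return A `train_config`.
#' @export
demo_train_config <- function(seed = 1L, variant = "liwc_cnn", ...) {
  args <- list(d = 32L, H = c(2L, 3L), kernels_per_window = 16L,
               max_iterations = 600L, eval_every = 25L, n = 100L,
               seed = seed, variant = variant, w2v_epochs = 3L)
  args[names(list(...))] <- list(...)
  do.call(train_config, args)
}

#' Cross-entropy loss with L2 penalty
#'
#' Mean categorical cross-entropy `-(1/N) sum_i log p_i(gold_i)` plus
#' `(lambda / 2) * (||V||^2 + sum_h ||W_h||^2)`.  Biases and embeddings are
#' excluded from the penalty.  Predicted probabilities at the gold class
#' are clamped at `1e-12` with a warning.
#'
#' @param probs Numeric matrix (posts x 4) of predicted probabilities, or a
#'   single probability 4-vector.
#' @param labels Gold labels (factor or character, 4-way).
#' @param params Optional `cnn_params` or dense parameter list whose
#'   weights enter the penalty.
#' @param lambda L2 coefficient (default 0).
#' @return Non-negative scalar loss.
#' @export
cross_entropy_loss <- function(probs, labels, params = NULL, lambda = 0) {
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1L)
  labels <- as_triage_factor(labels)
  stopifnot(nrow(probs) == length(labels), ncol(probs) == 4L, lambda >= 0)
  p <- probs[cbind(seq_len(nrow(probs)), as.integer(labels))]
  if (any(p < 1e-12)) {
    warning("predicted probability ~0 at the true class; clamped at 1e-12",
            call. = FALSE)
    p <- pmax(p, 1e-12)
  }
  data_term <- -mean(log(p))
  data_term + lambda / 2 * l2_weight_norm(params)
}

l2_weight_norm <- function(params) {
  if (is.null(params)) return(0)
  sum(unlist(lapply(params$W, function(w) sum(w^2)))) + sum(params$V^2)
}

#' Stratified train/validation split
#'
#' Splits a labeled corpus into disjoint train and validation sets whose
#' union is the input, preserving label proportions (within one post per
#' label) and reproducible by seed.
#'
#' @param corpus A labeled corpus data frame or a `tokenized_corpus`.
#' @param fraction Train-set share, in (0, 1) (default 0.9).
#' @param seed Integer seed.
#' @return List with elements `train` and `val` of the same type as the
#'   input.
#' @export
split_train_val <- function(corpus, fraction = 0.9, seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  labels <- if (inherits(corpus, "tokenized_corpus")) corpus$labels
            else as_triage_factor(validate_corpus(corpus)$label)
  if (anyNA(labels)) stop("split requires labeled posts", call. = FALSE)
  counts <- table(labels)
  low <- names(counts)[counts > 0 & counts < 2]
  if (length(low) > 0L) {
    stop(sprintf("label(s) with fewer than 2 posts cannot be stratified: %s",
                 paste(low, collapse = ", ")), call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  # largest-remainder apportionment: per-label counts within one post of
  # fraction * n_label while the total equals round(fraction * N)
  present <- levels(labels)[table(labels) > 0]
  nlab <- vapply(present, function(lv) sum(labels == lv), 0L)
  exact <- fraction * nlab
  ntr <- pmax(1L, pmin(nlab - 1L, floor(exact)))
  target <- round(fraction * length(labels))
  extra <- target - sum(ntr)
  if (extra > 0) {
    ord <- order(-(exact - floor(exact)), seq_along(present))
    ord <- ord[ntr[ord] < nlab[ord] - 1L]
    bump <- utils::head(ord, extra)
    ntr[bump] <- ntr[bump] + 1L
  }
  train_idx <- sort(unlist(lapply(seq_along(present), function(i) {
    idx <- which(labels == present[i])
    sample(idx, ntr[i])
  }), use.names = FALSE))
  val_idx <- setdiff(seq_along(labels), train_idx)
  take <- function(idx) {
    if (inherits(corpus, "tokenized_corpus")) subset_tokenized(corpus, idx)
    else corpus[idx, , drop = FALSE]
  }
  list(train = take(train_idx), val = take(val_idx))
}

#' Select the validation-peak iteration
#'
#' Returns the recorded iteration with maximal validation accuracy; ties
#' resolve to the earliest such iteration.
#'
#' @param history Data frame with columns `iteration` and `val_acc`
#'   (iterations strictly increasing).
#' @return The selected iteration index.
#' @export
select_best_iteration <- function(history) {
  stopifnot(is.data.frame(history), nrow(history) >= 1L,
            all(c("iteration", "val_acc") %in% names(history)))
  history$iteration[which.max(history$val_acc)]
}

## ---- internal batched forward/backward -----------------------------------

# Forward over a batch of vocab-id rows. `model` needs: E (|V| x d), a_vocab
# (weight per vocab row), params, variant, pad_id, n. Returns probs and the
# cache used by model_backward.
model_forward_ids <- function(Tid, model, dropout_mask = NULL) {
  B <- nrow(Tid); n <- ncol(Tid)
  tokvec <- as.vector(t(Tid))                   # post-major
  avec <- model$a_vocab[tokvec]
  Mstack <- model$E[tokvec, , drop = FALSE] * avec

  if (model$variant == "fasttext_avg") {
    npmask <- as.numeric(tokvec != model$pad_id)
    grp <- rep(seq_len(B), each = n)
    n_i <- pmax(rowsum(npmask, grp)[, 1], 1)
    Fmat <- rowsum(Mstack * npmask, grp) / n_i
    Fd <- if (is.null(dropout_mask)) Fmat else Fmat * dropout_mask
    Z <- sweep(Fd %*% t(model$params$V), 2L, model$params$vb, "+")
    probs <- softmax(Z)
    return(list(probs = probs,
                cache = list(B = B, n = n, tokvec = tokvec, avec = avec,
                             npmask = npmask, grp = grp, n_i = n_i,
                             Fmat = Fmat, Fd = Fd,
                             dropout_mask = dropout_mask)))
  }

  params <- model$params
  H <- params$H; m <- params$m
  use <- H <= n
  if (!any(use)) {
    stop(sprintf("sequence length %d shorter than every window size (%s)",
                 n, paste(H, collapse = ", ")), call. = FALSE)
  }
  wins <- vector("list", length(H))
  Fblocks <- vector("list", length(H))
  for (i in which(use)) {
    h <- H[i]; P <- n - h + 1L
    base <- rep((seq_len(B) - 1L) * n, each = P) + rep(seq_len(P), B)
    U <- do.call(cbind, lapply(seq_len(h) - 1L, function(t)
      Mstack[base + t, , drop = FALSE]))
    S <- stats::plogis(sweep(U %*% params$W[[i]], 2L, params$b[[i]], "+"))
    mat <- matrix(S, nrow = P)                  # P x (B*m), b fastest
    amax <- max.col(t(mat), ties.method = "first")
    pooled <- mat[cbind(amax, seq_len(B * m))]
    Fh <- matrix(pooled, nrow = B)              # B x m
    wins[[i]] <- list(U = U, base = base, P = P,
                      amax = matrix(amax, nrow = B), Fh = Fh)
    Fblocks[[i]] <- Fh
  }
  Fmat <- do.call(cbind, Fblocks[use])
  Fd <- if (is.null(dropout_mask)) Fmat else Fmat * dropout_mask
  Z <- sweep(Fd %*% t(params$V), 2L, params$vb, "+")
  probs <- softmax(Z)
  list(probs = probs,
       cache = list(B = B, n = n, tokvec = tokvec, avec = avec,
                    wins = wins, use = use, Fmat = Fmat, Fd = Fd,
                    dropout_mask = dropout_mask))
}

# Analytic gradients of the batch loss (cross-entropy + L2 on V and W).
# Returns loss and gradients for V, vb, W, b and E (dE only when asked).
model_backward <- function(fwd, ylab, model, lambda, want_dE = TRUE) {
  probs <- fwd$probs; cache <- fwd$cache
  B <- cache$B; params <- model$params
  p_true <- probs[cbind(seq_len(B), ylab)]
  clamped <- p_true < 1e-12
  if (any(clamped)) {
    warning("predicted probability ~0 at the true class; clamped at 1e-12",
            call. = FALSE)
    p_true <- pmax(p_true, 1e-12)
  }
  loss <- -mean(log(p_true)) + lambda / 2 * l2_weight_norm(params)

  Y <- matrix(0, B, 4L); Y[cbind(seq_len(B), ylab)] <- 1
  dZ <- (probs - Y) / B
  dV <- t(dZ) %*% cache$Fd + lambda * params$V
  dvb <- colSums(dZ)
  dFd <- dZ %*% params$V
  dF <- if (is.null(cache$dropout_mask)) dFd else dFd * cache$dropout_mask

  d <- ncol(model$E)
  dE <- NULL

  if (model$variant == "fasttext_avg") {
    if (want_dE) {
      dMstack <- (dF / cache$n_i)[cache$grp, , drop = FALSE] * cache$npmask
      dE <- accumulate_dE(dMstack, cache, model)
    }
    return(list(loss = loss, dV = dV, dvb = dvb, dW = NULL, db = NULL,
                dE = dE))
  }

  H <- params$H; m <- params$m
  dW <- lapply(params$W, function(w) w * lambda)
  db <- lapply(params$b, function(bb) bb * 0)
  dMstack <- if (want_dE) matrix(0, length(cache$tokvec), d) else NULL
  col0 <- 0L
  for (i in seq_along(H)) {
    if (!cache$use[i]) next
    win <- cache$wins[[i]]
    dFh <- dF[, col0 + seq_len(m), drop = FALSE]
    col0 <- col0 + m
    s <- win$Fh
    du <- dFh * s * (1 - s)                     # B x m
    db[[i]] <- db[[i]] + colSums(du)
    grow <- win$amax + (seq_len(B) - 1L) * win$P  # U row of each pooled max
    h <- H[i]
    if (want_dE) dUacc <- matrix(0, nrow(win$U), h * d)
    for (f in seq_len(m)) {
      rows <- grow[, f]
      dW[[i]][, f] <- dW[[i]][, f] +
        as.numeric(crossprod(win$U[rows, , drop = FALSE], du[, f]))
      if (want_dE) {
        dUacc[rows, ] <- dUacc[rows, ] +
          tcrossprod(du[, f], params$W[[i]][, f])
      }
    }
    if (want_dE) {
      for (t in seq_len(h) - 1L) {
        rows <- win$base + t
        dMstack[rows, ] <- dMstack[rows, ] +
          dUacc[, t * d + seq_len(d), drop = FALSE]
      }
    }
  }
  if (want_dE) dE <- accumulate_dE(dMstack, cache, model)
  list(loss = loss, dV = dV, dvb = dvb, dW = dW, db = db, dE = dE)
}

# Gradient w.r.t. the embedding rows: chain through the attention weights
# and sum over token occurrences. The PAD row stays frozen at zero.
accumulate_dE <- function(dMstack, cache, model) {
  contrib <- dMstack * cache$avec
  agg <- rowsum(contrib, cache$tokvec)
  dE <- matrix(0, nrow(model$E), ncol(model$E))
  dE[as.integer(rownames(agg)), ] <- agg
  dE[model$pad_id, ] <- 0
  dE
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(x) list(m = x * 0, v = x * 0)

adam_step <- function(x, g, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(x = x - lr * mhat / (sqrt(vhat) + eps), st = st)
}

## ---- training loop ---------------------------------------------------------

#' Train a triage classifier
#'
#' Runs the full pipeline: preprocessing (link replacement, emoji polarity
#' from the training labels, padding to `n`), a stratified 90/10
#' train/validation split, the word-class weighting pipeline (for the
#' `liwc_cnn` variant), embedding construction per variant, then mini-batch
#' Adam on the cross-entropy + L2 loss.  Validation accuracy is recorded
#' every `eval_every` iterations and the returned model carries the
#' parameter snapshot of the validation-accuracy peak (earliest on ties).
#' Fully deterministic given `config$seed`.
#'
#' @param corpus A labeled corpus data frame (see [corpus_io]) or an
#'   already-preprocessed `tokenized_corpus`.
#' @param lexicon A [liwc_lexicon()]; required for variant `"liwc_cnn"`,
#'   ignored otherwise.
#' @param config A [train_config()].
#' @return A `liwcnn_model`: the selected parameters, embedding matrix,
#'   word-weight table, discriminability ranking, emoji polarity map,
#'   config, and the training `history` data frame (columns `iteration`,
#'   `train_loss`, `train_acc`, `val_acc`).
#' @export
train_liwcnn <- function(corpus, lexicon = NULL, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (config$variant == "liwc_cnn" && !inherits(lexicon, "liwc_lexicon")) {
    stop("variant 'liwc_cnn' requires a lexicon", call. = FALSE)
  }
  tc <- if (inherits(corpus, "tokenized_corpus")) corpus
        else preprocess_corpus(corpus, n = config$n,
                               emoticons = config$emoticons)
  if (anyNA(tc$labels)) stop("training requires labeled posts", call. = FALSE)
  if (tc$n != config$n) {
    stop(sprintf("corpus tokenized with n = %d but config$n = %d",
                 tc$n, config$n), call. = FALSE)
  }
  sp <- split_train_val(tc, fraction = 1 - config$val_fraction,
                        seed = config$seed)
  tr <- sp$train; va <- sp$val

  vocab <- corpus_vocabulary(tc)

  # attention weights: computed once, on the training split only
  disc <- NULL
  if (config$variant == "liwc_cnn") {
    freq <- compute_class_frequencies(tr, lexicon)
    disc <- discriminability(freq, config$k)
    wtab <- word_weights(lexicon, disc, vocab)
    a_vocab <- unname(unclass(wtab))
  } else {
    wtab <- structure(stats::setNames(rep(1, length(vocab)), vocab),
                      class = "word_weight_table")
    a_vocab <- rep(1, length(vocab))
  }

  emb <- switch(config$variant,
    liwc_cnn = ,
    fasttext_avg = ,
    cnn_word2vec = train_word2vec(tc, d = config$d, seed = config$seed,
                                  window = config$w2v_window,
                                  epochs = config$w2v_epochs,
                                  negative = config$w2v_negative),
    cnn_random = random_gaussian_embeddings(vocab, config$d, config$seed))
  # align embedding rows to the vocabulary order and freeze PAD at zero
  E <- embedding_lookup(emb, vocab)
  rownames(E) <- vocab
  pad_id <- match(PAD_TOKEN, vocab)
  E[pad_id, ] <- 0

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)

  params <- if (config$variant == "fasttext_avg") {
    init_dense_params(config$d, seed = config$seed + 2L)
  } else {
    H_use <- config$H[config$H <= config$n]
    if (length(H_use) < length(config$H)) {
      warning(sprintf("window size(s) larger than n = %d skipped: %s",
                      config$n,
                      paste(setdiff(config$H, H_use), collapse = ", ")),
              call. = FALSE)
    }
    if (length(H_use) == 0L) {
      stop("every window size exceeds the sequence length", call. = FALSE)
    }
    init_cnn_params(config$d, H = H_use, m = config$kernels_per_window,
                    seed = config$seed + 2L)
  }

  model <- list(E = E, a_vocab = a_vocab, params = params,
                variant = config$variant, pad_id = pad_id)
  Tid_tr <- token_id_matrix(tr, vocab)
  Tid_va <- token_id_matrix(va, vocab)
  y_tr <- as.integer(tr$labels)
  y_va <- as.integer(va$labels)
  ntr <- nrow(Tid_tr)
  K <- if (config$variant == "fasttext_avg") config$d
       else length(params$H) * params$m

  st <- list(V = adam_init(params$V), vb = adam_init(params$vb))
  if (config$variant != "fasttext_avg") {
    st$W <- lapply(params$W, adam_init)
    st$b <- lapply(params$b, adam_init)
  }
  if (config$update_embeddings) st$E <- adam_init(E)

  history <- data.frame(iteration = integer(), train_loss = numeric(),
                        train_acc = numeric(), val_acc = numeric())
  best <- list(val_acc = -Inf, params = params, E = E, iteration = 0L)
  order_pool <- integer()

  for (it in seq_len(config$max_iterations)) {
    if (length(order_pool) < config$batch_size) {
      order_pool <- c(order_pool, sample.int(ntr))
    }
    bidx <- order_pool[seq_len(min(config$batch_size, ntr))]
    order_pool <- order_pool[-seq_len(min(config$batch_size, ntr))]

    mask <- NULL
    if (config$dropout > 0) {
      keep <- matrix(stats::rbinom(length(bidx) * K, 1L,
                                   1 - config$dropout), length(bidx), K)
      mask <- keep / (1 - config$dropout)
    }
    fwd <- model_forward_ids(Tid_tr[bidx, , drop = FALSE], model, mask)
    bk <- model_backward(fwd, y_tr[bidx], model, config$lambda,
                         want_dE = config$update_embeddings)

    lr <- config$learning_rate
    up <- adam_step(model$params$V, bk$dV, st$V, lr, it)
    model$params$V <- up$x; st$V <- up$st
    up <- adam_step(model$params$vb, bk$dvb, st$vb, lr, it)
    model$params$vb <- up$x; st$vb <- up$st
    if (config$variant != "fasttext_avg") {
      for (i in seq_along(model$params$W)) {
        up <- adam_step(model$params$W[[i]], bk$dW[[i]], st$W[[i]], lr, it)
        model$params$W[[i]] <- up$x; st$W[[i]] <- up$st
        up <- adam_step(model$params$b[[i]], bk$db[[i]], st$b[[i]], lr, it)
        model$params$b[[i]] <- up$x; st$b[[i]] <- up$st
      }
    }
    if (config$update_embeddings) {
      up <- adam_step(model$E, bk$dE, st$E, lr, it)
      model$E <- up$x; st$E <- up$st
      model$E[pad_id, ] <- 0
    }
    if (!is.finite(bk$loss)) {
      stop(sprintf("non-finite loss at iteration %d; consider a lower learning rate",
                   it), call. = FALSE)
    }

    if (it %% config$eval_every == 0L || it == config$max_iterations) {
      tr_probs <- fwd$probs
      tr_acc <- mean(max.col(tr_probs, ties.method = "first") == y_tr[bidx])
      va_probs <- model_forward_ids(Tid_va, model, NULL)$probs
      va_acc <- mean(max.col(va_probs, ties.method = "first") == y_va)
      history <- rbind(history,
                       data.frame(iteration = it, train_loss = bk$loss,
                                  train_acc = tr_acc, val_acc = va_acc))
      if (va_acc > best$val_acc) {
        best <- list(val_acc = va_acc, params = model$params, E = model$E,
                     iteration = it)
      }
    }
  }

  emb_final <- new_embedding(vocab, best$E)
  structure(list(version = 1L, variant = config$variant, config = config,
                 emb = emb_final, a_vocab = a_vocab, weight_table = wtab,
                 disc = disc, params = best$params, pad_id = pad_id,
                 polarity_map = tc$polarity_map, history = history,
                 best_iteration = select_best_iteration(history),
                 E = best$E),
            class = "liwcnn_model")
}

## ---- gradient checking -----------------------------------------------------

flatten_params <- function(model, include_embeddings = FALSE) {
  p <- model$params
  v <- c(as.numeric(p$V), p$vb)
  if (!is.null(p$W)) v <- c(v, unlist(p$W), unlist(p$b))
  if (include_embeddings) v <- c(v, as.numeric(model$E))
  v
}

unflatten_params <- function(theta, model, include_embeddings = FALSE) {
  p <- model$params
  at <- 0L
  take <- function(k) {
    out <- theta[at + seq_len(k)]
    at <<- at + k
    out
  }
  p$V <- matrix(take(length(p$V)), nrow(p$V), ncol(p$V))
  p$vb <- take(length(p$vb))
  if (!is.null(p$W)) {
    for (i in seq_along(p$W)) {
      p$W[[i]] <- matrix(take(length(p$W[[i]])), nrow(p$W[[i]]), ncol(p$W[[i]]))
    }
    for (i in seq_along(p$b)) p$b[[i]] <- take(length(p$b[[i]]))
  }
  model$params <- p
  if (include_embeddings) {
    model$E <- matrix(take(length(model$E)), nrow(model$E), ncol(model$E))
  }
  model
}

flatten_grads <- function(bk, model, include_embeddings = FALSE) {
  v <- c(as.numeric(bk$dV), bk$dvb)
  if (!is.null(bk$dW)) v <- c(v, unlist(bk$dW), unlist(bk$db))
  if (include_embeddings) v <- c(v, as.numeric(bk$dE))
  v
}

#' Verify the analytic gradients against finite differences
#'
#' Builds a tiny model (3 tokens per post, 2-dimensional embeddings, one
#' filter of window 2 for the CNN variants), computes the analytic gradient
#' of the batch loss, and compares every coordinate with a central
#' finite-difference estimate.  In double precision the maximum relative
#' error is expected below `1e-4`.
#'
#' @param seed Integer seed for the toy parameters and batch.
#' @param variant `"liwc_cnn"` or `"fasttext_avg"` (the unit-weight CNN
#'   variants share the `liwc_cnn` code path).
#' @param include_embeddings Also check the embedding-row gradients.
#' @param lambda L2 coefficient used in the check (default 0.1 so the
#'   penalty gradient is exercised).
#' @param eps Finite-difference step (default 1e-5).
#' @return List with `max_rel_error`, `n_params`, and the two gradient
#'   vectors.
#' @export
gradient_check <- function(seed = 1L, variant = "liwc_cnn",
                           include_embeddings = FALSE, lambda = 0.1,
                           eps = 1e-5) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  nvocab <- 5L; d <- 2L; n <- 3L; B <- 4L
  E <- matrix(stats::rnorm(nvocab * d, sd = 0.5), nvocab, d)
  E[1L, ] <- 0                                  # PAD row
  a_vocab <- c(1, 1 + stats::runif(nvocab - 1L, 0.1, 0.9))
  params <- if (variant == "fasttext_avg") {
    init_dense_params(d, seed = seed + 1L, init_sd = 0.5)
  } else {
    init_cnn_params(d, H = 2L, m = 1L, seed = seed + 1L, init_sd = 0.5)
  }
  model <- list(E = E, a_vocab = a_vocab, params = params,
                variant = variant, pad_id = 1L)
  Tid <- matrix(sample(2:nvocab, B * n, replace = TRUE), B, n)
  Tid[1L, n] <- 1L                              # one post with padding
  ylab <- sample.int(4L, B, replace = TRUE)

  fwd <- model_forward_ids(Tid, model, NULL)
  bk <- model_backward(fwd, ylab, model, lambda, want_dE = TRUE)
  ga <- flatten_grads(bk, model, include_embeddings)
  # padded-row embedding gradient is frozen; finite differences agree
  theta <- flatten_params(model, include_embeddings)

  loss_at <- function(th) {
    m2 <- unflatten_params(th, model, include_embeddings)
    if (include_embeddings) m2$E[1L, ] <- 0
    f <- model_forward_ids(Tid, m2, NULL)
    model_backward(f, ylab, m2, lambda, want_dE = FALSE)$loss
  }
  gn <- vapply(seq_along(theta), function(j) {
    tp <- theta; tp[j] <- tp[j] + eps
    tm <- theta; tm[j] <- tm[j] - eps
    (loss_at(tp) - loss_at(tm)) / (2 * eps)
  }, 0)
  if (include_embeddings) {
    # coordinates of the frozen PAD row carry zero analytic gradient
    npar <- length(ga) - length(E)
    pad_coords <- npar + (seq_len(ncol(E)) - 1L) * nrow(E) + 1L
    gn[pad_coords] <- 0
  }
  rel <- abs(ga - gn) / pmax(abs(ga) + abs(gn), 1e-8)
  list(max_rel_error = max(rel), n_params = length(theta),
       analytic = ga, numeric = gn)
}
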