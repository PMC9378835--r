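test_that("attention weighting scales rows and is the identity at weight 1", {
  X <- rbind(c(1, 1), c(3, 4))
  expect_identical(attention_weight(X, c(1, 1)), X)
  expect_equal(attention_weight(X, c(2, 1)), rbind(c(2, 2), c(3, 4)))
  # scaling a weight scales only the matched row, linearly
  expect_equal(attention_weight(X, c(3 * 2, 1))[1, ],
               3 * attention_weight(X, c(2, 1))[1, ])
  expect_error(attention_weight(X, c(1, 1, 1)), "one weight per row")
})

test_that("convolution evaluates the sigmoid sliding-window inner product", {
  # zero kernel, zero bias: every position sits at sigmoid(0) = 0.5
  M <- matrix(rnorm(12), 4, 3)
  S0 <- conv_features(M, matrix(0, 6, 2), c(0, 0), 2)
  expect_true(all(S0 == 0.5))
  expect_equal(dim(S0), c(3L, 2L))

  # hand evaluation: n = 3, h = 2, d = 2, w = ((1,0),(0,1)), b = 0
  M2 <- rbind(c(1, 0), c(0, 1), c(2, 0))
  W <- matrix(c(1, 0, 0, 1), 4, 1)   # rows ordered (window row 1, window row 2)
  S <- conv_features(M2, W, 0, 2)
  # position 1: <w, ((1,0),(0,1))> = 2 -> sigmoid(2) = 0.88079...
  expect_equal(S[1, 1], 0.88079, tolerance = 1e-5)
  expect_equal(S[1, 1], 1 / (1 + exp(-2)), tolerance = 1e-12)
  # position 2: <w, ((0,1),(2,0))> = 0 -> sigmoid(0) = 0.5
  expect_equal(S[2, 1], 0.5)

  # output length contract on random shapes
  set.seed(1)
  for (rep in 1:5) {
    n <- sample(3:9, 1); d <- sample(2:4, 1); h <- sample(2:3, 1)
    m <- sample(1:3, 1)
    S <- conv_features(matrix(rnorm(n * d), n, d),
                       matrix(rnorm(h * d * m), h * d, m), rnorm(m), h)
    expect_equal(dim(S), c(n - h + 1L, m))
  }
  expect_warning(out <- conv_features(M2, W, 0, 5), "skipped")
  expect_null(out)
})

test_that("max pooling takes per-filter maxima in fixed order", {
  expect_equal(max_pool(list(matrix(c(0.1, 0.9, 0.4), 3, 1))), 0.9)
  expect_equal(max_pool(list(matrix(0.3, 4, 1))), 0.3)
  M2 <- rbind(c(1, 0), c(0, 1), c(2, 0))
  W <- matrix(c(1, 0, 0, 1), 4, 1)
  expect_equal(max_pool(list(conv_features(M2, W, 0, 2))), 0.88079,
               tolerance = 1e-5)
  # concatenation across windows keeps (window, filter) order
  S1 <- matrix(c(0.2, 0.8, 0.1, 0.4), 2, 2)
  S2 <- matrix(c(0.6, 0.3), 2, 1)
  expect_equal(max_pool(list(S1, S2)), c(0.8, 0.4, 0.6))
  expect_error(max_pool(list(NULL)), "nothing to pool")
})

test_that("the forward pass is a valid softmax and matches hand computation", {
  emb <- random_gaussian_embeddings(c("tok1", "tok2", "tok3"), d = 2, seed = 3)
  params <- init_cnn_params(d = 2, H = 2L, m = 1L, seed = 4)
  w <- structure(stats::setNames(c(1.5, 1.2), c("tok1", "tok2")),
                 class = "word_weight_table")
  y <- forward_post(c("tok1", "tok2", "tok3"), emb, w, params)
  expect_equal(sum(y), 1, tolerance = 1e-9)
  expect_true(all(y >= 0 & y <= 1))
  expect_named(y, triage_levels())

  # independent hand computation of the whole pipeline in scalar R
  X <- rbind(emb$vectors["tok1", ], emb$vectors["tok2", ],
             emb$vectors["tok3", ])
  M <- X * c(1.5, 1.2, 1)
  u1 <- sum(params$W[[1]][, 1] * c(M[1, ], M[2, ])) + params$b[[1]][1]
  u2 <- sum(params$W[[1]][, 1] * c(M[2, ], M[3, ])) + params$b[[1]][1]
  Fv <- max(1 / (1 + exp(-u1)), 1 / (1 + exp(-u2)))
  z <- params$V[, 1] * Fv + params$vb
  expected <- exp(z) / sum(exp(z))
  expect_equal(unname(y), unname(expected), tolerance = 1e-6)

  # uniform dense layer: exact symmetry
  params0 <- params
  params0$V[] <- 0; params0$vb[] <- 0
  y0 <- forward_post(c("tok1", "tok2", "tok3"), emb, w, params0)
  expect_equal(unname(y0), rep(0.25, 4))
})

test_that("unknown tokens route through UNK instead of failing", {
  emb <- random_gaussian_embeddings("known", d = 2, seed = 6)
  params <- init_cnn_params(d = 2, H = 2L, m = 1L, seed = 7)
  y <- forward_post(c("known", "mystery"), emb, NULL, params)
  expect_equal(sum(y), 1, tolerance = 1e-9)
})

test_that("baselines reduce to the documented special cases", {
  emb <- random_gaussian_embeddings(c("tok1", "tok2"), d = 3, seed = 8)
  dense <- liwcnn:::init_dense_params(d = 3, seed = 9)
  # one-token post: fasttext average is that token's vector
  y1 <- baseline_forward(c("tok1", "PAD", "PAD"), emb, dense, "fasttext_avg")
  z <- dense$V %*% emb$vectors["tok1", ] + dense$vb
  expect_equal(unname(y1), unname(as.numeric(exp(z) / sum(exp(z)))),
               tolerance = 1e-12)
  expect_equal(sum(y1), 1, tolerance = 1e-9)

  # the CNN baselines are exactly the forward pass with unit weights
  params <- init_cnn_params(d = 3, H = 2L, m = 2L, seed = 10)
  toks <- c("tok1", "tok2", "tok1")
  unit <- structure(stats::setNames(rep(1, 2), c("tok1", "tok2")),
                    class = "word_weight_table")
  expect_identical(baseline_forward(toks, emb, params, "cnn_random"),
                   forward_post(toks, emb, unit, params))
  expect_error(baseline_forward(toks, emb, params, "bogus"))
})

test_that("permuting output units and dense rows permutes probabilities", {
  emb <- random_gaussian_embeddings(c("tok1", "tok2"), d = 2, seed = 11)
  params <- init_cnn_params(d = 2, H = 2L, m = 2L, seed = 12)
  toks <- c("tok1", "tok2", "tok2")
  y <- forward_post(toks, emb, NULL, params)
  perm <- c(3L, 1L, 4L, 2L)
  params2 <- params
  params2$V <- params$V[perm, ]
  params2$vb <- params$vb[perm]
  y2 <- forward_post(toks, emb, NULL, params2)
  expect_equal(unname(y2), unname(y)[perm], tolerance = 1e-12)
})

test_that("checkpoints round-trip through save and load", {
  tc <- preprocess_corpus(generate_corpus(tiny_spec(), generate_lexicon(tiny_spec())),
                          n = 30)
  cfg <- train_config(d = 8L, H = 2L, kernels_per_window = 2L,
                      max_iterations = 5L, eval_every = 5L, n = 30L,
                      variant = "cnn_random", seed = 1L)
  model <- suppressWarnings(train_liwcnn(tc, NULL, cfg))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  model2 <- load_checkpoint(path)
  expect_identical(model2$params, model$params)
  expect_identical(model2$version, 1L)
  bad <- tempfile(fileext = ".rds"); saveRDS(list(1), bad)
  expect_error(load_checkpoint(bad), "not a liwcnn checkpoint")
})
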