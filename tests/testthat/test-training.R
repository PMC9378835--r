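test_that("the loss evaluates cross-entropy and the L2 penalty in closed form", {
  probs <- matrix(0.25, nrow = 1, ncol = 4)
  expect_equal(cross_entropy_loss(probs, "green"), -log(0.25))
  expect_equal(round(cross_entropy_loss(probs, "amber"), 5), 1.38629)

  near_perfect <- matrix(c(1 - 3e-9, 1e-9, 1e-9, 1e-9), 1)
  expect_lt(cross_entropy_loss(near_perfect, "green"), 1e-8)

  # zero data term, single weight vector of norm 1, lambda = 0.1 -> 0.05
  params <- list(W = list(matrix(c(0.6, 0.8), 2, 1)), V = matrix(0, 4, 1))
  expect_equal(cross_entropy_loss(matrix(c(1, 0, 0, 0), 1), "green",
                                  params, lambda = 0.1),
               0.05, tolerance = 1e-12)

  expect_warning(
    loss0 <- cross_entropy_loss(matrix(c(0, 1, 0, 0), 1), "green"),
    "clamped")
  expect_true(is.finite(loss0))
})

test_that("the L2 term grows monotonically in any weight magnitude", {
  base <- list(W = list(matrix(0.3, 4, 2)), V = matrix(0.1, 4, 8))
  l0 <- liwcnn:::l2_weight_norm(base)
  for (i in 1:5) {
    pert <- base
    pert$W[[1]][sample(8, 1)] <- pert$W[[1]][sample(8, 1)] + runif(1, 0.1, 1)
    expect_gt(liwcnn:::l2_weight_norm(pert), l0)
  }
})

test_that("the stratified split is proportional, disjoint and seeded", {
  corpus <- data.frame(id = as.character(1:100),
                       label = rep(triage_levels(), 25),
                       text = "x")
  sp <- split_train_val(corpus, fraction = 0.9, seed = 3)
  expect_equal(nrow(sp$train), 90)
  expect_equal(nrow(sp$val), 10)
  expect_length(intersect(sp$train$id, sp$val$id), 0)
  expect_setequal(c(sp$train$id, sp$val$id), corpus$id)
  for (lv in triage_levels()) {
    expect_lte(abs(sum(sp$train$label == lv) - 0.9 * 25), 1)
  }
  sp2 <- split_train_val(corpus, fraction = 0.9, seed = 3)
  expect_identical(sp$train$id, sp2$train$id)

  # 8 posts, 2 per label, fraction 0.5: exactly one of each label per side
  c8 <- data.frame(id = as.character(1:8),
                   label = rep(triage_levels(), each = 2), text = "x")
  sp8 <- split_train_val(c8, fraction = 0.5, seed = 1)
  expect_equal(unname(table(sp8$train$label)[triage_levels()]), rep(1L, 4),
               ignore_attr = TRUE)
  expect_equal(unname(table(sp8$val$label)[triage_levels()]), rep(1L, 4),
               ignore_attr = TRUE)

  lone <- data.frame(id = as.character(1:5),
                     label = c("green", "green", "amber", "amber", "crisis"),
                     text = "x")
  expect_error(split_train_val(lone, 0.5, 1), "crisis")
  expect_error(split_train_val(corpus, 1.2, 1), "fraction")
})

test_that("the validation peak is selected, earliest on ties", {
  h <- data.frame(iteration = c(100L, 200L, 300L),
                  val_acc = c(0.5, 0.8, 0.7))
  expect_equal(select_best_iteration(h), 200L)
  h2 <- data.frame(iteration = c(10L, 20L, 30L), val_acc = c(0.1, 0.2, 0.3))
  expect_equal(select_best_iteration(h2), 30L)
  h3 <- data.frame(iteration = c(100L, 200L, 300L, 400L),
                   val_acc = c(0.5, 0.8, 0.7, 0.8))
  expect_equal(select_best_iteration(h3), 200L)
})

test_that("analytic gradients match central finite differences", {
  for (args in list(list(seed = 1),
                    list(seed = 2, include_embeddings = TRUE),
                    list(seed = 3, variant = "fasttext_avg",
                         include_embeddings = TRUE))) {
    chk <- do.call(gradient_check, args)
    expect_lt(chk$max_rel_error, 1e-4)
  }
  chk <- gradient_check(seed = 4)
  expect_lte(chk$n_params, 20L)
})

test_that("training descends on separable data and selects a checkpoint", {
  spec <- tiny_spec(seed = 2)
  lex <- generate_lexicon(spec, seed = 2)
  corpus <- generate_corpus(spec, lex, seed = 2)
  cfg <- train_config(d = 8L, H = c(2L, 3L), kernels_per_window = 4L,
                      max_iterations = 200L, eval_every = 10L, n = 30L,
                      dropout = 0, lambda = 0, variant = "cnn_random",
                      seed = 2L, w2v_epochs = 1L)
  model <- suppressWarnings(train_liwcnn(corpus, NULL, cfg))
  h <- model$history
  expect_true(all(diff(h$iteration) > 0))
  expect_lt(h$train_loss[h$iteration == 200], h$train_loss[h$iteration == 10])
  expect_equal(model$best_iteration,
               h$iteration[which.max(h$val_acc)])
  # the stored parameters are the snapshot at the selected iteration
  expect_equal(max(h$val_acc), h$val_acc[h$iteration == model$best_iteration])
})

test_that("training is bit-reproducible given the seed", {
  spec <- tiny_spec(seed = 4, posts = 20L)
  lex <- generate_lexicon(spec, seed = 4)
  corpus <- generate_corpus(spec, lex, seed = 4)
  cfg <- train_config(d = 6L, H = 2L, kernels_per_window = 2L,
                      max_iterations = 30L, eval_every = 10L, n = 30L,
                      seed = 9L, w2v_epochs = 1L)
  m1 <- suppressWarnings(train_liwcnn(corpus, lex, cfg))
  m2 <- suppressWarnings(train_liwcnn(corpus, lex, cfg))
  expect_identical(m1$params, m2$params)
  expect_identical(m1$E, m2$E)
  expect_identical(m1$history, m2$history)
})

test_that("training validates its inputs", {
  spec <- tiny_spec(seed = 5, posts = 8L)
  lex <- generate_lexicon(spec, seed = 5)
  corpus <- generate_corpus(spec, lex, seed = 5)
  cfg <- train_config(max_iterations = 2L, n = 20L, seed = 1L)
  expect_error(train_liwcnn(corpus, NULL, cfg), "requires a lexicon")
  unlabeled <- corpus; unlabeled$label <- NA
  cfg2 <- train_config(max_iterations = 2L, n = 20L, seed = 1L,
                       variant = "cnn_random")
  expect_error(train_liwcnn(unlabeled, NULL, cfg2), "labeled")
})
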