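test_that("class frequencies match hand counts on constructed corpora", {
  lex <- liwc_lexicon(data.frame(id = 1L, name = "L1_c"),
                      list(a = 1L, d = 1L))
  tc <- make_tokenized(list(c("a", "b", "c"), c("d", "e")),
                       c("green", "green"))
  freq <- suppressWarnings(compute_class_frequencies(tc, lex))
  expect_equal(freq$tf["L1_c", "green"], 2 / 5)
  expect_equal(unname(freq$token_totals["green"]), 5)

  # saturation: every token of a category matches
  tc2 <- make_tokenized(list(c("a", "d", "a")), "crisis")
  freq2 <- suppressWarnings(compute_class_frequencies(tc2, lex))
  expect_equal(freq2$tf["L1_c", "crisis"], 1.0)

  # a class with no corpus occurrence is zero everywhere
  lex3 <- liwc_lexicon(data.frame(id = 1:2, name = c("L1_c", "L2_c")),
                       list(a = 1L, zz = 2L))
  freq3 <- suppressWarnings(compute_class_frequencies(tc, lex3))
  expect_true(all(freq3$tf["L2_c", ] == 0))

  # pad tokens count nowhere
  tcp <- make_tokenized(list(c("a", "b")), "red", n = 6)
  freqp <- suppressWarnings(compute_class_frequencies(tcp, lex))
  expect_equal(freqp$tf["L1_c", "red"], 1 / 2)

  expect_error(compute_class_frequencies(
    make_tokenized(list("a"), NA_character_), lex), "labeled")
})

test_that("class frequencies equal the nested-loop oracle on random corpora", {
  set.seed(42)
  for (rep in 1:40) {
    lex <- random_lexicon()
    nposts <- sample(2:6, 1)
    token_list <- replicate(nposts, replicate(sample(1:50, 1), random_token()),
                            simplify = FALSE)
    labels <- sample(triage_levels(), nposts, replace = TRUE)
    tc <- make_tokenized(token_list, labels)
    got <- suppressWarnings(compute_class_frequencies(tc, lex))
    expect_identical(unname(got$tf), unname(brute_tf(token_list, labels, lex)))
  }
})

test_that("discriminability reproduces the closed-form normalization chain", {
  freq <- structure(list(
    tf = matrix(c(0.4, 0.2, 0.1, 0.1), nrow = 1,
                dimnames = list("L1_c", triage_levels())),
    classes = data.frame(id = 1L, name = "L1_c", semantic = TRUE),
    categories = triage_levels(),
    token_totals = stats::setNames(rep(10, 4), triage_levels())),
    class = "class_frequency_table")
  disc <- discriminability(freq, k = 1)
  # normalized row (1.0, 0.5, 0.25, 0.25): mu = 0.5, delta = sqrt(0.375)
  expect_equal(unname(disc$tf_norm[1, ]), c(1, 0.5, 0.25, 0.25))
  expect_equal(unname(disc$mu["L1_c"]), 0.5)
  expect_equal(unname(disc$sd["L1_c"]), sqrt(0.375), tolerance = 1e-12)
  expect_equal(round(unname(disc$sd["L1_c"]), 5), 0.61237)
})

test_that("constant rows have zero spread and top-k selection is ordered", {
  tf <- rbind(c(0.1, 0.1, 0.1, 0.1),     # constant -> delta 0
              c(0.4, 0.1, 0.1, 0.1),     # strong
              c(0.2, 0.1, 0.1, 0.1),     # weaker
              c(0, 0, 0, 0))             # absent -> never selected
  freq <- structure(list(
    tf = matrix(tf, nrow = 4,
                dimnames = list(paste0("L", 1:4, "_c"), triage_levels())),
    classes = data.frame(id = 1:4, name = paste0("L", 1:4, "_c"),
                         semantic = TRUE),
    categories = triage_levels(),
    token_totals = stats::setNames(rep(10, 4), triage_levels())),
    class = "class_frequency_table")
  disc <- discriminability(freq, k = 2)
  expect_equal(unname(disc$sd["L1_c"]), 0)
  expect_equal(unname(disc$sd["L4_c"]), 0)
  expect_equal(disc$selected, c(2L, 3L))
  expect_true(all(disc$sd[match(disc$selected, 1:4)] >=
                    max(disc$sd[-match(disc$selected, 1:4)])))

  expect_warning(discriminability(freq, k = 9), "selecting all")
  expect_error(discriminability(freq, k = 0), "k must be")

  # ties break by ascending class id
  tft <- freq
  tft$tf <- matrix(rbind(c(0.4, 0.1, 0.1, 0.1), c(0.4, 0.1, 0.1, 0.1),
                         c(0.2, 0.2, 0.2, 0.2), c(0.1, 0.1, 0.1, 0.2)),
                   nrow = 4, dimnames = dimnames(freq$tf))
  disct <- discriminability(tft, k = 1)
  expect_equal(disct$selected, 1L)
})

test_that("word weights follow the selected-class softmax with the max rule", {
  lex <- liwc_lexicon(data.frame(id = 1:3, name = c("a_c", "b_c", "c_c")),
                      list(x = 1L, y = 2L, z = c(1L, 2L), w = 3L))
  disc <- structure(list(
    sd = stats::setNames(c(0.4, 0.3, 0.9), c("a_c", "b_c", "c_c")),
    selected = c(1L, 2L), k = 2L,
    classes = data.frame(id = 1:3, name = c("a_c", "b_c", "c_c"),
                         semantic = TRUE)),
    class = "class_discriminability")
  w <- word_weights(lex, disc, c("x", "y", "z", "w", "oov"))
  expected <- exp(0.4) / (exp(0.4) + exp(0.3)) + 1
  expect_equal(round(expected, 5), 1.52498)
  expect_equal(unname(w["x"]), expected, tolerance = 1e-12)
  # multi-class token: max-delta rule gives the identical value
  expect_identical(unname(w["z"]), unname(w["x"]))
  # out-of-lexicon and unselected-class-only tokens sit exactly at 1
  expect_identical(unname(w["oov"]), 1)
  expect_identical(unname(w["w"]), 1)

  disc0 <- disc; disc0$selected <- integer()
  expect_error(word_weights(lex, disc0, "x"), "no selected classes")
})

test_that("weights are bounded in [1, 2) and equal 1 iff no selected match", {
  set.seed(3)
  for (rep in 1:20) {
    lex <- random_lexicon()
    toks <- replicate(80, random_token())
    tc <- make_tokenized(split(toks, rep(1:8, each = 10)),
                         sample(triage_levels(), 8, replace = TRUE))
    freq <- suppressWarnings(compute_class_frequencies(tc, lex))
    disc <- suppressWarnings(discriminability(freq, k = 3))
    if (length(disc$selected) == 0L) next
    w <- word_weights(lex, disc, unique(toks))
    expect_true(all(w >= 1 & w < 2))
    matched <- vapply(unique(toks), function(t)
      length(intersect(brute_match(lex, t), disc$selected)) > 0, TRUE)
    expect_identical(unname(w == 1), unname(!matched))
  }
})

test_that("linguistic feature vectors are per-post class fractions", {
  lex <- liwc_lexicon(data.frame(id = 1L, name = "L_c"), list(a = 1L))
  disc <- structure(list(
    sd = c(L_c = 0.5), selected = 1L, k = 1L,
    classes = data.frame(id = 1L, name = "L_c", semantic = TRUE)),
    class = "class_discriminability")
  tc <- make_tokenized(list(c("a", "b", "c", "d"),   # 1 of 4
                            c("x", "y"),             # none
                            c("a", "a", "a")),       # all
                       c("green", "amber", "crisis"))
  lgf <- lgf_features(tc, lex, disc)
  expect_equal(unname(lgf[, "L_c"]), c(0.25, 0, 1))
  expect_true(all(lgf >= 0 & lgf <= 1))

  tc0 <- make_tokenized(list(character()), "green", n = 3)
  expect_warning(lgf0 <- lgf_features(tc0, lex, disc), "zero tokens")
  expect_equal(unname(lgf0[1, ]), 0)
})

test_that("duplicating every post leaves TF, delta and weights unchanged", {
  set.seed(5)
  lex <- random_lexicon()
  token_list <- replicate(8, replicate(12, random_token()), simplify = FALSE)
  labels <- rep(triage_levels(), 2)
  tc1 <- make_tokenized(token_list, labels)
  tc2 <- make_tokenized(c(token_list, token_list), c(labels, labels))
  f1 <- suppressWarnings(compute_class_frequencies(tc1, lex))
  f2 <- suppressWarnings(compute_class_frequencies(tc2, lex))
  expect_equal(f1$tf, f2$tf)
  d1 <- suppressWarnings(discriminability(f1, 2))
  d2 <- suppressWarnings(discriminability(f2, 2))
  expect_equal(d1$sd, d2$sd)
  vocab <- unique(unlist(token_list))
  expect_equal(word_weights(lex, d1, vocab), word_weights(lex, d2, vocab))
})
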