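# Shared fixtures and independent oracles. Everything is generated in code;
# oracles are deliberately naive (nested loops, full scans) so they stay
# independent of the vectorized implementation paths they check.

make_test_lexicon <- function() {
  liwc_lexicon(
    classes = data.frame(id = c(1L, 2L), name = c("death_c", "friends_c")),
    entries = list(die = 1L, dying = 1L, "friend*" = 2L))
}

write_test_dic <- function(path = tempfile(fileext = ".dic")) {
  writeLines(c("%", "1\tdeath_c", "2\tfriends_c", "%",
               "die\t1", "dying\t1", "friend*\t2"), path)
  path
}

# Brute-force token match: scan every pattern.
brute_match <- function(lexicon, token) {
  hits <- integer()
  for (i in seq_along(lexicon$entries)) {
    pat <- names(lexicon$entries)[i]
    ok <- if (endsWith(pat, "*")) {
      startsWith(token, substr(pat, 1L, nchar(pat) - 1L))
    } else {
      token == pat
    }
    if (ok) hits <- c(hits, lexicon$entries[[i]])
  }
  sort(unique(hits))
}

# Random lexicon over a small alphabet so wildcard collisions actually occur.
random_lexicon <- function(nclass = 4L, npat = 12L) {
  syll <- c("ab", "ba", "ca", "abc", "bc", "a", "b", "c")
  pats <- unique(replicate(npat, paste0(
    paste(sample(syll, sample(1:2, 1)), collapse = ""),
    if (runif(1) < 0.4) "*" else "")))
  pats <- pats[order(pats)]
  entries <- lapply(seq_along(pats), function(i)
    sort(unique(sample.int(nclass, sample(1:2, 1)))))
  names(entries) <- pats
  liwc_lexicon(data.frame(id = seq_len(nclass),
                          name = paste0("k", seq_len(nclass), "_c")),
               entries)
}

random_token <- function() {
  paste(sample(c("ab", "ba", "ca", "abc", "bc", "a", "b", "c", "zz"),
               sample(1:3, 1), replace = TRUE), collapse = "")
}

# Build a tokenized_corpus directly from token vectors (bypasses text
# preprocessing so weighting tests control the tokens exactly).
make_tokenized <- function(token_list, labels, n = max(lengths(token_list))) {
  mat <- matrix("PAD", nrow = length(token_list), ncol = n)
  n_i <- integer(length(token_list))
  for (i in seq_along(token_list)) {
    k <- min(length(token_list[[i]]), n)
    n_i[i] <- k
    if (k > 0L) mat[i, seq_len(k)] <- token_list[[i]][seq_len(k)]
  }
  structure(list(ids = paste0("p", seq_along(token_list)),
                 labels = factor(labels, levels = triage_levels()),
                 tokens = mat, n_i = n_i, n = n,
                 polarity_map = stats::setNames(character(), character())),
            class = "tokenized_corpus")
}

# Nested-loop class-frequency oracle: counts every (token, class) membership
# by scanning all patterns per token.
brute_tf <- function(token_list, labels, lexicon) {
  cats <- triage_levels()
  class_ids <- lexicon$classes$id[lexicon$classes$semantic]
  tf <- matrix(0, nrow = length(class_ids), ncol = 4L,
               dimnames = list(lexicon$classes$name[lexicon$classes$semantic],
                               cats))
  totals <- stats::setNames(numeric(4), cats)
  for (i in seq_along(token_list)) {
    c_i <- labels[i]
    for (tok in token_list[[i]]) {
      if (tok == "PAD") next
      totals[c_i] <- totals[c_i] + 1
      for (l in seq_along(class_ids)) {
        if (class_ids[l] %in% brute_match(lexicon, tok)) {
          tf[l, c_i] <- tf[l, c_i] + 1
        }
      }
    }
  }
  sweep(tf, 2, pmax(totals, 1), "/")
}

# Independent per-class precision/recall scorer built from raw counts.
brute_eval <- function(gold, pred) {
  lv <- triage_levels()
  f1 <- function(gp, pp) {
    tp <- sum(gp & pp)
    pr <- if (sum(pp) == 0) 0 else tp / sum(pp)
    rc <- if (sum(gp) == 0) 0 else tp / sum(gp)
    if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  }
  pc <- sapply(lv, function(l) f1(gold == l, pred == l))
  list(all_acc = mean(gold == pred),
       all_f1 = mean(pc),
       non_green_f1 = mean(pc[c("amber", "red", "crisis")]),
       flagged_f1 = f1(gold != "green", pred != "green"),
       flagged_acc = mean((gold != "green") == (pred != "green")),
       urgent_f1 = f1(gold %in% c("red", "crisis"), pred %in% c("red", "crisis")),
       urgent_acc = mean((gold %in% c("red", "crisis")) ==
                          (pred %in% c("red", "crisis"))))
}

# Small, quickly separable generator spec for training-loop tests.
tiny_spec <- function(seed = 1L, posts = 40L) {
  generator_spec(num_classes = 4L, words_per_class = 5L,
                 background_vocab = 40L,
                 rates = 0.30 * diag(4),   # class i marks category i
                 post_length = c(15L, 25L), posts_per_category = posts,
                 emoji_rates = matrix(0, 6, 4), url_rate = 0,
                 seed = seed)
}
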