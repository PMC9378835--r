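#' Synthetic corpus generator specification
#'
#' Defines a bag-of-words generator with known class-conditional structure:
#' a lexicon of `num_classes` word classes, per-(class, category) token
#' emission rates, background vocabulary, per-category emoji emission
#' probabilities over a small inventory, and link insertion.  Every pipeline
#' stage can be exercised against the known ground truth.
#'
#' Each token of a post is drawn independently: with probability
#' `rates[l, c]` from class `l`'s word list (uniformly), otherwise from the
#' background vocabulary.  Per-category emission probabilities must sum to
#' at most 1 per category.  Each emoji's per-post occurrence count is
#' `Binomial(max_repeat, emoji_rates[e, c])`, inserted as an adjacent run at
#' a random position (emojis are commonly typed repeated); a link is
#' inserted with probability `url_rate`.
#'
#' @param num_classes Number of lexicon word classes.
#' @param words_per_class Unique tokens per class.
#' @param background_vocab Background vocabulary size.
#' @param rates Numeric matrix `num_classes x 4` (columns in
#'   [triage_levels()] order) of per-token emission probabilities.
#' @param post_length Length-2 integer vector `c(min, max)`; post lengths
#'   are uniform on this range.
#' @param posts_per_category Posts generated per category.
#' @param emoji_inventory Character vector of emoji codepoints.
#' @param emoji_rates Numeric matrix `length(emoji_inventory) x 4` of
#'   per-occurrence Binomial probabilities.
#' @param max_repeat Binomial size for emoji occurrence counts.
#' @param url_rate Probability a post contains a link.
#' @param wildcard_fraction Fraction of lexicon words emitted as
#'   trailing-wildcard patterns.
#' @param inflect_prob Probability a wildcard word is emitted with an
#'   inflectional suffix (`s`, `ed`, `ing`), exercising wildcard matching.
#' @param seed Default seed carried by the spec.
#' @return A validated `generator_spec` list.
#' @export
generator_spec <- function(num_classes = 8L, words_per_class = 15L,
                           background_vocab = 300L, rates = NULL,
                           post_length = c(70L, 100L),
                           posts_per_category = 400L,
                           emoji_inventory = default_emoji_inventory(),
                           emoji_rates = default_emoji_rates(),
                           max_repeat = 4L, url_rate = 0.1,
                           wildcard_fraction = 0.2, inflect_prob = 0.5,
                           seed = 1L) {
  if (is.null(rates)) rates <- default_planted_rates(num_classes)
  rates <- as.matrix(rates)
  colnames(rates) <- triage_levels()
  emoji_rates <- as.matrix(emoji_rates)
  colnames(emoji_rates) <- triage_levels()
  spec <- list(num_classes = as.integer(num_classes),
               words_per_class = as.integer(words_per_class),
               background_vocab = as.integer(background_vocab),
               rates = rates,
               post_length = as.integer(post_length),
               posts_per_category = as.integer(posts_per_category),
               emoji_inventory = emoji_inventory,
               emoji_rates = emoji_rates,
               max_repeat = as.integer(max_repeat),
               url_rate = url_rate,
               wildcard_fraction = wildcard_fraction,
               inflect_prob = inflect_prob,
               seed = as.integer(seed))
  validate_generator_spec(spec)
  structure(spec, class = "generator_spec")
}

validate_generator_spec <- function(spec) {
  with(spec, {
    stopifnot(num_classes >= 1, words_per_class >= 1, background_vocab >= 1,
              posts_per_category >= 1, length(post_length) == 2L,
              post_length[1] >= 1, post_length[2] >= post_length[1],
              max_repeat >= 1, url_rate >= 0, url_rate <= 1,
              wildcard_fraction >= 0, wildcard_fraction <= 1,
              inflect_prob >= 0, inflect_prob <= 1)
    stopifnot(nrow(rates) == num_classes, ncol(rates) == 4L,
              all(rates >= 0), all(rates <= 1))
    if (any(colSums(rates) > 1)) {
      stop("per-category class emission probabilities must sum to <= 1",
           call. = FALSE)
    }
    stopifnot(nrow(emoji_rates) == length(emoji_inventory),
              ncol(emoji_rates) == 4L, all(emoji_rates >= 0),
              all(emoji_rates <= 1))
  })
  invisible(spec)
}

# Planted-signal rate matrix: class 1 discriminates the categories, the
# remaining classes emit uniformly.
default_planted_rates <- function(num_classes) {
  rates <- matrix(0.02, nrow = num_classes, ncol = 4L,
                  dimnames = list(NULL, triage_levels()))
  rates[1L, ] <- c(green = 0.005, amber = 0.02, red = 0.05, crisis = 0.08)
  rates
}

# Six emojis: two crisis-heavy (urgent-only -> negative markers), two
# green-heavy (non-urgent-only -> positive), and one red- plus one
# amber-leaning emoji that occur in every category and so collapse to the
# neutral marker while still marking their category through run length.
default_emoji_inventory <- function() {
  c("\U0001f62d",  # loudly crying
    "\U0001f494",  # broken heart
    "\U0001f60a",  # smiling
    "\U0001f31f",  # glowing star
    "\U0001f614",  # pensive
    "\U0001f610")  # neutral face
}

default_emoji_rates <- function() {
  q <- rbind(
    c(green = 0,    amber = 0,    red = 0.30, crisis = 0.90),
    c(green = 0,    amber = 0,    red = 0.15, crisis = 0.70),
    c(green = 0.85, amber = 0.35, red = 0,    crisis = 0),
    c(green = 0.65, amber = 0.15, red = 0,    crisis = 0),
    c(green = 0.03, amber = 0.03, red = 0.80, crisis = 0.03),
    c(green = 0.03, amber = 0.80, red = 0.03, crisis = 0.03))
  rownames(q) <- default_emoji_inventory()
  q
}

#' The default planted-signal fixture
#'
#' Eight word classes of 15 words each; class 1 is planted with emission
#' rates (crisis 0.08, red 0.05, amber 0.02, green 0.005) while the other
#' seven emit uniformly at 0.02, so only class 1 carries category signal.
#' 400 posts per category of 70-100 tokens, a 6-emoji inventory with
#' urgent-skewed emissions, and links in 10% of posts.
#'
#' @param seed Seed carried by the spec.
#' @return A `generator_spec`.
#' @export
planted_signal_spec <- function(seed = 1L) {
  generator_spec(seed = seed)
}

#' Generate a synthetic lexicon
#'
#' `num_classes` classes of `words_per_class` unique tokens, disjoint from
#' the background vocabulary by construction.  A `wildcard_fraction` of the
#' words become trailing-wildcard patterns, whose corpus occurrences may
#' carry inflectional suffixes.
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed (defaults to the spec's).
#' @return A [liwc_lexicon()]; the word list per class is stored in the
#'   `"words"` attribute for oracle tests.
#' @export
generate_lexicon <- function(spec, seed = spec$seed) {
  validate_generator_spec(spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  classes <- data.frame(id = seq_len(spec$num_classes),
                        name = sprintf("synclass%02d_c", seq_len(spec$num_classes)),
                        semantic = TRUE)
  words <- lapply(seq_len(spec$num_classes), function(l) {
    sprintf("c%02dw%03d", l, seq_len(spec$words_per_class))
  })
  entries <- list()
  wildcard <- vector("list", spec$num_classes)
  for (l in seq_len(spec$num_classes)) {
    nw <- spec$words_per_class
    is_wc <- rep(FALSE, nw)
    nwc <- round(spec$wildcard_fraction * nw)
    if (nwc > 0L) is_wc[sample.int(nw, nwc)] <- TRUE
    pats <- ifelse(is_wc, paste0(words[[l]], "*"), words[[l]])
    entries <- c(entries, stats::setNames(as.list(rep(l, nw)), pats))
    wildcard[[l]] <- is_wc
  }
  lex <- liwc_lexicon(classes, entries)
  attr(lex, "words") <- words
  attr(lex, "wildcard") <- wildcard
  lex
}

#' Generate a labeled synthetic corpus
#'
#' For each category, `posts_per_category` posts whose tokens are drawn
#' independently: with probability `rates[l, c]` a uniform word of class
#' `l`, otherwise a uniform background token.  Wildcard-pattern words carry
#' an inflectional suffix with probability `inflect_prob`.  Emoji
#' occurrence counts are `Binomial(max_repeat, emoji_rates[e, c])` per
#' emoji, inserted as an adjacent run at a random token boundary; with
#' probability `url_rate` a link is inserted.  The generating parameters
#' and the per-post planted token counts are attached as the
#' `"ground_truth"` attribute.
#'
#' @param spec A [generator_spec()].
#' @param lexicon The lexicon from [generate_lexicon()] (same spec).
#' @param seed Integer seed (defaults to the spec's).
#' @return A corpus data frame (`id`, `label`, `text`) with attribute
#'   `ground_truth` (list: `spec`, `class_token_counts`, `word_tokens`).
#' @export
generate_corpus <- function(spec, lexicon, seed = spec$seed) {
  validate_generator_spec(spec)
  words <- attr(lexicon, "words")
  wildcard <- attr(lexicon, "wildcard")
  if (is.null(words)) {
    stop("lexicon must come from generate_lexicon() for the same spec",
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  suffixes <- c("s", "ed", "ing")
  bg <- sprintf("bg%04d", seq_len(spec$background_vocab))
  cats <- triage_levels()
  npc <- spec$posts_per_category
  total <- 4L * npc

  ids <- character(total); labels <- character(total); texts <- character(total)
  counts <- matrix(0L, nrow = total, ncol = spec$num_classes)
  word_tok <- integer(total)
  row <- 0L
  for (ci in seq_along(cats)) {
    cat_name <- cats[ci]
    p_class <- spec$rates[, ci]
    p_all <- c(p_class, 1 - sum(p_class))
    for (j in seq_len(npc)) {
      row <- row + 1L
      L <- sample(spec$post_length[1]:spec$post_length[2], 1L)
      src <- sample.int(spec$num_classes + 1L, L, replace = TRUE, prob = p_all)
      toks <- character(L)
      for (l in seq_len(spec$num_classes)) {
        at <- which(src == l)
        if (length(at) == 0L) next
        wi <- sample.int(spec$words_per_class, length(at), replace = TRUE)
        w <- words[[l]][wi]
        infl <- wildcard[[l]][wi] & stats::runif(length(at)) < spec$inflect_prob
        if (any(infl)) {
          w[infl] <- paste0(w[infl],
                            sample(suffixes, sum(infl), replace = TRUE))
        }
        toks[at] <- w
        counts[row, l] <- length(at)
      }
      at_bg <- which(src == spec$num_classes + 1L)
      if (length(at_bg) > 0L) {
        toks[at_bg] <- bg[sample.int(spec$background_vocab, length(at_bg),
                                     replace = TRUE)]
      }
      word_tok[row] <- L
      # emoji runs and link insertion
      extras <- character()
      ne <- stats::rbinom(length(spec$emoji_inventory), spec$max_repeat,
                          spec$emoji_rates[, ci])
      for (e in which(ne > 0L)) {
        extras <- c(extras, paste(rep(spec$emoji_inventory[e], ne[e]),
                                  collapse = " "))
      }
      if (stats::runif(1L) < spec$url_rate) {
        extras <- c(extras, sprintf("http://posts.example/%s%04d",
                                    substr(cat_name, 1, 1), j))
      }
      if (length(extras) > 0L) {
        pos <- sample.int(L + 1L, length(extras), replace = TRUE) - 1L
        for (i in order(pos, decreasing = TRUE)) {
          toks <- append(toks, extras[i], after = pos[i])
        }
      }
      ids[row] <- sprintf("%s_%04d", cat_name, j)
      labels[row] <- cat_name
      texts[row] <- paste(toks, collapse = " ")
    }
  }
  corpus <- data.frame(id = ids, label = labels, text = texts)
  colnames(counts) <- lexicon$classes$name
  attr(corpus, "ground_truth") <- list(spec = spec,
                                       class_token_counts = counts,
                                       word_tokens = word_tok)
  corpus
}

#' Write a generated corpus with its ground truth
#'
#' Emits `corpus.jsonl`, `lexicon.dic` and `ground_truth.json` into a
#' directory.
#'
#' @param corpus Corpus from [generate_corpus()].
#' @param lexicon The generating lexicon.
#' @param dir Output directory (created if missing).
#' @return Named vector of the three file paths, invisibly.
#' @export
write_synthetic_bundle <- function(corpus, lexicon, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- attr(corpus, "ground_truth")
  paths <- c(corpus = file.path(dir, "corpus.jsonl"),
             lexicon = file.path(dir, "lexicon.dic"),
             ground_truth = file.path(dir, "ground_truth.json"))
  write_corpus_jsonl(corpus, paths[["corpus"]])
  write_dic(lexicon, paths[["lexicon"]])
  gt_out <- list(spec = gt$spec[setdiff(names(gt$spec), "emoji_inventory")],
                 emoji_inventory = vapply(gt$spec$emoji_inventory,
                                          function(e) sprintf("U+%04X",
                                                              utf8ToInt(e)), ""),
                 class_token_counts = gt$class_token_counts,
                 word_tokens = gt$word_tokens)
  jsonlite::write_json(gt_out, paths[["ground_truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
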