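#' Construct a LIWC-style lexicon
#'
#' A lexicon maps word patterns to word classes.  Patterns are lowercase
#' literal tokens or trailing-wildcard prefixes such as `"friend*"`, which
#' match any token starting with `"friend"`.  Each class carries a `semantic`
#' flag: descriptive classes (word counts, words per sentence, ...) can be
#' flagged non-semantic with [mark_descriptive()] and are then ignored by the
#' frequency and weighting pipeline.
#'
#' @param classes Data frame with columns `id` (unique positive integers),
#'   `name` (character) and optionally `semantic` (logical, default `TRUE`).
#' @param entries Named list: names are patterns, values are integer vectors
#'   of class ids (each pattern must map to at least one class).
#' @return An object of class `liwc_lexicon` with elements `classes`
#'   (data.frame) and `entries` (named list of integer vectors).
#' @export
#' @examples
#' lex <- liwc_lexicon(
#'   classes = data.frame(id = c(1L, 2L), name = c("death_c", "friends_c")),
#'   entries = list(die = 1L, dying = 1L, "friend*" = 2L))
#' match_token(lex, "friends")
liwc_lexicon <- function(classes, entries) {
  stopifnot(is.data.frame(classes), all(c("id", "name") %in% names(classes)))
  classes$id <- as.integer(classes$id)
  classes$name <- as.character(classes$name)
  if (is.null(classes$semantic)) classes$semantic <- TRUE
  classes$semantic <- as.logical(classes$semantic)
  if (nrow(classes) == 0L) {
    stop("lexicon must declare at least one word class", call. = FALSE)
  }
  if (anyDuplicated(classes$id)) {
    stop("class ids must be unique", call. = FALSE)
  }
  entries <- as.list(entries)
  if (length(entries) > 0L) {
    pats <- names(entries)
    if (is.null(pats) || any(!nzchar(pats))) {
      stop("every entry must be a named pattern", call. = FALSE)
    }
    if (anyDuplicated(pats)) stop("duplicate patterns in entries", call. = FALSE)
    if (any(pats != tolower(pats))) {
      stop("patterns must be lowercase", call. = FALSE)
    }
    star <- gregexpr("*", pats, fixed = TRUE)
    bad <- vapply(seq_along(pats), function(i) {
      pos <- star[[i]]
      pos[1] != -1L && (length(pos) > 1L || pos[1] != nchar(pats[i]))
    }, logical(1))
    if (any(bad)) {
      stop(sprintf("only a single trailing '*' wildcard is supported: %s",
                   paste(pats[bad], collapse = ", ")), call. = FALSE)
    }
    entries <- lapply(entries, function(ids) sort(unique(as.integer(ids))))
    if (any(lengths(entries) == 0L)) {
      stop("every pattern must map to at least one class", call. = FALSE)
    }
    unknown <- setdiff(unique(unlist(entries)), classes$id)
    if (length(unknown) > 0L) {
      stop(sprintf("entries reference unknown class id(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(classes = classes[order(classes$id), , drop = FALSE],
                 entries = entries),
            class = "liwc_lexicon")
}

#' @export
print.liwc_lexicon <- function(x, ...) {
  nw <- sum(endsWith(names(x$entries) %||% character(), "*"))
  cat(sprintf("<liwc_lexicon> %d classes (%d semantic), %d patterns (%d wildcard)\n",
              nrow(x$classes), sum(x$classes$semantic),
              length(x$entries), nw))
  invisible(x)
}

#' Flag word classes as descriptive (non-semantic)
#'
#' Descriptive classes are bookkeeping categories without lexical semantics;
#' they are excluded from frequency analysis, discriminability ranking and
#' attention weights.
#'
#' @param lexicon A [liwc_lexicon()].
#' @param class_ids Integer ids (or character names) of classes to flag.
#' @return The lexicon with the `semantic` flag cleared on those classes.
#' @export
mark_descriptive <- function(lexicon, class_ids) {
  stopifnot(inherits(lexicon, "liwc_lexicon"))
  if (is.character(class_ids)) {
    class_ids <- lexicon$classes$id[match(class_ids, lexicon$classes$name)]
  }
  miss <- setdiff(as.integer(class_ids), lexicon$classes$id)
  if (length(miss) > 0L) {
    stop(sprintf("unknown class id(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  lexicon$classes$semantic[lexicon$classes$id %in% class_ids] <- FALSE
  lexicon
}

#' Read a lexicon in the `.dic` dialect
#'
#' The file starts with a `%`-delimited header block of `id<TAB>name` lines,
#' followed by entry lines `pattern<TAB>id[<TAB>id...]`.  Entries referencing
#' class ids absent from the header are a validation error.
#'
#' @param path Path to a UTF-8 `.dic` file.
#' @return A [liwc_lexicon()].  All classes load with `semantic = TRUE`; use
#'   [mark_descriptive()] to flag descriptive classes.
#' @export
read_dic <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  delim <- which(trimws(lines) == "%")
  if (length(delim) < 2L || delim[1] != 1L) {
    stop(sprintf("%s: malformed header: expected a '%%'-delimited category block starting at line 1",
                 path), call. = FALSE)
  }
  header <- lines[(delim[1] + 1L):(delim[2] - 1L)]
  if (delim[2] - delim[1] <= 1L) {
    stop(sprintf("%s: empty category block", path), call. = FALSE)
  }
  hparts <- strsplit(header, "\t", fixed = TRUE)
  if (any(lengths(hparts) < 2L)) {
    bad <- which(lengths(hparts) < 2L)[1]
    stop(sprintf("%s: malformed header line %d: %s", path,
                 delim[1] + bad, header[bad]), call. = FALSE)
  }
  ids <- suppressWarnings(as.integer(vapply(hparts, `[[`, "", 1L)))
  if (anyNA(ids)) {
    bad <- which(is.na(ids))[1]
    stop(sprintf("%s: non-integer class id on header line %d", path,
                 delim[1] + bad), call. = FALSE)
  }
  classes <- data.frame(id = ids,
                        name = vapply(hparts, `[[`, "", 2L),
                        semantic = TRUE)

  body <- if (delim[2] < length(lines)) lines[(delim[2] + 1L):length(lines)] else character()
  entries <- list()
  if (length(body) > 0L) {
    bparts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(bparts) < 2L)) {
      bad <- which(lengths(bparts) < 2L)[1]
      stop(sprintf("%s: malformed entry line %d: %s", path,
                   delim[2] + bad, body[bad]), call. = FALSE)
    }
    pats <- tolower(vapply(bparts, `[[`, "", 1L))
    vals <- lapply(bparts, function(p) {
      v <- suppressWarnings(as.integer(p[-1]))
      v[!is.na(v)]
    })
    entries <- stats::setNames(vals, pats)
  }
  liwc_lexicon(classes, entries)
}

#' Write a lexicon in the `.dic` dialect
#'
#' @param lexicon A [liwc_lexicon()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dic <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "liwc_lexicon"))
  header <- sprintf("%d\t%s", lexicon$classes$id, lexicon$classes$name)
  body <- vapply(seq_along(lexicon$entries), function(i) {
    paste(c(names(lexicon$entries)[i], lexicon$entries[[i]]), collapse = "\t")
  }, "")
  writeLines(c("%", header, "%", body), path, useBytes = TRUE)
  invisible(path)
}

# Split entries into a literal hash environment and wildcard prefix tables.
# Cached on the lexicon object the first time a match is requested.
lexicon_matcher <- function(lexicon) {
  m <- attr(lexicon, "matcher")
  if (!is.null(m)) return(m)
  pats <- names(lexicon$entries) %||% character()
  wc <- endsWith(pats, "*")
  lit <- new.env(parent = emptyenv(), size = max(1L, sum(!wc)))
  for (i in which(!wc)) assign(pats[i], lexicon$entries[[i]], envir = lit)
  prefixes <- substr(pats[wc], 1L, nchar(pats[wc]) - 1L)
  m <- list(literal = lit, prefixes = prefixes,
            prefix_ids = lexicon$entries[wc])
  m
}

#' Match a single token against a lexicon
#'
#' Returns the union of class ids from the exact-match entry (if any) and
#' every trailing-wildcard entry whose prefix is a prefix of the token.
#' Out-of-lexicon tokens yield an empty integer vector.
#'
#' @param lexicon A [liwc_lexicon()].
#' @param token A single lowercase token.
#' @return Sorted integer vector of class ids (possibly empty).
#' @export
match_token <- function(lexicon, token) {
  stopifnot(inherits(lexicon, "liwc_lexicon"), is.character(token),
            length(token) == 1L)
  match_tokens(lexicon, token)[[1]]
}

#' Match a vector of tokens against a lexicon
#'
#' Vectorized form of [match_token()]; each unique token is matched once.
#'
#' @inheritParams match_token
#' @param tokens Character vector of lowercase tokens.
#' @return List of sorted integer vectors of class ids, one per token.
#' @export
match_tokens <- function(lexicon, tokens) {
  m <- lexicon_matcher(lexicon)
  uniq <- unique(tokens)
  hits <- lapply(uniq, function(tok) {
    ids <- if (exists(tok, envir = m$literal, inherits = FALSE)) {
      get(tok, envir = m$literal, inherits = FALSE)
    } else integer()
    if (length(m$prefixes) > 0L) {
      w <- startsWith(tok, m$prefixes)
      if (any(w)) ids <- c(ids, unlist(m$prefix_ids[w], use.names = FALSE))
    }
    sort(unique(as.integer(ids)))
  })
  hits[match(tokens, uniq)]
}
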