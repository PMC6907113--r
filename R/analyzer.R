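#' Text analyzer configuration
#'
#' Bundles the settings that [tokenize()] uses: optional stopword removal and
#' Porter stemming. The analyzer is deliberately simple — lowercasing,
#' splitting on any non-alphanumeric character, optional stopword filtering,
#' then stemming — because downstream proximity weighting measures distances
#' on the analyzed token stream, and every token dropped shortens those
#' distances. Stopword removal is therefore off by default.
#'
#' @param stopwords character vector of words to drop (compared after
#'   lowercasing, before stemming). Default: none.
#' @param stem logical; apply the Porter stemmer (default `TRUE`).
#' @return an object of class `text_analyzer`.
#' @seealso [tokenize()], [porter_stem()]
#' @export
#' @examples
#' tokenize("Heart disease in China", text_analyzer(stopwords = "in"))
text_analyzer <- function(stopwords = character(), stem = TRUE) {
  stopifnot(is.character(stopwords), is.logical(stem), length(stem) == 1L)
  structure(list(stopwords = tolower(stopwords), stem = stem),
            class = "text_analyzer")
}

#' Tokenize raw text
#'
#' Lowercases (after NFC normalization), splits on runs of non-alphanumeric
#' characters, optionally removes stopwords, and Porter-stems each surviving
#' token. Token positions are the 0-based indices in the returned vector;
#' the distance between two tokens is the absolute difference of their
#' positions, so adjacent tokens are at distance 1.
#'
#' @param text a character scalar (may be empty).
#' @param analyzer a [text_analyzer()].
#' @return character vector of tokens, in original order.
#' @export
tokenize <- function(text, analyzer = text_analyzer()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character())
  text <- tolower(enc2utf8(text))
  toks <- strsplit(text, "[^a-z0-9]+")[[1L]]
  toks <- toks[nzchar(toks)]
  if (length(analyzer$stopwords)) {
    toks <- toks[!(toks %in% analyzer$stopwords)]
  }
  if (isTRUE(analyzer$stem) && length(toks)) {
    uniq <- unique(toks)
    toks <- porter_stem(uniq)[match(toks, uniq)]
  }
  unname(toks)
}

#' Porter stemmer
#'
#' The original Porter (1980) suffix-stripping algorithm for English,
#' implemented directly from the algorithm definition: five rule steps
#' conditioned on the measure m of the candidate stem (the number of
#' vowel-consonant sequences in its [C](VC)^m[V] form). Words of length one
#' or two are returned unchanged, as in the reference implementation.
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length as `words`.
#' @export
#' @examples
#' porter_stem(c("diseases", "disease", "relational", "caresses"))
porter_stem <- function(words) {
  stopifnot(is.character(words))
  vapply(words, porter_stem1, character(1), USE.NAMES = FALSE)
}

# --- Porter internals ---------------------------------------------------

# consonant flags for each letter of w; y is a consonant at the start or
# after a vowel, a vowel after a consonant
.pstem_cons <- function(chars) {
  n <- length(chars)
  cons <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c("a", "e", "i", "o", "u")) {
      cons[i] <- FALSE
    } else if (ch == "y") {
      cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
    } else {
      cons[i] <- TRUE
    }
  }
  cons
}

# the measure m: number of V-to-C transitions
.pstem_m <- function(chars) {
  cons <- .pstem_cons(chars)
  n <- length(cons)
  if (n < 2L) return(0L)
  sum(cons[-1L] & !cons[-n])
}

.pstem_has_vowel <- function(chars) any(!.pstem_cons(chars))

.pstem_double_cons <- function(chars) {
  n <- length(chars)
  n >= 2L && chars[n] == chars[n - 1L] && .pstem_cons(chars)[n]
}

# *o condition: stem ends consonant-vowel-consonant, final consonant
# not w, x or y
.pstem_cvc <- function(chars) {
  n <- length(chars)
  if (n < 3L) return(FALSE)
  cons <- .pstem_cons(chars)
  cons[n] && !cons[n - 1L] && cons[n - 2L] && !(chars[n] %in% c("w", "x", "y"))
}

.pstem_ends <- function(word, suffix) {
  nw <- nchar(word); ns <- nchar(suffix)
  nw >= ns && substring(word, nw - ns + 1L, nw) == suffix
}

.pstem_chop <- function(word, suffix) substring(word, 1L, nchar(word) - nchar(suffix))

# rule tables for steps 2-4; applied longest-suffix-first, and once the
# longest matching suffix is found no shorter one is tried even if the
# measure condition fails (reference-implementation semantics)
.pstem_step2_rules <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
  c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
  c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
  c("ation", "ate"), c("ator", "ate"), c("alism", "al"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"), c("aliti", "al"),
  c("iviti", "ive"), c("biliti", "ble")
)
.pstem_step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)
.pstem_step4_suffixes <- c(
  "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
  "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize"
)

.pstem_apply_rules <- function(word, rules, min_m) {
  ord <- order(-vapply(rules, function(r) nchar(r[1L]), integer(1)))
  for (r in rules[ord]) {
    if (.pstem_ends(word, r[1L])) {
      stem <- .pstem_chop(word, r[1L])
      if (.pstem_m(strsplit(stem, "")[[1L]]) > min_m) {
        word <- paste0(stem, r[2L])
      }
      return(word)  # longest match consumes the step
    }
  }
  word
}

porter_stem1 <- function(word) {
  if (is.na(word) || nchar(word) <= 2L) return(word)

  # step 1a: plurals
  if (.pstem_ends(word, "sses")) {
    word <- paste0(.pstem_chop(word, "sses"), "ss")
  } else if (.pstem_ends(word, "ies")) {
    word <- paste0(.pstem_chop(word, "ies"), "i")
  } else if (!.pstem_ends(word, "ss") && .pstem_ends(word, "s")) {
    word <- .pstem_chop(word, "s")
  }

  # step 1b: -ed / -ing
  step1b_fix <- FALSE
  if (.pstem_ends(word, "eed")) {
    stem <- .pstem_chop(word, "eed")
    if (.pstem_m(strsplit(stem, "")[[1L]]) > 0L) word <- paste0(stem, "ee")
  } else if (.pstem_ends(word, "ed")) {
    stem <- .pstem_chop(word, "ed")
    if (.pstem_has_vowel(strsplit(stem, "")[[1L]])) {
      word <- stem; step1b_fix <- TRUE
    }
  } else if (.pstem_ends(word, "ing")) {
    stem <- .pstem_chop(word, "ing")
    if (.pstem_has_vowel(strsplit(stem, "")[[1L]])) {
      word <- stem; step1b_fix <- TRUE
    }
  }
  if (step1b_fix) {
    chars <- strsplit(word, "")[[1L]]
    if (.pstem_ends(word, "at") || .pstem_ends(word, "bl") ||
        .pstem_ends(word, "iz")) {
      word <- paste0(word, "e")
    } else if (.pstem_double_cons(chars) &&
               !(chars[length(chars)] %in% c("l", "s", "z"))) {
      word <- substring(word, 1L, nchar(word) - 1L)
    } else if (.pstem_m(chars) == 1L && .pstem_cvc(chars)) {
      word <- paste0(word, "e")
    }
  }

  # step 1c: y -> i after a vowel-bearing stem
  if (.pstem_ends(word, "y")) {
    stem <- .pstem_chop(word, "y")
    if (.pstem_has_vowel(strsplit(stem, "")[[1L]])) {
      word <- paste0(stem, "i")
    }
  }

  word <- .pstem_apply_rules(word, .pstem_step2_rules, 0L)
  word <- .pstem_apply_rules(word, .pstem_step3_rules, 0L)

  # step 4: strip residual derivational suffixes when m > 1
  suf <- .pstem_step4_suffixes
  suf <- suf[order(-nchar(suf))]
  for (s in suf) {
    if (.pstem_ends(word, s)) {
      stem <- .pstem_chop(word, s)
      ok <- .pstem_m(strsplit(stem, "")[[1L]]) > 1L
      if (ok && s == "ion") {
        ok <- .pstem_ends(stem, "s") || .pstem_ends(stem, "t")
      }
      if (ok) word <- stem
      break
    }
  }

  # step 5a: drop a final e
  if (.pstem_ends(word, "e")) {
    stem <- .pstem_chop(word, "e")
    chars <- strsplit(stem, "")[[1L]]
    m <- .pstem_m(chars)
    if (m > 1L || (m == 1L && !.pstem_cvc(chars))) word <- stem
  }

  # step 5b: -ll -> -l when m > 1
  chars <- strsplit(word, "")[[1L]]
  if (.pstem_m(chars) > 1L && .pstem_double_cons(chars) &&
      chars[length(chars)] == "l") {
    word <- substring(word, 1L, nchar(word) - 1L)
  }
  word
}
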