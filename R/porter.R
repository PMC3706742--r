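# Porter stemmer (the 1980 algorithm), implemented from its published
# definition: measure-based conditions over consonant/vowel sequences and
# five suffix-stripping steps with longest-match-wins semantics within a
# step.  Words of length <= 2 are returned unchanged.

# consonant/vowel pattern of a word: "C"/"V" per letter; y is a vowel only
# when preceded by a consonant
porter_cv <- function(word) {
  letters_ <- strsplit(word, "", fixed = TRUE)[[1]]
  n <- length(letters_)
  cv <- character(n)
  for (i in seq_len(n)) {
    ch <- letters_[i]
    if (ch %in% c("a", "e", "i", "o", "u")) {
      cv[i] <- "V"
    } else if (ch == "y") {
      cv[i] <- if (i > 1 && cv[i - 1] == "C") "V" else "C"
    } else {
      cv[i] <- "C"
    }
  }
  paste(cv, collapse = "")
}

# m = number of VC blocks in the condensed C/V sequence
porter_m <- function(stem) {
  if (!nzchar(stem)) return(0L)
  cv <- gsub("(.)\\1+", "\\1", porter_cv(stem))
  lengths(regmatches(cv, gregexpr("VC", cv)))
}

porter_has_vowel <- function(stem) {
  nzchar(stem) && grepl("V", porter_cv(stem), fixed = TRUE)
}

# *d: ends with a double consonant
porter_ends_cc <- function(word) {
  n <- nchar(word)
  if (n < 2) return(FALSE)
  a <- substr(word, n - 1, n - 1)
  b <- substr(word, n, n)
  a == b && substr(porter_cv(word), n, n) == "C"
}

# *o: ends consonant-vowel-consonant where the final consonant is not w, x, y
porter_ends_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3) return(FALSE)
  cv <- porter_cv(word)
  last <- substr(word, n, n)
  substr(cv, n - 2, n) == "CVC" && !(last %in% c("w", "x", "y"))
}

porter_ends <- function(word, suffix) {
  n <- nchar(word)
  k <- nchar(suffix)
  n > k && substr(word, n - k + 1, n) == suffix
}

porter_chop <- function(word, k) substr(word, 1, nchar(word) - k)

# shared driver for steps 2-4: rules is a list of c(suffix, replacement);
# the longest matching suffix is the only one whose condition is tested
porter_rule_step <- function(word, rules, cond) {
  widths <- vapply(rules, function(r) nchar(r[[1]]), integer(1))
  for (r in rules[order(-widths)]) {
    if (porter_ends(word, r[[1]])) {
      stem <- porter_chop(word, nchar(r[[1]]))
      if (cond(stem, word)) word <- paste0(stem, r[[2]])
      return(word)
    }
  }
  word
}

porter_step1 <- function(w) {
  # 1a: plurals
  if (porter_ends(w, "sses")) {
    w <- porter_chop(w, 2)
  } else if (porter_ends(w, "ies")) {
    w <- paste0(porter_chop(w, 3), "i")
  } else if (!porter_ends(w, "ss") && porter_ends(w, "s")) {
    w <- porter_chop(w, 1)
  }
  # 1b: -ed / -ing
  if (porter_ends(w, "eed")) {
    if (porter_m(porter_chop(w, 3)) > 0) w <- porter_chop(w, 1)
  } else {
    stripped <- FALSE
    if (porter_ends(w, "ed") && porter_has_vowel(porter_chop(w, 2))) {
      w <- porter_chop(w, 2); stripped <- TRUE
    } else if (porter_ends(w, "ing") && porter_has_vowel(porter_chop(w, 3))) {
      w <- porter_chop(w, 3); stripped <- TRUE
    }
    if (stripped) {
      if (porter_ends(w, "at") || porter_ends(w, "bl") || porter_ends(w, "iz")) {
        w <- paste0(w, "e")
      } else if (porter_ends_cc(w) &&
                 !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
        w <- porter_chop(w, 1)
      } else if (porter_m(w) == 1 && porter_ends_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }
  # 1c: y -> i when the stem has a vowel
  if (porter_ends(w, "y") && porter_has_vowel(porter_chop(w, 1))) {
    w <- paste0(porter_chop(w, 1), "i")
  }
  w
}

porter_step2_rules <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
  c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
  c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
  c("ation", "ate"), c("ator", "ate"), c("alism", "al"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"), c("aliti", "al"),
  c("iviti", "ive"), c("biliti", "ble")
)

porter_step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)

porter_step4_rules <- list(
  c("al", ""), c("ance", ""), c("ence", ""), c("er", ""), c("ic", ""),
  c("able", ""), c("ible", ""), c("ant", ""), c("ement", ""), c("ment", ""),
  c("ent", ""), c("ion", ""), c("ou", ""), c("ism", ""), c("ate", ""),
  c("iti", ""), c("ous", ""), c("ive", ""), c("ize", "")
)

porter_step5 <- function(w) {
  # 5a: drop a final e
  if (porter_ends(w, "e")) {
    stem <- porter_chop(w, 1)
    m <- porter_m(stem)
    if (m > 1 || (m == 1 && !porter_ends_cvc(stem))) w <- stem
  }
  # 5b: -ll -> -l at m > 1
  if (porter_ends_cc(w) && porter_ends(w, "l") && porter_m(porter_chop(w, 1)) > 1) {
    w <- porter_chop(w, 1)
  }
  w
}

porter_stem_one <- function(w) {
  if (nchar(w) <= 2) return(w)
  w <- porter_step1(w)
  w <- porter_rule_step(w, porter_step2_rules,
                        function(stem, word) porter_m(stem) > 0)
  w <- porter_rule_step(w, porter_step3_rules,
                        function(stem, word) porter_m(stem) > 0)
  w <- porter_rule_step(w, porter_step4_rules, function(stem, word) {
    if (porter_m(stem) <= 1) return(FALSE)
    last <- substr(stem, nchar(stem), nchar(stem))
    # the -ion rule additionally requires the stem to end in s or t
    !(porter_ends(word, "ion") && !last %in% c("s", "t"))
  })
  porter_step5(w)
}

#' Stem words with the Porter algorithm
#'
#' Applies the original Porter suffix-stripping algorithm to each element of
#' a character vector of lowercase word tokens.  Words of one or two
#' characters, and tokens containing digits only, pass through unchanged by
#' construction of the rules.
#'
#' @param words Character vector of lowercase tokens.
#' @return Character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("regulation", "secondary", "shoots"))
#' @export
porter_stem <- function(words) {
  if (length(words) == 0) return(character(0))
  uw <- unique(words)
  hit <- mget(uw, envir = .porter_cache, ifnotfound = NA_character_)
  stems <- unlist(hit, use.names = FALSE)
  todo <- is.na(stems)
  if (any(todo)) {
    fresh <- vapply(uw[todo], porter_stem_one, character(1), USE.NAMES = FALSE)
    stems[todo] <- fresh
    for (i in which(todo)) assign(uw[i], stems[i], envir = .porter_cache)
  }
  stems[match(words, uw)]
}

# session-lifetime memoization of stems (vocabulary-sized, bounded)
.porter_cache <- new.env(parent = emptyenv())
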