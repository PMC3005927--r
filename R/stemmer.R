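# English Porter stemmer (Porter 1980), the algorithm underlying the Snowball
# English stemmer. Implemented here because function-mention grounding scores
# rely on comparing stemmed token sets ("activity" -> "activ",
# "binding" -> "bind").

pt_is_cons <- function(w, i) {
  ch <- substr(w, i, i)
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!pt_is_cons(w, i - 1L))
  }
  TRUE
}

# measure m of the stem: number of VC sequences
pt_measure <- function(w) {
  n <- nchar(w)
  if (n == 0L) return(0L)
  types <- vapply(seq_len(n), function(i) pt_is_cons(w, i), logical(1))
  rle_types <- rle(types)
  v <- rle_types$values
  # count transitions vowel-run -> consonant-run
  m <- 0L
  for (i in seq_along(v)) {
    if (i > 1L && v[i] && !v[i - 1L]) m <- m + 1L
  }
  m
}

pt_has_vowel <- function(w) {
  n <- nchar(w)
  n > 0L && any(!vapply(seq_len(n), function(i) pt_is_cons(w, i), logical(1)))
}

pt_double_cons <- function(w) {
  n <- nchar(w)
  n >= 2L && substr(w, n, n) == substr(w, n - 1L, n - 1L) && pt_is_cons(w, n)
}

# *o: stem ends cvc where final c is not w, x or y
pt_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  if (!pt_is_cons(w, n) || pt_is_cons(w, n - 1L) || !pt_is_cons(w, n - 2L))
    return(FALSE)
  !substr(w, n, n) %in% c("w", "x", "y")
}

pt_ends <- function(w, suf) {
  n <- nchar(w); k <- nchar(suf)
  n > k && substr(w, n - k + 1L, n) == suf
}

pt_replace <- function(w, suf, rep) {
  paste0(substr(w, 1L, nchar(w) - nchar(suf)), rep)
}

# apply the first matching (suffix, replacement) rule whose stem satisfies cond
pt_rule_set <- function(w, rules, min_m = 1L) {
  for (r in rules) {
    suf <- r[[1]]; rep <- r[[2]]
    if (pt_ends(w, suf)) {
      stem <- substr(w, 1L, nchar(w) - nchar(suf))
      if (pt_measure(stem) >= min_m) return(paste0(stem, rep))
      return(w)
    }
  }
  w
}

#' Stem an English word (Porter algorithm)
#'
#' @param word Character vector of lowercase words.
#' @return Character vector of stems.
#' @export
porter_stem <- function(word) {
  vapply(word, pt_stem_one, character(1), USE.NAMES = FALSE)
}

pt_stem_one <- function(w) {
  w <- tolower(w)
  if (nchar(w) <= 2L) return(w)

  # step 1a
  if (pt_ends(w, "sses")) w <- pt_replace(w, "sses", "ss")
  else if (pt_ends(w, "ies")) w <- pt_replace(w, "ies", "i")
  else if (pt_ends(w, "ss")) w <- w
  else if (pt_ends(w, "s")) w <- pt_replace(w, "s", "")

  # step 1b
  if (pt_ends(w, "eed")) {
    stem <- substr(w, 1L, nchar(w) - 3L)
    if (pt_measure(stem) > 0L) w <- paste0(stem, "ee")
  } else {
    hit <- FALSE
    if (pt_ends(w, "ed")) {
      stem <- substr(w, 1L, nchar(w) - 2L)
      if (pt_has_vowel(stem)) { w <- stem; hit <- TRUE }
    } else if (pt_ends(w, "ing")) {
      stem <- substr(w, 1L, nchar(w) - 3L)
      if (pt_has_vowel(stem)) { w <- stem; hit <- TRUE }
    }
    if (hit) {
      if (pt_ends(w, "at") || pt_ends(w, "bl") || pt_ends(w, "iz")) {
        w <- paste0(w, "e")
      } else if (pt_double_cons(w) &&
                 !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
        w <- substr(w, 1L, nchar(w) - 1L)
      } else if (pt_measure(w) == 1L && pt_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  # step 1c
  if (pt_ends(w, "y") && pt_has_vowel(substr(w, 1L, nchar(w) - 1L))) {
    w <- pt_replace(w, "y", "i")
  }

  # step 2 (m > 0)
  w <- pt_rule_set(w, list(
    list("ational", "ate"), list("tional", "tion"), list("enci", "ence"),
    list("anci", "ance"), list("izer", "ize"), list("abli", "able"),
    list("alli", "al"), list("entli", "ent"), list("eli", "e"),
    list("ousli", "ous"), list("ization", "ize"), list("ation", "ate"),
    list("ator", "ate"), list("alism", "al"), list("iveness", "ive"),
    list("fulness", "ful"), list("ousness", "ous"), list("aliti", "al"),
    list("iviti", "ive"), list("biliti", "ble")), min_m = 1L)

  # step 3 (m > 0)
  w <- pt_rule_set(w, list(
    list("icate", "ic"), list("ative", ""), list("alize", "al"),
    list("iciti", "ic"), list("ical", "ic"), list("ful", ""),
    list("ness", "")), min_m = 1L)

  # step 4 (m > 1)
  n0 <- nchar(w)
  for (suf in c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
                "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
                "ous", "ive", "ize")) {
    if (pt_ends(w, suf)) {
      stem <- substr(w, 1L, nchar(w) - nchar(suf))
      ok <- pt_measure(stem) > 1L
      if (suf == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) w <- stem
      break
    }
  }

  # step 5a
  if (pt_ends(w, "e")) {
    stem <- substr(w, 1L, nchar(w) - 1L)
    m <- pt_measure(stem)
    if (m > 1L || (m == 1L && !pt_cvc(stem))) w <- stem
  }
  # step 5b
  if (pt_measure(w) > 1L && pt_double_cons(w) &&
      substr(w, nchar(w), nchar(w)) == "l") {
    w <- substr(w, 1L, nchar(w) - 1L)
  }
  w
}
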