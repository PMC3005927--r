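# Character offsets throughout the annotation model are 0-based, half-open
# [start, end) into the document text; protein sequence positions (grounding)
# are 1-based, the convention wNm mutation mentions use.

#' Tokenize text into whitespace-delimited tokens with punctuation detachment
#'
#' Splits `text` on whitespace, then detaches leading and trailing punctuation
#' characters (`. , ; : ( ) [ ]`) of each chunk into separate tokens.
#' Characters such as `/`, `-` and `+` are kept inside tokens so that
#' kinetic-variable surfaces ("kcat/Km"), percentage ranges ("30-40%") and
#' mutation series ("Arg172Lys+His65Ala") survive as single tokens. Internal
#' punctuation (as in "1,2-dibromoethane") is never detached.
#'
#' Tokens that arise from detachment carry `is_space_delimited = FALSE`; the
#' token-distance scoring used for impact statements counts only
#' space-delimited tokens.
#'
#' @param text A character scalar (may be empty).
#' @return A data.frame with columns `start`, `end` (0-based, half-open),
#'   `surface` and `is_space_delimited`.
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(start = integer(), end = integer(),
                      surface = character(), is_space_delimited = logical(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)

  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")

  out_start <- integer(0); out_end <- integer(0)
  out_surf <- character(0); out_space <- logical(0)
  detach <- ".,;:()[]"

  for (i in seq_along(starts)) {
    s <- starts[i]            # 1-based
    e <- s + lens[i] - 1L
    chunk <- substr(text, s, e)
    # peel leading/trailing detachment characters
    lead <- character(0); trail <- character(0)
    while (nchar(chunk) > 1L &&
           grepl(substr(chunk, 1L, 1L), detach, fixed = TRUE)) {
      lead <- c(lead, substr(chunk, 1L, 1L))
      chunk <- substr(chunk, 2L, nchar(chunk))
    }
    while (nchar(chunk) > 1L &&
           grepl(substr(chunk, nchar(chunk), nchar(chunk)), detach,
                 fixed = TRUE)) {
      trail <- c(substr(chunk, nchar(chunk), nchar(chunk)), trail)
      chunk <- substr(chunk, 1L, nchar(chunk) - 1L)
    }
    core_is_punct <- grepl("^[.,;:()\\[\\]]+$", chunk, perl = TRUE)
    pos <- s
    for (ch in lead) {
      out_start <- c(out_start, pos - 1L); out_end <- c(out_end, pos)
      out_surf <- c(out_surf, ch); out_space <- c(out_space, FALSE)
      pos <- pos + 1L
    }
    out_start <- c(out_start, pos - 1L)
    out_end <- c(out_end, pos + nchar(chunk) - 1L)
    out_surf <- c(out_surf, chunk)
    # a bare punctuation chunk (e.g. a lone period) is not a space token
    # for distance purposes
    out_space <- c(out_space, !core_is_punct)
    pos <- pos + nchar(chunk)
    for (ch in trail) {
      out_start <- c(out_start, pos - 1L); out_end <- c(out_end, pos)
      out_surf <- c(out_surf, ch); out_space <- c(out_space, FALSE)
      pos <- pos + 1L
    }
  }
  data.frame(start = out_start, end = out_end, surface = out_surf,
             is_space_delimited = out_space, stringsAsFactors = FALSE)
}

#' Default protected abbreviations for sentence splitting
#'
#' A period ending one of these surfaces never opens a sentence boundary.
#' @export
protected_abbreviations <- function() {
  c("e.g.", "i.e.", "et al.", "al.", "Fig.", "Figs.", "cf.", "vs.", "ca.",
    "approx.", "Dr.", "No.", "Ref.", "Eq.", "resp.", "sp.", "spp.")
}

#' Split text into sentences
#'
#' A boundary opens after `.`, `?` or `!` when followed by whitespace and an
#' uppercase letter or digit. Periods that terminate a protected abbreviation
#' or sit inside a decimal number never split. Sentence spans are trimmed to
#' exclude surrounding whitespace and cover all non-whitespace text.
#'
#' @param text A character scalar.
#' @param protected Character vector of protected abbreviations.
#' @return A data.frame with columns `index` (0-based ordinal), `start`, `end`
#'   (0-based, half-open character offsets).
#' @export
split_sentences <- function(text, protected = protected_abbreviations()) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(index = integer(), start = integer(), end = integer())
  if (is.na(text) || !nzchar(trimws(text))) return(empty)

  n <- nchar(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  boundaries <- integer(0)   # 1-based index of the terminator character

  for (i in seq_len(n)) {
    ch <- chars[i]
    if (!ch %in% c(".", "?", "!")) next
    # must be followed by whitespace then uppercase letter or digit
    j <- i + 1L
    if (j > n || !grepl("^\\s$", chars[j])) next
    while (j <= n && grepl("^\\s$", chars[j])) j <- j + 1L
    if (j > n) { boundaries <- c(boundaries, i); next }
    if (!grepl("^[A-Z0-9]$", chars[j])) next
    if (ch == ".") {
      # decimal number guard: digit.digit never splits (handled by the
      # whitespace requirement above) but "3." before "5 mM" could; require
      # the period not be preceded AND followed by digits without space --
      # already ensured. Protected abbreviation guard:
      prefix <- substr(text, max(1L, i - 12L), i)
      hit <- FALSE
      for (ab in protected) {
        if (nchar(prefix) >= nchar(ab) &&
            substr(prefix, nchar(prefix) - nchar(ab) + 1L,
                   nchar(prefix)) == ab) {
          # whole-word: char before the abbreviation must not be a letter
          k <- i - nchar(ab)
          if (k < 1L || !grepl("^[A-Za-z]$", substr(text, k, k))) {
            hit <- TRUE; break
          }
        }
      }
      if (hit) next
      # single capital-letter initial ("A. B.") is split per the base rule
    }
    boundaries <- c(boundaries, i)
  }

  cut_starts <- c(1L, boundaries + 1L)
  cut_ends <- c(boundaries, n)
  keep <- cut_starts <= cut_ends
  cut_starts <- cut_starts[keep]; cut_ends <- cut_ends[keep]

  out <- empty
  idx <- 0L
  for (k in seq_along(cut_starts)) {
    seg <- substr(text, cut_starts[k], cut_ends[k])
    lead_ws <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail_ws <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    s <- cut_starts[k] + lead_ws
    e <- cut_ends[k] - trail_ws
    if (s > e) next
    out <- rbind(out, data.frame(index = idx, start = s - 1L, end = e))
    idx <- idx + 1L
  }
  out
}

#' Build a document with sentence and token annotations
#'
#' @param text Full document text (UTF-8 character scalar).
#' @param doc_id Opaque document identifier.
#' @param protected Protected abbreviations for [split_sentences()].
#' @return An object of class `mi_document`: a list with `doc_id`, `text`,
#'   `sentences` (data.frame) and `tokens` (data.frame with a `sentence`
#'   column giving the owning sentence index, 0-based).
#' @export
mi_document <- function(text, doc_id = "doc", protected = protected_abbreviations()) {
  sent <- split_sentences(text, protected)
  tok <- tokenize(text)
  if (nrow(tok) > 0L) {
    tok$sentence <- NA_integer_
    for (i in seq_len(nrow(sent))) {
      inside <- tok$start >= sent$start[i] & tok$end <= sent$end[i]
      tok$sentence[inside] <- sent$index[i]
    }
  } else {
    tok$sentence <- integer(0)
  }
  structure(list(doc_id = doc_id, text = text, sentences = sent,
                 tokens = tok),
            class = "mi_document")
}

#' @export
print.mi_document <- function(x, ...) {
  cat(sprintf("<mi_document '%s': %d chars, %d sentences, %d tokens>\n",
              x$doc_id, nchar(x$text), nrow(x$sentences), nrow(x$tokens)))
  invisible(x)
}

# substring of document text for a 0-based half-open span
span_text <- function(text, start, end) substr(text, start + 1L, end)

# tokens of one sentence (by 0-based sentence index)
sentence_tokens <- function(doc, index) {
  doc$tokens[!is.na(doc$tokens$sentence) & doc$tokens$sentence == index, ,
             drop = FALSE]
}
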