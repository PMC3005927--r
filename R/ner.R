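# Named entity recognition: point mutation mentions (with wNm normalization),
# protein/gene/organism gazetteer matching, protein-property mentions
# (function noun phrases and kinetic variables) and directionality words.

RESIDUE_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V")

RESIDUE_NAME_TO_ONE <- c(
  alanine = "A", arginine = "R", asparagine = "N", aspartate = "D",
  "aspartic acid" = "D", cysteine = "C", glutamine = "Q", glutamate = "E",
  "glutamic acid" = "E", glycine = "G", histidine = "H", isoleucine = "I",
  leucine = "L", lysine = "K", methionine = "M", phenylalanine = "F",
  proline = "P", serine = "S", threonine = "T", tryptophan = "W",
  tyrosine = "Y", valine = "V")

three_letter_alt <- function() paste(names(RESIDUE_THREE_TO_ONE), collapse = "|")

empty_mutations <- function() {
  data.frame(start = integer(), end = integer(), surface = character(),
             wildtype = character(), position = integer(),
             mutant = character(), normalized = character(),
             sentence = integer(), stringsAsFactors = FALSE)
}

#' Normalize a raw mutation mention to wNm form
#'
#' Accepts one-letter ("W125F") and three-letter ("Trp125Phe") substitution
#' strings. Unknown residue codes, or identical wildtype and mutant residues,
#' reject the mention (return `NULL`). Normalization is idempotent:
#' normalizing an already-normalized mention returns it unchanged.
#'
#' @param raw A character scalar mutation mention.
#' @return A list with `wildtype`, `position`, `mutant`, `normalized`, or
#'   `NULL` when the mention is rejected.
#' @export
normalize_mutation <- function(raw) {
  m1 <- regmatches(raw, regexec("^([A-Za-z])([1-9][0-9]*)([A-Za-z])$", raw))[[1]]
  if (length(m1) == 4L) {
    w <- toupper(m1[2]); mt <- toupper(m1[4])
    if (!(w %in% RESIDUE_THREE_TO_ONE) || !(mt %in% RESIDUE_THREE_TO_ONE))
      return(NULL)
    if (w == mt) return(NULL)
    pos <- as.integer(m1[3])
    return(list(wildtype = w, position = pos, mutant = mt,
                normalized = paste0(w, pos, mt)))
  }
  m3 <- regmatches(raw,
                   regexec("^([A-Za-z]{3})-?([1-9][0-9]*)-?([A-Za-z]{3})$", raw))[[1]]
  if (length(m3) == 4L) {
    key_w <- paste0(toupper(substr(m3[2], 1, 1)), tolower(substr(m3[2], 2, 3)))
    key_m <- paste0(toupper(substr(m3[4], 1, 1)), tolower(substr(m3[4], 2, 3)))
    w <- unname(RESIDUE_THREE_TO_ONE[key_w])
    mt <- unname(RESIDUE_THREE_TO_ONE[key_m])
    if (is.na(w) || is.na(mt) || w == mt) return(NULL)
    pos <- as.integer(m3[3])
    return(list(wildtype = w, position = pos, mutant = mt,
                normalized = paste0(w, pos, mt)))
  }
  NULL
}

# all regex matches with positions; returns data.frame(start0, end0, surface)
regex_spans <- function(text, pattern) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(), end = integer(),
                      surface = character(), stringsAsFactors = FALSE))
  st <- as.integer(m); len <- attr(m, "match.length")
  data.frame(start = st - 1L, end = st + len - 1L,
             surface = substring(text, st, st + len - 1L),
             stringsAsFactors = FALSE)
}

#' Find point mutation mentions in a document
#'
#' Three pattern families are matched, in order of precedence:
#' \enumerate{
#'   \item one-letter wNm, e.g. "W125F";
#'   \item three-letter wNm, e.g. "Trp125Phe" (series joined by "+", such as
#'     "Arg172Lys+His65Ala", yield one mention per member);
#'   \item three-letter "Xxx-123" (or "Xxx123") mentions inside a
#'     "replacement/mutation/substitution of ... with/to/by <residue name>"
#'     frame, e.g. "Replacement of Trp-125 with arginine".
#' }
#' A word-boundary guard rejects matches embedded in longer alphanumeric
#' identifiers (strain names such as "GJ10" never match). Mentions whose
#' wildtype equals the mutant residue are rejected.
#'
#' @param doc An [mi_document()].
#' @return A data.frame with span, residue fields, `normalized` wNm string
#'   and owning `sentence` index.
#' @export
find_mutation_mentions <- function(doc) {
  text <- doc$text
  out <- empty_mutations()
  aa <- "[ACDEFGHIKLMNPQRSTVWY]"
  tl <- three_letter_alt()

  add <- function(out, start, end, surface) {
    nm <- normalize_mutation(surface)
    if (is.null(nm)) return(out)
    rbind(out, data.frame(start = start, end = end, surface = surface,
                          wildtype = nm$wildtype, position = nm$position,
                          mutant = nm$mutant, normalized = nm$normalized,
                          sentence = NA_integer_, stringsAsFactors = FALSE))
  }

  # (a) one-letter wNm
  pat1 <- sprintf("(?<![A-Za-z0-9])%s[1-9][0-9]*%s(?![A-Za-z0-9])", aa, aa)
  sp <- regex_spans(text, pat1)
  for (i in seq_len(nrow(sp))) out <- add(out, sp$start[i], sp$end[i], sp$surface[i])

  # (b) three-letter wNm (case-insensitive residue codes)
  pat3 <- sprintf("(?i)(?<![A-Za-z0-9])(?:%s)[1-9][0-9]*(?:%s)(?![A-Za-z0-9])",
                  tl, tl)
  sp <- regex_spans(text, pat3)
  for (i in seq_len(nrow(sp))) {
    if (any(sp$start[i] < out$end & sp$end[i] > out$start)) next
    out <- add(out, sp$start[i], sp$end[i], sp$surface[i])
  }

  # (c) natural-language frame: "replacement of Trp-125 ... with arginine"
  frame <- sprintf(paste0(
    "(?i)\\b(?:replacement|mutation|substitution)s?\\s+of\\s+",
    "((?:%s)-?[1-9][0-9]*",
    "(?:\\s*(?:,|,?\\s+or|,?\\s+and)\\s+(?:%s)-?[1-9][0-9]*)*)",
    "\\s+(?:with|to|by)\\s+(%s)\\b"), tl, tl,
    paste(names(RESIDUE_NAME_TO_ONE), collapse = "|"))
  m <- gregexpr(frame, text, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    st <- as.integer(m); len <- attr(m, "match.length")
    for (k in seq_along(st)) {
      whole <- substring(text, st[k], st[k] + len[k] - 1L)
      parts <- regmatches(whole, regexec(frame, whole, perl = TRUE))[[1]]
      mut_res <- unname(RESIDUE_NAME_TO_ONE[tolower(parts[3])])
      item_pat <- sprintf("(?i)(%s)-?([1-9][0-9]*)", tl)
      items <- gregexpr(item_pat, whole, perl = TRUE)[[1]]
      ist <- as.integer(items); ilen <- attr(items, "match.length")
      for (j in seq_along(ist)) {
        isurf <- substring(whole, ist[j], ist[j] + ilen[j] - 1L)
        ip <- regmatches(isurf, regexec(item_pat, isurf, perl = TRUE))[[1]]
        key_w <- paste0(toupper(substr(ip[2], 1, 1)), tolower(substr(ip[2], 2, 3)))
        w <- unname(RESIDUE_THREE_TO_ONE[key_w])
        if (is.na(w) || is.na(mut_res) || w == mut_res) next
        s0 <- st[k] + ist[j] - 2L           # 0-based start of the item
        e0 <- s0 + ilen[j]
        if (any(s0 < out$end & e0 > out$start)) next
        out <- rbind(out, data.frame(
          start = s0, end = e0, surface = isurf, wildtype = w,
          position = as.integer(ip[3]), mutant = mut_res,
          normalized = paste0(w, ip[3], mut_res),
          sentence = NA_integer_, stringsAsFactors = FALSE))
      }
    }
  }

  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$sentence <- assign_sentence(out$start, doc$sentences)
  out
}

assign_sentence <- function(starts, sentences) {
  vapply(starts, function(s) {
    hit <- which(sentences$start <= s & s < sentences$end)
    if (length(hit)) sentences$index[hit[1]] else NA_integer_
  }, integer(1))
}

#' Find protein, gene and organism mentions via gazetteer matching
#'
#' Multiword names are matched case-insensitively (recall on long names);
#' single-word names case-sensitively (precision on short names); organism
#' names always case-insensitively. At each token position the longest
#' matching name wins, with ties broken left-to-right; a matched span is
#' never re-entered, so overlapping names yield only the longest annotation.
#'
#' @param doc An [mi_document()].
#' @param lex A `protein_lexicon`.
#' @return A data.frame with `start`, `end`, `kind` (Protein/Gene/Organism),
#'   `surface`, `name` (canonical lexicon name) and a list column
#'   `accessions`.
#' @export
find_entity_mentions <- function(doc, lex) {
  tok <- doc$tokens
  out <- data.frame(start = integer(), end = integer(), kind = character(),
                    surface = character(), name = character(),
                    stringsAsFactors = FALSE)
  out$accessions <- list()
  if (nrow(tok) == 0L) return(out)

  # candidate table: protein/gene names plus organism names
  cand <- lex$names[, c("name", "kind", "multiword", "case_sensitive")]
  if (length(lex$organisms)) {
    cand <- rbind(cand, data.frame(
      name = lex$organisms, kind = "Organism",
      multiword = vapply(lex$organisms,
                         function(x) length(strsplit(trimws(x), "\\s+")[[1]]) >= 2L,
                         logical(1)),
      case_sensitive = FALSE, stringsAsFactors = FALSE))
  }
  cand <- unique(cand)
  if (nrow(cand) == 0L) return(out)
  cand$toks <- lapply(strsplit(cand$name, "\\s+"), function(x) x[nzchar(x)])
  cand$ntok <- lengths(cand$toks)
  cand <- cand[order(-cand$ntok, -nchar(cand$name)), , drop = FALSE]

  accs_for <- function(name, kind) {
    if (kind == "Organism") return(character(0))
    sort(unique(lex$names$accession[lex$names$name == name &
                                    lex$names$kind == kind]))
  }

  i <- 1L
  n <- nrow(tok)
  while (i <= n) {
    matched <- FALSE
    for (ci in seq_len(nrow(cand))) {
      k <- cand$ntok[ci]
      if (k == 0L || i + k - 1L > n) next
      segment <- tok$surface[i:(i + k - 1L)]
      target <- cand$toks[[ci]]
      ok <- if (cand$case_sensitive[ci]) identical(segment, target)
            else identical(tolower(segment), tolower(target))
      if (!ok) next
      s0 <- tok$start[i]; e0 <- tok$end[i + k - 1L]
      row <- data.frame(start = s0, end = e0, kind = cand$kind[ci],
                        surface = span_text(doc$text, s0, e0),
                        name = cand$name[ci], stringsAsFactors = FALSE)
      row$accessions <- list(accs_for(cand$name[ci], cand$kind[ci]))
      out <- rbind(out, row)
      i <- i + k
      matched <- TRUE
      break
    }
    if (!matched) i <- i + 1L
  }
  out$sentence <- assign_sentence(out$start, doc$sentences)
  rownames(out) <- NULL
  out
}

KINETIC_PATTERNS <- list(
  KCAT_OVER_KM = "^[kK]_?\\(?cat\\)?_?/K_?\\(?[mM]\\)?_?$",
  KCAT = "^[kK]_?\\(?cat\\)?_?$",
  KM = "^K_?\\(?[mM]\\)?_?$")

FUNCTION_HEAD_NOUNS <- c("activity", "binding", "affinity", "specificity")

#' Find protein-property mentions in one sentence
#'
#' Function properties are noun phrases ending in one of the head nouns
#' "activity", "binding", "affinity" or "specificity": the maximal contiguous
#' run of content words (no stop words, no detached punctuation, no
#' directionality words, no tokens containing digits) ending at the head.
#' Kinetic variables are whole-token surface variants of KM ("Km", "K_m",
#' "K(m)", "KM"), kcat ("kcat", "k_cat", "k(cat)") and the compound kcat/KM;
#' whole-token anchoring gives the compound precedence over its parts and
#' rejects variables fused with further mathematics ("Km=5").
#'
#' @param doc An [mi_document()].
#' @param sentence_index 0-based sentence ordinal.
#' @param dlex A `direction_lexicon` (used to keep direction words out of
#'   noun phrases).
#' @return A data.frame with `start`, `end`, `kind` ("function"/"kinetic"),
#'   `head`, `variable` and list column `np_tokens`.
#' @export
find_property_mentions <- function(doc, sentence_index,
                                   dlex = build_direction_lexicon()) {
  tok <- sentence_tokens(doc, sentence_index)
  out <- data.frame(start = integer(), end = integer(), kind = character(),
                    head = character(), variable = character(),
                    stringsAsFactors = FALSE)
  out$np_tokens <- list()
  if (nrow(tok) == 0L) { out$sentence <- integer(0); return(out) }

  dwords <- tolower(dlex$word)
  stops <- mi_stopwords()
  is_content <- function(j) {
    s <- tok$surface[j]
    tok$is_space_delimited[j] &&
      !grepl("[0-9]", s) &&
      grepl("[A-Za-z]", s) &&
      !(tolower(s) %in% stops) &&
      !(tolower(s) %in% dwords) &&
      !any(vapply(KINETIC_PATTERNS, function(p) grepl(p, s), logical(1)))
  }

  # kinetic variables: whole-token matches, compound first
  for (j in seq_len(nrow(tok))) {
    s <- tok$surface[j]
    for (vn in names(KINETIC_PATTERNS)) {
      if (grepl(KINETIC_PATTERNS[[vn]], s)) {
        row <- data.frame(start = tok$start[j], end = tok$end[j],
                          kind = "kinetic", head = s, variable = vn,
                          stringsAsFactors = FALSE)
        row$np_tokens <- list(character(0))
        out <- rbind(out, row)
        break
      }
    }
  }

  # function noun phrases: content runs ending at a head noun
  content <- vapply(seq_len(nrow(tok)), is_content, logical(1))
  heads <- which(tolower(tok$surface) %in% FUNCTION_HEAD_NOUNS)
  used <- rep(FALSE, nrow(tok))
  # rightmost head of a content run is the head noun of that noun phrase
  for (h in rev(heads)) {
    if (used[h]) next
    j <- h
    while (j - 1L >= 1L && content[j - 1L]) j <- j - 1L
    np <- tok$surface[j:h]
    row <- data.frame(start = tok$start[j], end = tok$end[h],
                      kind = "function", head = tolower(tok$surface[h]),
                      variable = NA_character_, stringsAsFactors = FALSE)
    row$np_tokens <- list(np)
    out <- rbind(out, row)
    used[j:h] <- TRUE
  }

  out <- out[order(out$start), , drop = FALSE]
  out$sentence <- rep(sentence_index, nrow(out))
  rownames(out) <- NULL
  out
}

#' Find directionality words in one sentence
#'
#' Whole-token, case-insensitive matches against the expanded direction
#' lexicon; each match is labeled with its category.
#'
#' @param doc An [mi_document()].
#' @param sentence_index 0-based sentence ordinal.
#' @param dlex A `direction_lexicon`.
#' @return A data.frame with `start`, `end`, `surface`, `category`.
#' @export
find_direction_terms <- function(doc, sentence_index, dlex) {
  tok <- sentence_tokens(doc, sentence_index)
  hit <- match(tolower(tok$surface), tolower(dlex$word))
  keep <- !is.na(hit)
  data.frame(start = tok$start[keep], end = tok$end[keep],
             surface = tok$surface[keep],
             category = dlex$category[hit[keep]],
             sentence = rep(sentence_index, sum(keep)),
             stringsAsFactors = FALSE)
}
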