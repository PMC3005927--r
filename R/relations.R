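# Relation detection: split sentences into one-property segments, pair
# directionality terms with properties into scored impact statements, link
# impacts to grounded mutants by sentence distance, resolve contradictions
# by combined mean score.

#' Split a sentence into one-property segments
#'
#' A sentence with two or more property mentions is split between consecutive
#' properties at a comma token or the token "and"; when neither occurs in the
#' gap, the split falls immediately before the later property. A sentence
#' with zero or one property is a single segment.
#'
#' @param doc An [mi_document()].
#' @param sentence_index 0-based sentence ordinal.
#' @param properties Property mentions of that sentence (data.frame from
#'   [find_property_mentions()]), sorted by position.
#' @return List of segments, each a list with `start`, `end` (character
#'   span) and `property` (row index into `properties`, or NA).
#' @export
segment_properties <- function(doc, sentence_index, properties) {
  sent <- doc$sentences[doc$sentences$index == sentence_index, ]
  stopifnot(nrow(sent) == 1L)
  if (nrow(properties) <= 1L) {
    return(list(list(start = sent$start, end = sent$end,
                     property = if (nrow(properties)) 1L else NA_integer_)))
  }
  properties <- properties[order(properties$start), , drop = FALSE]
  tok <- sentence_tokens(doc, sentence_index)
  cuts <- integer(0)   # character offset at which the next segment starts
  for (i in seq_len(nrow(properties) - 1L)) {
    gap_tok <- tok[tok$start >= properties$end[i] &
                   tok$end <= properties$start[i + 1L], , drop = FALSE]
    delim <- which(gap_tok$surface == "," | tolower(gap_tok$surface) == "and")
    if (length(delim)) {
      cuts <- c(cuts, gap_tok$end[delim[1]])
    } else {
      cuts <- c(cuts, properties$start[i + 1L])
    }
  }
  bounds <- c(sent$start, cuts, sent$end)
  lapply(seq_len(nrow(properties)), function(i) {
    list(start = bounds[i], end = bounds[i + 1L], property = i)
  })
}

# number of space-delimited tokens strictly between two character spans,
# plus one; the unit of the impact score. A term inside the property noun
# phrase has distance 1 by definition.
token_distance <- function(tok, span_a, span_b) {
  lo <- min(span_a[2], span_b[2])
  hi <- max(span_a[1], span_b[1])
  if (lo > hi) return(1L)   # overlapping spans
  between <- tok$is_space_delimited & tok$start >= lo & tok$end <= hi
  sum(between) + 1L
}

#' Classify the impact expressed in a one-property segment
#'
#' The non-negation direction term nearest the property (in space tokens)
#' determines the direction; ties go to the leftmost term. A negation term
#' within two space tokens before the chosen term remaps the category:
#' positive -> neutral, negative -> neutral, neutral -> non_neutral,
#' non_neutral -> neutral. The impact score is 1 / tokenDistance, with the
#' distance set to 1 when the term lies inside the property noun phrase.
#'
#' @param doc An [mi_document()].
#' @param segment One segment from [segment_properties()].
#' @param property The property mention row (one-row data.frame).
#' @param directions Direction terms of the sentence (data.frame).
#' @return A list with `direction`, `token_distance`, `impact_score`,
#'   `term_surface`, or `NULL` when the segment holds no direction term.
#' @export
classify_impact <- function(doc, segment, property, directions) {
  inseg <- directions[directions$start >= segment$start &
                      directions$end <= segment$end, , drop = FALSE]
  terms <- inseg[inseg$category != "negation", , drop = FALSE]
  if (nrow(terms) == 0L) return(NULL)
  tok <- doc$tokens
  pspan <- c(property$start, property$end)
  d <- vapply(seq_len(nrow(terms)), function(i) {
    if (terms$start[i] >= property$start && terms$end[i] <= property$end)
      return(1L)
    token_distance(tok, c(terms$start[i], terms$end[i]), pspan)
  }, integer(1))
  pick <- which(d == min(d))[1]
  chosen <- terms[pick, ]
  category <- chosen$category

  negs <- inseg[inseg$category == "negation" & inseg$end <= chosen$start, ,
                drop = FALSE]
  if (nrow(negs)) {
    gaps <- vapply(seq_len(nrow(negs)), function(i) {
      sum(tok$is_space_delimited & tok$start >= negs$end[i] &
            tok$end <= chosen$start)
    }, integer(1))
    if (any(gaps <= 1L)) {
      category <- switch(category,
                         positive = "neutral", negative = "neutral",
                         neutral = "non_neutral", non_neutral = "neutral")
    }
  }
  td <- d[pick]
  list(direction = category, token_distance = td, impact_score = 1 / td,
       term_surface = chosen$surface, term_start = chosen$start)
}

#' Extract impact statements for every sentence of a document
#'
#' Convenience driver over [segment_properties()] and [classify_impact()].
#'
#' @param doc An [mi_document()].
#' @param properties All property mentions (data.frame with `sentence`).
#' @param directions All direction terms (data.frame with `sentence`).
#' @return A data.frame of impact statements with the property fields
#'   attached (`prop_start`, `prop_end`, `prop_kind`, `prop_head`,
#'   `variable`, list column `np_tokens`).
#' @export
extract_impacts <- function(doc, properties, directions) {
  out <- data.frame(sentence = integer(), direction = character(),
                    token_distance = integer(), impact_score = numeric(),
                    prop_start = integer(), prop_end = integer(),
                    prop_kind = character(), prop_head = character(),
                    variable = character(), stringsAsFactors = FALSE)
  out$np_tokens <- list()
  for (s in doc$sentences$index) {
    props <- properties[properties$sentence == s, , drop = FALSE]
    if (nrow(props) == 0L) next
    props <- props[order(props$start), , drop = FALSE]
    dirs <- directions[directions$sentence == s, , drop = FALSE]
    segs <- segment_properties(doc, s, props)
    for (seg in segs) {
      if (is.na(seg$property)) next
      prop <- props[seg$property, , drop = FALSE]
      imp <- classify_impact(doc, seg, prop, dirs)
      if (is.null(imp)) next
      row <- data.frame(sentence = s, direction = imp$direction,
                        token_distance = imp$token_distance,
                        impact_score = imp$impact_score,
                        prop_start = prop$start, prop_end = prop$end,
                        prop_kind = prop$kind, prop_head = prop$head,
                        variable = prop$variable, stringsAsFactors = FALSE)
      row$np_tokens <- prop$np_tokens
      out <- rbind(out, row)
    }
  }
  rownames(out) <- NULL
  out
}

#' Link impact statements to grounded mutant mentions by sentence distance
#'
#' For each impact, the same sentence and then up to three previous sentences
#' are searched; the nearest non-empty set of grounded mutation mentions all
#' receive the relation, with relation score 1 / sentenceDistance
#' (sentenceDistance = 1 for the same sentence, up to 4 for three sentences
#' back). Mentions in following sentences are never linked. An impact with
#' no mention inside the window produces no relation.
#'
#' @param impacts Data.frame from [extract_impacts()].
#' @param mentions Grounded mutation mention occurrences (data.frame with
#'   `normalized` and `sentence`).
#' @return A data.frame of raw relations (one row per impact x linked
#'   mutant) with `sentence_distance` and `relation_score`.
#' @export
link_mutants <- function(impacts, mentions) {
  out <- impacts[0, , drop = FALSE]
  out$mutation <- character(0)
  out$sentence_distance <- integer(0)
  out$relation_score <- numeric(0)
  for (i in seq_len(nrow(impacts))) {
    s <- impacts$sentence[i]
    for (k in 0:3) {
      hits <- unique(mentions$normalized[!is.na(mentions$sentence) &
                                         mentions$sentence == s - k])
      if (length(hits)) {
        for (m in hits) {
          row <- impacts[i, , drop = FALSE]
          row$mutation <- m
          row$sentence_distance <- k + 1L
          row$relation_score <- 1 / (k + 1L)
          out <- rbind(out, row)
        }
        break
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Resolve contradictory relations by combined mean score
#'
#' The combined score of a relation is the arithmetic mean of its relation
#' score, impact score and (for grounded function properties) the GO
#' similarity score; for kinetic variables and ungrounded function mentions
#' the similarity term is omitted. Among relations that share a
#' (mutant, property) key but disagree on direction, only the relation with
#' the highest combined score survives; ties keep the relation occurring
#' earliest in the document.
#'
#' @param relations Data.frame with `mutation`, `direction`, `property_key`,
#'   `relation_score`, `impact_score`, `similarity` (NA when not measured),
#'   `sentence`, `prop_start`.
#' @return The filtered relations data.frame with `combined_score` attached.
#' @export
resolve_contradictions <- function(relations) {
  if (nrow(relations) == 0L) {
    relations$combined_score <- numeric(0)
    return(relations)
  }
  relations$combined_score <- vapply(seq_len(nrow(relations)), function(i) {
    parts <- c(relations$relation_score[i], relations$impact_score[i])
    if (!is.na(relations$similarity[i])) parts <- c(parts, relations$similarity[i])
    mean(parts)
  }, numeric(1))
  key <- paste(relations$mutation, relations$property_key, sep = "\r")
  keep <- rep(TRUE, nrow(relations))
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(unique(relations$direction[idx])) <= 1L) next
    ord <- idx[order(-relations$combined_score[idx], relations$sentence[idx],
                     relations$prop_start[idx])]
    keep[idx] <- FALSE
    keep[ord[1]] <- TRUE
  }
  out <- relations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
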