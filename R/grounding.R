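# Grounding: protein mentions -> candidate accession pool; mutation sets ->
# sequence positions via pairwise regular expressions with displacement
# detection; function mentions -> GO concepts scored by stemmed-token
# similarity.

#' Build the candidate accession pool for a document
#'
#' Accessions of every matched protein/gene name are pooled, together with
#' accessions of lexicon names equal to a matched name followed by an
#' alphanumeric suffix (so a mention "DhlA" also pulls in "DhlA2"). The pool
#' is trimmed to accessions whose mention support is at least
#' `ceiling(f * max_support)`. When the document mentions at least one
#' organism, accessions not associated with any mentioned organism are then
#' discarded; if that filter empties the pool, the trimmed pre-filter pool is
#' kept with a warning.
#'
#' @param entities Entity annotations from [find_entity_mentions()].
#' @param lex A `protein_lexicon`.
#' @param f Trimming fraction in (0, 1]; default 0.5.
#' @return An object of class `candidate_pool`: list with `accessions`
#'   (data.frame of `accession`, `support`) and `organism_filtered` flag.
#' @export
build_candidate_pool <- function(entities, lex, f = 0.5) {
  support <- list()
  bump <- function(support, accs) {
    for (a in accs) support[[a]] <- (support[[a]] %||% 0L) + 1L
    support
  }
  pg <- entities[entities$kind %in% c("Protein", "Gene"), , drop = FALSE]
  all_names <- lex$names
  for (i in seq_len(nrow(pg))) {
    accs <- pg$accessions[[i]]
    nm <- pg$name[i]
    # suffix expansion: lexicon names that extend this name alphanumerically
    ext <- all_names$name[
      tolower(substr(all_names$name, 1L, nchar(nm))) == tolower(nm) &
      nchar(all_names$name) > nchar(nm) &
      grepl("^[A-Za-z0-9]+$",
            substr(all_names$name, nchar(nm) + 1L, nchar(all_names$name)))]
    if (length(ext))
      accs <- union(accs, all_names$accession[all_names$name %in% ext])
    support <- bump(support, accs)
  }
  if (length(support) == 0L) {
    return(structure(list(
      accessions = data.frame(accession = character(), support = integer(),
                              stringsAsFactors = FALSE),
      organism_filtered = FALSE), class = "candidate_pool"))
  }
  df <- data.frame(accession = names(support),
                   support = unlist(support, use.names = FALSE),
                   stringsAsFactors = FALSE)
  thr <- ceiling(f * max(df$support))
  df <- df[df$support >= thr, , drop = FALSE]

  org_mentions <- unique(tolower(entities$name[entities$kind == "Organism"]))
  filtered <- FALSE
  if (length(org_mentions)) {
    keep <- vapply(df$accession, function(a) {
      orgs <- tolower(lex$accession_to_organism[[a]])
      length(orgs) > 0L && any(orgs %in% org_mentions)
    }, logical(1))
    if (any(keep)) {
      df <- df[keep, , drop = FALSE]
      filtered <- TRUE
    } else {
      warning("organism filter removed every candidate; keeping unfiltered pool")
    }
  }
  df <- df[order(df$accession), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(accessions = df, organism_filtered = filtered),
            class = "candidate_pool")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the pairwise regular expression for two mutation mentions
#'
#' For mentions w1N1m1 and w2N2m2 (sorted so N1 < N2) the pattern is the
#' wildtype residue of the first, exactly N2 - N1 - 1 single-character
#' wildcards, then the wildtype residue of the second: A378C and S381L give
#' "A..S".
#'
#' @param m1,m2 Lists or one-row data.frames with `wildtype` and `position`.
#' @return Pattern string, or `NULL` when the positions are equal (the pair
#'   is skipped).
#' @export
build_pair_regex <- function(m1, m2) {
  p1 <- as.integer(m1$position); p2 <- as.integer(m2$position)
  if (p1 == p2) return(NULL)
  if (p1 > p2) { tmp <- m1; m1 <- m2; m2 <- tmp; tmp <- p1; p1 <- p2; p2 <- tmp }
  paste0(m1$wildtype, strrep(".", p2 - p1 - 1L), m2$wildtype)
}

# all (overlapping) 1-based match starts of `pattern` in `seq`
regex_match_starts <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Ground a set of mutation mentions onto candidate sequences
#'
#' For every candidate accession and every pair of mentions (distinct
#' positions), the pairwise regular expression of [build_pair_regex()] is
#' matched at all overlapping offsets of the sequence. Each match proposes a
#' numbering displacement d = match start (1-based) - N1; all mentions are
#' then verified against the sequence at position N + d. The
#' (accession, displacement) candidate grounding the most mentions wins;
#' ties are broken by smaller |d|, then lexicographically smaller accession,
#' then smaller d. Mentions that do not verify under the winner are
#' discarded.
#'
#' @param mentions Mutation mentions (data.frame from
#'   [find_mutation_mentions()]); duplicates by `normalized` collapse to one.
#' @param pool A `candidate_pool`.
#' @param lex A `protein_lexicon` (supplies sequences).
#' @param max_displacement Displacement search bound (default 10).
#' @return An object of class `grounding_result`: list with `accession`,
#'   `sequence`, `displacement`, `grounded` (data.frame incl. the grounded
#'   1-based `seq_position`) and `discarded`.
#' @export
ground_mutations <- function(mentions, pool, lex, max_displacement = 10L) {
  uniq <- mentions[!duplicated(mentions$normalized), , drop = FALSE]
  if (nrow(uniq) < 2L)
    stop("mutation grounding requires at least two distinct mutation mentions")
  accs <- pool$accessions$accession
  if (length(accs) == 0L) stop("candidate pool is empty")

  empty_res <- function() {
    structure(list(accession = NA_character_, sequence = NA_character_,
                   displacement = NA_integer_,
                   grounded = uniq[0, , drop = FALSE],
                   discarded = uniq), class = "grounding_result")
  }

  verify_count <- function(seq, d) {
    ok <- logical(nrow(uniq))
    for (i in seq_len(nrow(uniq))) {
      p <- uniq$position[i] + d
      ok[i] <- p >= 1L && p <= nchar(seq) &&
        substr(seq, p, p) == uniq$wildtype[i]
    }
    ok
  }

  cands <- data.frame(accession = character(), d = integer(),
                      count = integer(), stringsAsFactors = FALSE)
  pairs <- if (nrow(uniq) >= 2L) utils::combn(nrow(uniq), 2L) else NULL
  for (acc in accs) {
    seq <- lex$accession_to_sequence[[acc]]
    if (is.null(seq)) next
    seen_d <- integer(0)
    for (pc in seq_len(ncol(pairs))) {
      i <- pairs[1, pc]; j <- pairs[2, pc]
      pat <- build_pair_regex(uniq[i, ], uniq[j, ])
      if (is.null(pat)) next
      n1 <- min(uniq$position[i], uniq$position[j])
      for (st in regex_match_starts(seq, pat)) {
        d <- st - n1
        if (abs(d) > max_displacement || d %in% seen_d) next
        seen_d <- c(seen_d, d)
        cands <- rbind(cands, data.frame(
          accession = acc, d = d, count = sum(verify_count(seq, d)),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (nrow(cands) == 0L) return(empty_res())
  cands <- cands[order(-cands$count, abs(cands$d), cands$accession, cands$d), ,
                 drop = FALSE]
  best <- cands[1, ]
  seq <- lex$accession_to_sequence[[best$accession]]
  ok <- verify_count(seq, best$d)
  grounded <- uniq[ok, , drop = FALSE]
  grounded$seq_position <- grounded$position + best$d
  structure(list(accession = best$accession, sequence = seq,
                 displacement = as.integer(best$d), grounded = grounded,
                 discarded = uniq[!ok, , drop = FALSE]),
            class = "grounding_result")
}

#' @export
print.grounding_result <- function(x, ...) {
  cat(sprintf("<grounding_result: %s (d=%s), %d grounded, %d discarded>\n",
              x$accession, x$displacement, nrow(x$grounded),
              nrow(x$discarded)))
  invisible(x)
}

#' Prepare a phrase for token-set similarity
#'
#' Splits on non-alphanumeric characters, lowercases, removes stop words and
#' stems with the English Porter stemmer, returning the unique stem set.
#'
#' @param words Character vector (words or whole phrases).
#' @param stopwords Stop-word list.
#' @return Sorted character vector of unique stems.
#' @export
prepare_tokens <- function(words, stopwords = mi_stopwords()) {
  toks <- unlist(strsplit(tolower(words), "[^a-z0-9]+"))
  toks <- toks[nzchar(toks)]
  toks <- toks[!(toks %in% stopwords)]
  if (!length(toks)) return(character(0))
  sort(unique(porter_stem(toks)))
}

#' Relative intersection of two prepared token sets
#'
#' The default is the Jaccard index |N∩G| / |N∪G|, which is symmetric and
#' bounded in \[0, 1\]; `"over_g"` (|N∩G|/|G|) and `"over_n"` (|N∩G|/|N|)
#' are available as alternatives.
#'
#' @param n,g Character vectors (prepared token sets).
#' @param method One of "jaccard", "over_g", "over_n".
#' @return Similarity in \[0, 1\] (0 when the denominator set is empty).
#' @export
relative_intersection <- function(n, g, method = c("jaccard", "over_g", "over_n")) {
  method <- match.arg(method)
  n <- unique(n); g <- unique(g)
  inter <- length(intersect(n, g))
  denom <- switch(method,
                  jaccard = length(union(n, g)),
                  over_g = length(g),
                  over_n = length(n))
  if (denom == 0L) return(0)
  inter / denom
}

#' Ground a function mention to a Gene Ontology concept
#'
#' Candidate concepts are the GO annotations of the pooled accessions plus
#' all their is_a ancestors. The mention's noun-phrase tokens and each
#' concept synonym are prepared with [prepare_tokens()]; the concept whose
#' best synonym maximizes [relative_intersection()] is chosen (ties go to the
#' lexicographically smallest GO id). Returns `NULL` when no candidate
#' scores above zero or the pooled accessions carry no GO annotations.
#'
#' @param np_tokens Character vector: content words of the function mention.
#' @param pool A `candidate_pool`.
#' @param lex A `protein_lexicon`.
#' @param go A `go_graph`.
#' @param method Similarity variant for [relative_intersection()].
#' @return List with `go_id` and `similarity`, or `NULL`.
#' @export
ground_function <- function(np_tokens, pool, lex, go, method = "jaccard") {
  direct <- unique(unlist(lapply(pool$accessions$accession,
                                 function(a) lex$accession_to_go[[a]])))
  direct <- direct[direct %in% names(go$concepts)]
  if (!length(direct)) return(NULL)
  cand <- unique(c(direct, unlist(lapply(direct, go_ancestors, go = go))))
  cand <- sort(cand[cand %in% names(go$concepts)])
  n <- prepare_tokens(np_tokens)
  best_id <- NA_character_; best_score <- 0
  for (id in cand) {
    for (syn in go$concepts[[id]]$synonyms) {
      s <- relative_intersection(n, prepare_tokens(syn), method)
      if (s > best_score) { best_score <- s; best_id <- id }
    }
  }
  if (best_score <= 0) return(NULL)
  list(go_id = best_id, similarity = best_score)
}
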