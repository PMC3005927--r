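# Gazetteers and mappings: protein/gene/organism names <-> accessions <->
# sequences <-> GO annotations (the mutation grounding database), the GO
# molecular-function graph, and the directionality word lists.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' English stop words used when preparing token sets for GO similarity
#' @export
mi_stopwords <- function() {
  c("a", "an", "the", "of", "and", "or", "in", "on", "at", "to", "for",
    "with", "by", "from", "as", "is", "are", "was", "were", "be", "been",
    "being", "that", "this", "these", "those", "its", "it", "their",
    "which", "into", "via", "between", "during", "through", "other",
    "such", "than", "but", "also", "both", "all", "any", "each")
}

#' Load a protein lexicon from a simplified Swiss-Prot-style flat file
#'
#' The format is a line-prefixed record grammar covering the fields the
#' pipeline consumes: `AC` (primary accession), `DE` (protein name), `GN`
#' (gene name), `OS` (organism name), `DR GO:NNNNNNN` (GO cross-reference)
#' and `SQ` (amino-acid sequence, possibly wrapped over continuation lines
#' starting with two spaces). Records are separated by `//`.
#'
#' Names with two or more whitespace-separated words are flagged for
#' case-insensitive matching (recall); single-word names are matched
#' case-sensitively (precision). Sequences are uppercased and validated
#' against the 20-letter amino-acid alphabet; a record with an invalid
#' residue, or missing AC or SQ, is rejected with a warning while the rest
#' of the file loads.
#'
#' @param path Path to the flat file.
#' @return An object of class `protein_lexicon`.
#' @export
load_protein_lexicon <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  cur <- NULL
  new_rec <- function() list(ac = NULL, de = character(0), gn = character(0),
                             os = character(0), go = character(0),
                             sq = character(0), line = NA_integer_)
  flush <- function(cur, recs) { if (!is.null(cur)) c(recs, list(cur)) else recs }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^//", ln)) { recs <- flush(cur, recs); cur <- NULL; next }
    if (!nzchar(trimws(ln))) next
    if (is.null(cur)) { cur <- new_rec(); cur$line <- i }
    tag <- substr(ln, 1L, 2L)
    val <- trimws(substr(ln, 3L, nchar(ln)))
    if (tag == "AC") cur$ac <- sub(";$", "", val)
    else if (tag == "DE") cur$de <- c(cur$de, sub("\\.$", "", val))
    else if (tag == "GN") cur$gn <- c(cur$gn, sub("\\.$", "", val))
    else if (tag == "OS") cur$os <- c(cur$os, sub("\\.$", "", val))
    else if (tag == "DR") {
      m <- regmatches(val, regexpr("GO:[0-9]+", val))
      if (length(m)) cur$go <- c(cur$go, m)
    }
    else if (tag == "SQ") cur$sq <- c(cur$sq, gsub("\\s", "", val))
    else if (grepl("^\\s\\s", ln)) cur$sq <- c(cur$sq, gsub("\\s", "", ln))
  }
  recs <- flush(cur, recs)

  lex <- empty_protein_lexicon()
  for (r in recs) {
    seq <- toupper(paste0(r$sq, collapse = ""))
    if (is.null(r$ac) || !nzchar(seq)) {
      warning(sprintf("record at line %d missing AC or SQ; skipped", r$line))
      next
    }
    if (!all(strsplit(seq, "")[[1]] %in% AA_ALPHABET)) {
      warning(sprintf("record %s: sequence contains non-standard residue; skipped",
                      r$ac))
      next
    }
    lex <- lexicon_add_record(lex, accession = r$ac, protein_names = r$de,
                              gene_names = r$gn, organisms = r$os,
                              go_ids = r$go, sequence = seq)
  }
  lex
}

#' Create an empty protein lexicon
#'
#' Use with [lexicon_add_record()] to build lexicons programmatically.
#' @export
empty_protein_lexicon <- function() {
  structure(list(
    names = data.frame(name = character(), key = character(),
                       accession = character(), kind = character(),
                       multiword = logical(), case_sensitive = logical(),
                       stringsAsFactors = FALSE),
    accession_to_sequence = list(),
    accession_to_organism = list(),
    accession_to_go = list(),
    organisms = character(0)
  ), class = "protein_lexicon")
}

#' Add one record to a protein lexicon
#'
#' Programmatic alternative to [load_protein_lexicon()]; used by the
#' synthetic-corpus generator and tests.
#' @param lex A `protein_lexicon`.
#' @param accession,protein_names,gene_names,organisms,go_ids,sequence Record
#'   fields.
#' @export
lexicon_add_record <- function(lex, accession, protein_names = character(0),
                               gene_names = character(0),
                               organisms = character(0),
                               go_ids = character(0), sequence) {
  stopifnot(inherits(lex, "protein_lexicon"))
  sequence <- toupper(sequence)
  add <- function(nm, kind) {
    multi <- length(strsplit(trimws(nm), "\\s+")[[1]]) >= 2L
    data.frame(name = nm, key = if (multi) tolower(nm) else nm,
               accession = accession, kind = kind, multiword = multi,
               case_sensitive = !multi, stringsAsFactors = FALSE)
  }
  for (nm in protein_names) lex$names <- rbind(lex$names, add(nm, "Protein"))
  for (nm in gene_names) lex$names <- rbind(lex$names, add(nm, "Gene"))
  lex$accession_to_sequence[[accession]] <- sequence
  lex$accession_to_organism[[accession]] <-
    unique(c(lex$accession_to_organism[[accession]], organisms))
  lex$accession_to_go[[accession]] <-
    unique(c(lex$accession_to_go[[accession]], go_ids))
  lex$organisms <- unique(c(lex$organisms, organisms))
  lex
}

#' @export
print.protein_lexicon <- function(x, ...) {
  cat(sprintf("<protein_lexicon: %d accessions, %d names, %d organisms>\n",
              length(x$accession_to_sequence), nrow(x$names),
              length(x$organisms)))
  invisible(x)
}

#' Serialize a protein lexicon to the simplified flat-file format
#' @param lex A `protein_lexicon`.
#' @param path Output path.
#' @export
write_protein_lexicon <- function(lex, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (acc in sort(names(lex$accession_to_sequence))) {
    writeLines(paste0("AC ", acc), con)
    nm <- lex$names[lex$names$accession == acc, , drop = FALSE]
    for (i in seq_len(nrow(nm))) {
      tag <- if (nm$kind[i] == "Protein") "DE" else "GN"
      writeLines(paste0(tag, " ", nm$name[i]), con)
    }
    for (os in lex$accession_to_organism[[acc]])
      writeLines(paste0("OS ", os), con)
    for (go in lex$accession_to_go[[acc]])
      writeLines(paste0("DR ", go), con)
    seq <- lex$accession_to_sequence[[acc]]
    writeLines(paste0("SQ ", seq), con)
    writeLines("//", con)
  }
  invisible(path)
}

#' Load the molecular-function part of the Gene Ontology from an OBO file
#'
#' Parses OBO 1.2-style `[Term]` stanzas (`id`, `name`, `namespace`,
#' `synonym`, `is_a`, `is_obsolete`). Only `molecular_function` terms are
#' retained; obsolete terms are dropped; each concept's synonym set includes
#' its primary name.
#'
#' @param path Path to the OBO file.
#' @return An object of class `go_graph`: list of concepts keyed by GO id,
#'   each with `name`, `synonyms`, `parents`.
#' @export
load_go <- function(path) {
  lines <- readLines(path, warn = FALSE)
  concepts <- list()
  cur <- NULL
  flush <- function(cur, concepts) {
    if (is.null(cur) || is.null(cur$id)) return(concepts)
    if (isTRUE(cur$obsolete)) return(concepts)
    if (!identical(cur$namespace, "molecular_function")) return(concepts)
    cur$synonyms <- unique(c(cur$name, cur$synonyms))
    concepts[[cur$id]] <- cur[c("name", "synonyms", "parents")]
    concepts
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      concepts <- flush(cur, concepts)
      cur <- list(id = NULL, name = NA_character_, namespace = NA_character_,
                  synonyms = character(0), parents = character(0),
                  obsolete = FALSE)
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) { concepts <- flush(cur, concepts); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^namespace:", ln))
      cur$namespace <- trimws(sub("^namespace:", "", ln))
    else if (grepl("^synonym:", ln)) {
      m <- regmatches(ln, regexpr('"[^"]*"', ln))
      if (length(m)) cur$synonyms <- c(cur$synonyms, gsub('"', "", m))
    }
    else if (grepl("^is_a:", ln)) {
      id <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$parents <- c(cur$parents, id)
    }
    else if (grepl("^is_obsolete:\\s*true", ln)) cur$obsolete <- TRUE
  }
  concepts <- flush(cur, concepts)
  g <- structure(list(concepts = concepts), class = "go_graph")
  # reject cyclic is_a among retained terms
  for (id in names(concepts)) {
    go_ancestors(g, id)   # errors on a cycle
  }
  g
}

#' @export
print.go_graph <- function(x, ...) {
  cat(sprintf("<go_graph: %d molecular_function concepts>\n",
              length(x$concepts)))
  invisible(x)
}

#' Transitive is_a ancestors of a GO concept
#' @param go A `go_graph`.
#' @param id GO id.
#' @return Character vector of ancestor ids (excluding `id` itself).
#' @export
go_ancestors <- function(go, id) {
  seen <- character(0)
  frontier <- go$concepts[[id]]$parents
  frontier <- frontier[frontier %in% names(go$concepts)]
  while (length(frontier)) {
    nxt <- frontier[1]
    frontier <- frontier[-1]
    if (nxt == id || nxt %in% seen) {
      if (nxt == id) stop(sprintf("is_a cycle involving %s", id))
      next
    }
    seen <- c(seen, nxt)
    par <- go$concepts[[nxt]]$parents
    frontier <- c(frontier, par[par %in% names(go$concepts)])
    if (length(seen) > length(go$concepts))
      stop(sprintf("is_a cycle involving %s", id))
  }
  seen
}

#' Serialize a go_graph back to a minimal OBO file
#' @param go A `go_graph`.
#' @param path Output path.
#' @export
write_go_obo <- function(go, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (id in sort(names(go$concepts))) {
    cc <- go$concepts[[id]]
    writeLines("", con)
    writeLines("[Term]", con)
    writeLines(paste0("id: ", id), con)
    writeLines(paste0("name: ", cc$name), con)
    writeLines("namespace: molecular_function", con)
    for (s in setdiff(cc$synonyms, cc$name))
      writeLines(sprintf('synonym: "%s" EXACT []', s), con)
    for (p in cc$parents)
      writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Seed word lists for the five directionality categories
#'
#' The categories are positive, negative, neutral, negation and non_neutral.
#' @export
direction_seed_lists <- function() {
  list(
    positive = c("increase", "enhance", "higher", "improve"),
    negative = c("abolish", "decrease", "reduce", "lower", "inhibit",
                 "impair", "loose", "defect", "disrupt", "diminish"),
    neutral = c("identical", "similar", "full"),
    negation = c("without", "no", "not"),
    non_neutral = c("affect", "effect", "alter", "differ")
  )
}

# deterministic orthographic expansion of a seed word with inflected and
# nominal variants; matching is token-exact against the expanded list, so no
# stemmer is needed at match time
expand_direction_word <- function(w) {
  if (nchar(w) <= 3L) return(w)
  forms <- w
  last <- substr(w, nchar(w), nchar(w))
  stem_e <- substr(w, 1L, nchar(w) - 1L)
  if (last == "e") {
    forms <- c(forms, paste0(w, "s"), paste0(w, "d"),
               paste0(stem_e, "ing"))
    # nominalization: -ce -> -ction ("reduce" -> "reduction")
    if (substr(w, nchar(w) - 1L, nchar(w)) == "ce")
      forms <- c(forms, paste0(substr(w, 1L, nchar(w) - 1L), "tion"))
  } else {
    plural <- if (grepl("(s|sh|ch|x)$", w)) paste0(w, "es") else paste0(w, "s")
    forms <- c(forms, plural, paste0(w, "ed"), paste0(w, "ing"))
    # nominalization: -t -> -tion ("inhibit" -> "inhibition")
    if (last == "t") forms <- c(forms, paste0(w, "ion"))
  }
  unique(forms)
}

#' Build the directionality lexicon from seed lists
#'
#' Each seed word is expanded with inflected and nominal variants (plural,
#' past, gerund, -tion/-ion nominalizations where orthographically
#' applicable); expansion is deterministic. Negation words and very short
#' words are not expanded. If a surface form would land in two categories the
#' first category (in the order positive, negative, neutral, negation,
#' non_neutral) wins and a warning is issued.
#'
#' @param seed_lists Named list of five character vectors; defaults to
#'   [direction_seed_lists()].
#' @return An object of class `direction_lexicon`: a data.frame with columns
#'   `word` and `category`.
#' @export
build_direction_lexicon <- function(seed_lists = direction_seed_lists()) {
  cats <- c("positive", "negative", "neutral", "negation", "non_neutral")
  stopifnot(all(names(seed_lists) %in% cats))
  out <- data.frame(word = character(), category = character(),
                    stringsAsFactors = FALSE)
  for (cat in cats) {
    for (seed in seed_lists[[cat]]) {
      forms <- if (cat == "negation") seed else expand_direction_word(tolower(seed))
      for (f in forms) {
        if (f %in% out$word) {
          prev <- out$category[out$word == f][1]
          if (prev != cat)
            warning(sprintf("'%s' seeded in both %s and %s; keeping %s",
                            f, prev, cat, prev))
          next
        }
        out <- rbind(out, data.frame(word = f, category = cat,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  structure(out, class = c("direction_lexicon", "data.frame"))
}
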