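# End-to-end driver: NER -> grounding -> impacts -> mutant-impact relations,
# plus standoff JSON serialization.

#' Pipeline configuration
#'
#' @param pool_fraction Candidate-pool trimming fraction (default 0.5).
#' @param max_displacement Mutation-grounding displacement bound (default 10).
#' @param similarity_method GO similarity variant ("jaccard", "over_g",
#'   "over_n").
#' @export
mi_config <- function(pool_fraction = 0.5, max_displacement = 10L,
                      similarity_method = "jaccard") {
  list(pool_fraction = pool_fraction,
       max_displacement = as.integer(max_displacement),
       similarity_method = similarity_method)
}

#' Run the full mutation-impact pipeline on one document
#'
#' Tokenizes and sentence-splits the text, finds mutation / entity /
#' property / direction mentions, builds the candidate accession pool,
#' grounds the mutation set (documents with fewer than two distinct mutation
#' mentions, or an empty pool, yield no grounding), grounds function
#' mentions to GO, extracts impact statements, links them to grounded
#' mutants and resolves contradictions.
#'
#' @param text Document text.
#' @param doc_id Document identifier.
#' @param lex A `protein_lexicon`.
#' @param go A `go_graph`.
#' @param dlex A `direction_lexicon`.
#' @param config See [mi_config()].
#' @return An object of class `mi_result`: list with the document, all
#'   annotation tables, `pool`, `grounding` (or NULL) and `relations`.
#' @export
annotate_document <- function(text, doc_id, lex, go,
                              dlex = build_direction_lexicon(),
                              config = mi_config()) {
  doc <- mi_document(text, doc_id)
  mutations <- find_mutation_mentions(doc)
  entities <- find_entity_mentions(doc, lex)

  properties <- NULL
  directions <- NULL
  for (s in doc$sentences$index) {
    properties <- rbind(properties, find_property_mentions(doc, s, dlex))
    directions <- rbind(directions, find_direction_terms(doc, s, dlex))
  }
  if (is.null(properties)) properties <- find_property_mentions(doc, -1L, dlex)
  if (is.null(directions))
    directions <- data.frame(start = integer(), end = integer(),
                             surface = character(), category = character(),
                             sentence = integer(), stringsAsFactors = FALSE)

  pool <- build_candidate_pool(entities, lex, f = config$pool_fraction)

  grounding <- NULL
  n_uniq <- length(unique(mutations$normalized))
  if (n_uniq >= 2L && nrow(pool$accessions) > 0L) {
    grounding <- ground_mutations(mutations, pool, lex,
                                  max_displacement = config$max_displacement)
  }

  impacts <- extract_impacts(doc, properties, directions)

  relations <- impacts[0, , drop = FALSE]
  relations$mutation <- character(0)
  relations$sentence_distance <- integer(0)
  relations$relation_score <- numeric(0)
  relations$property_key <- character(0)
  relations$similarity <- numeric(0)
  relations$combined_score <- numeric(0)

  if (!is.null(grounding) && nrow(grounding$grounded) > 0L &&
      nrow(impacts) > 0L) {
    grounded_occurrences <- mutations[
      mutations$normalized %in% grounding$grounded$normalized, , drop = FALSE]
    raw <- link_mutants(impacts, grounded_occurrences)
    if (nrow(raw) > 0L) {
      raw$property_key <- NA_character_
      raw$similarity <- NA_real_
      for (i in seq_len(nrow(raw))) {
        if (raw$prop_kind[i] == "kinetic") {
          raw$property_key[i] <- raw$variable[i]
        } else {
          gf <- ground_function(raw$np_tokens[[i]], pool, lex, go,
                                method = config$similarity_method)
          if (!is.null(gf)) {
            raw$property_key[i] <- gf$go_id
            raw$similarity[i] <- gf$similarity
          } else {
            raw$property_key[i] <- paste0("np:", tolower(
              paste(raw$np_tokens[[i]], collapse = "_")))
          }
        }
      }
      relations <- resolve_contradictions(raw)
    }
  }

  structure(list(doc = doc, mutations = mutations, entities = entities,
                 properties = properties, directions = directions,
                 pool = pool, grounding = grounding, impacts = impacts,
                 relations = relations),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("<mi_result '%s': %d mutation mentions, %d grounded, %d relations>\n",
              x$doc$doc_id, nrow(x$mutations),
              if (is.null(x$grounding)) 0L else nrow(x$grounding$grounded),
              nrow(x$relations)))
  invisible(x)
}

#' Run the pipeline over a corpus
#'
#' @param texts Named character vector or list (names are doc ids).
#' @inheritParams annotate_document
#' @return List of `mi_result`, one per document, named by doc id.
#' @export
process_corpus <- function(texts, lex, go, dlex = build_direction_lexicon(),
                           config = mi_config()) {
  ids <- names(texts)
  if (is.null(ids)) ids <- sprintf("doc%03d", seq_along(texts))
  res <- lapply(seq_along(texts), function(i)
    annotate_document(texts[[i]], ids[i], lex, go, dlex, config))
  names(res) <- ids
  res
}

#' Collect grounding predictions from pipeline results
#'
#' One row per grounded unique mutation mention:
#' (doc_id, mutation, accession, position on the database sequence).
#' @param results List of `mi_result`.
#' @export
collect_grounding_predictions <- function(results) {
  rows <- lapply(results, function(r) {
    if (is.null(r$grounding) || nrow(r$grounding$grounded) == 0L) return(NULL)
    data.frame(doc_id = r$doc$doc_id,
               mutation = r$grounding$grounded$normalized,
               accession = r$grounding$accession,
               position = r$grounding$grounded$seq_position,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(doc_id = character(), mutation = character(),
                      accession = character(), position = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  unique(out)
}

#' Collect relation predictions from pipeline results
#'
#' One row per unique (doc_id, mutation, direction, property_key) triple.
#' @param results List of `mi_result`.
#' @export
collect_relation_predictions <- function(results) {
  rows <- lapply(results, function(r) {
    if (nrow(r$relations) == 0L) return(NULL)
    data.frame(doc_id = r$doc$doc_id, mutation = r$relations$mutation,
               direction = r$relations$direction,
               property_key = r$relations$property_key,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(doc_id = character(), mutation = character(),
                      direction = character(), property_key = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  unique(out)
}

#' Serialize pipeline annotations as standoff JSON
#'
#' All annotations reference the text by 0-based, half-open character
#' offsets; the text itself is included for self-containment.
#'
#' @param result An `mi_result`.
#' @param path Output path (".json"); when NULL the JSON string is returned.
#' @export
write_standoff_json <- function(result, path = NULL) {
  anns <- list()
  push <- function(anns, kind, df, feature_cols) {
    for (i in seq_len(nrow(df))) {
      feats <- lapply(feature_cols, function(cl) df[[cl]][i])
      names(feats) <- feature_cols
      anns[[length(anns) + 1L]] <- list(kind = kind, start = df$start[i],
                                        end = df$end[i], features = feats)
    }
    anns
  }
  anns <- push(anns, "Mutation", result$mutations,
               c("wildtype", "position", "mutant", "normalized"))
  for (knd in c("Protein", "Gene", "Organism")) {
    sub <- result$entities[result$entities$kind == knd, , drop = FALSE]
    anns <- push(anns, knd, sub, c("name"))
  }
  fp <- result$properties[result$properties$kind == "function", , drop = FALSE]
  anns <- push(anns, "FunctionProperty", fp, c("head"))
  kv <- result$properties[result$properties$kind == "kinetic", , drop = FALSE]
  anns <- push(anns, "KineticVariable", kv, c("variable"))
  anns <- push(anns, "Direction", result$directions, c("surface", "category"))

  payload <- list(
    doc_id = result$doc$doc_id,
    text = result$doc$text,
    annotations = anns,
    grounding = if (is.null(result$grounding)) NULL else list(
      accession = result$grounding$accession,
      displacement = result$grounding$displacement,
      grounded = result$grounding$grounded$normalized,
      discarded = result$grounding$discarded$normalized),
    relations = if (nrow(result$relations)) lapply(
      seq_len(nrow(result$relations)), function(i) list(
        mutation = result$relations$mutation[i],
        direction = result$relations$direction[i],
        property_key = result$relations$property_key[i],
        combined_score = result$relations$combined_score[i])) else list()
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                           digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
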