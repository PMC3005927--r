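# RDF instance triples over the mutation-impact concept vocabulary
# (Protein, ProteinMutant, ProteinProperty, ElementaryMutation,
# MutationSeries, MutationSpecification, MutationImpact), serialized as
# Turtle and N-Triples. Graphs are plain data.frames of triples with
# deterministic IRIs (no blank nodes), so graph identity is set identity.

MI_NS <- "http://mutimpact.local/ns#"
MI_ID <- "http://mutimpact.local/id/"
GO_NS <- "http://purl.obolibrary.org/obo/"
XSD_INTEGER <- "http://www.w3.org/2001/XMLSchema#integer"
RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

# The instance vocabulary: the seven mutation-impact concept classes, the
# linking predicates specifiesImpact/impactIsSpecifiedBy, the datatype
# properties hasSequence/hasWildtypeResidue, and the remaining predicates
# minted in the package namespace. This function is the single place the
# vocabulary is defined.
mi_vocabulary <- function() {
  list(
    classes = paste0(MI_NS, c("Protein", "ProteinMutant", "ProteinProperty",
                              "ElementaryMutation", "MutationSeries",
                              "MutationSpecification", "MutationImpact")),
    predicates = paste0(MI_NS, c("hasSequence", "hasWildtypeResidue",
                                 "hasMutantResidue", "hasPosition",
                                 "specifiesImpact", "impactIsSpecifiedBy",
                                 "affectsProperty", "hasDirection",
                                 "groundedTo", "mentionedIn", "hasMutation",
                                 "hasMutant", "hasImpact"))
  )
}

empty_graph <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(),
             object_kind = character(),   # "iri", "literal", "integer"
             stringsAsFactors = FALSE)
}

triple <- function(s, p, o, kind = "iri") {
  data.frame(subject = s, predicate = p, object = o, object_kind = kind,
             stringsAsFactors = FALSE)
}

iri_safe <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

go_iri <- function(go_id) paste0(GO_NS, sub(":", "_", go_id))

apply_mutation_to_sequence <- function(sequence, seq_position, mutant) {
  stopifnot(seq_position >= 1L, seq_position <= nchar(sequence))
  paste0(substr(sequence, 1L, seq_position - 1L), mutant,
         substr(sequence, seq_position + 1L, nchar(sequence)))
}

#' Emit RDF triples for one pipeline result
#'
#' One MutationSpecification node per grounded document links the Protein
#' (with its accession IRI and hasSequence literal), each grounded
#' ElementaryMutation (hasWildtypeResidue / hasMutantResidue / hasPosition),
#' a MutationSeries grouping them, one ProteinMutant per grounded mutation
#' (carrying the mutated sequence as a hasSequence literal) and each
#' MutationImpact (direction individual plus a property link: the GO IRI for
#' grounded function mentions, a kinetic-variable individual otherwise) via
#' specifiesImpact / impactIsSpecifiedBy. Node IRIs are deterministic
#' functions of the document id and annotation content. A document with no
#' grounding yields only its document node.
#'
#' @param result An `mi_result` from [annotate_document()].
#' @return A triple data.frame (columns subject, predicate, object,
#'   object_kind).
#' @export
emit_triples <- function(result) {
  g <- empty_graph()
  doc_id <- iri_safe(result$doc$doc_id)
  doc_node <- paste0(MI_ID, "document/", doc_id)
  if (is.null(result$grounding) || nrow(result$grounding$grounded) == 0L) {
    # document node only; no concept instances to assert
    return(rbind(g, triple(doc_node, "http://purl.org/dc/terms/identifier",
                           result$doc$doc_id, "literal")))
  }
  gr <- result$grounding
  ns <- function(x) paste0(MI_NS, x)
  id <- function(...) paste0(MI_ID, paste0(...))

  protein <- id("protein/", iri_safe(gr$accession))
  spec <- id("doc/", doc_id, "/specification")
  series <- id("doc/", doc_id, "/series")

  g <- rbind(g,
    triple(protein, RDF_TYPE, ns("Protein")),
    triple(protein, ns("hasSequence"), gr$sequence, "literal"),
    triple(spec, RDF_TYPE, ns("MutationSpecification")),
    triple(spec, ns("groundedTo"), protein),
    triple(spec, ns("mentionedIn"), doc_node),
    triple(series, RDF_TYPE, ns("MutationSeries")))

  for (i in seq_len(nrow(gr$grounded))) {
    m <- gr$grounded[i, ]
    mut <- id("doc/", doc_id, "/mutation/", m$normalized)
    mutant <- id("doc/", doc_id, "/mutant/", m$normalized)
    g <- rbind(g,
      triple(mut, RDF_TYPE, ns("ElementaryMutation")),
      triple(mut, ns("hasWildtypeResidue"), m$wildtype, "literal"),
      triple(mut, ns("hasMutantResidue"), m$mutant, "literal"),
      triple(mut, ns("hasPosition"), as.character(m$seq_position), "integer"),
      triple(series, ns("hasMutation"), mut),
      triple(spec, ns("hasMutation"), mut),
      triple(mutant, RDF_TYPE, ns("ProteinMutant")),
      triple(mutant, ns("hasMutation"), mut),
      triple(mutant, ns("hasSequence"),
             apply_mutation_to_sequence(gr$sequence, m$seq_position, m$mutant),
             "literal"),
      triple(spec, ns("hasMutant"), mutant))
  }

  rel <- result$relations
  for (i in seq_len(nrow(rel))) {
    imp <- id("doc/", doc_id, "/impact/", i, "_", rel$direction[i], "_",
              iri_safe(rel$property_key[i]), "_", rel$mutation[i])
    prop_node <- if (rel$prop_kind[i] == "kinetic") {
      id("variable/", iri_safe(rel$property_key[i]))
    } else if (grepl("^GO:", rel$property_key[i])) {
      go_iri(rel$property_key[i])
    } else {
      id("property/", iri_safe(rel$property_key[i]))
    }
    mutant <- id("doc/", doc_id, "/mutant/", rel$mutation[i])
    g <- rbind(g,
      triple(imp, RDF_TYPE, ns("MutationImpact")),
      triple(imp, ns("hasDirection"), id("direction/", rel$direction[i])),
      triple(imp, ns("affectsProperty"), prop_node),
      triple(prop_node, RDF_TYPE, ns("ProteinProperty")),
      triple(spec, ns("specifiesImpact"), imp),
      triple(imp, ns("impactIsSpecifiedBy"), spec),
      triple(mutant, ns("hasImpact"), imp))
  }
  g <- unique(g)
  rownames(g) <- NULL
  g
}

rdf_escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x
}

format_object <- function(o, kind) {
  switch(kind,
         iri = paste0("<", o, ">"),
         literal = paste0('"', rdf_escape_literal(o), '"'),
         integer = paste0('"', o, '"^^<', XSD_INTEGER, ">"),
         stop("unknown object kind: ", kind))
}

#' Serialize a triple graph as N-Triples
#' @param graph Triple data.frame from [emit_triples()].
#' @param path Output path (".nt").
#' @export
write_ntriples <- function(graph, path) {
  lines <- vapply(seq_len(nrow(graph)), function(i) {
    sprintf("<%s> <%s> %s .", graph$subject[i], graph$predicate[i],
            format_object(graph$object[i], graph$object_kind[i]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a triple graph as Turtle
#' @param graph Triple data.frame from [emit_triples()].
#' @param path Output path (".ttl").
#' @export
write_turtle <- function(graph, path) {
  shorten <- function(x) {
    if (identical(x, RDF_TYPE)) return("a")
    for (pre in list(c(MI_NS, "mi:"), c(MI_ID, "mid:"), c(GO_NS, "obo:"))) {
      if (startsWith(x, pre[1])) {
        local <- substring(x, nchar(pre[1]) + 1L)
        # only prefix when the local part is a valid Turtle PN_LOCAL
        if (grepl("^[A-Za-z0-9_][A-Za-z0-9_.-]*$", local))
          return(paste0(pre[2], local))
      }
    }
    paste0("<", x, ">")
  }
  lines <- c(
    sprintf("@prefix mi: <%s> .", MI_NS),
    sprintf("@prefix mid: <%s> .", MI_ID),
    sprintf("@prefix obo: <%s> .", GO_NS),
    sprintf("@prefix xsd: <%s> .", "http://www.w3.org/2001/XMLSchema#"),
    "")
  for (s in unique(graph$subject)) {
    rows <- graph[graph$subject == s, , drop = FALSE]
    po <- vapply(seq_len(nrow(rows)), function(i) {
      obj <- switch(rows$object_kind[i],
                    iri = shorten(rows$object[i]),
                    literal = paste0('"', rdf_escape_literal(rows$object[i]), '"'),
                    integer = paste0('"', rows$object[i], '"^^xsd:integer'))
      paste0("    ", shorten(rows$predicate[i]), " ", obj)
    }, character(1))
    lines <- c(lines, paste0(shorten(s)),
               paste0(po, c(rep(" ;", length(po) - 1L), " .")), "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse an N-Triples file back into a triple data.frame
#' @param path Path to an ".nt" file written by [write_ntriples()].
#' @export
parse_ntriples <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  g <- empty_graph()
  pat <- "^<([^>]+)>\\s+<([^>]+)>\\s+(.+)\\s+\\.$"
  for (ln in lines) {
    m <- regmatches(ln, regexec(pat, ln))[[1]]
    if (length(m) != 4L) stop("malformed N-Triples line: ", ln)
    obj <- m[4]
    if (grepl("^<", obj)) {
      g <- rbind(g, triple(m[2], m[3], sub("^<(.+)>$", "\\1", obj)))
    } else if (grepl(paste0('\\^\\^<', XSD_INTEGER, ">$"), obj)) {
      val <- sub('^"(.*)"\\^\\^<.*$', "\\1", obj)
      g <- rbind(g, triple(m[2], m[3], val, "integer"))
    } else {
      val <- sub('^"(.*)"$', "\\1", obj)
      val <- gsub('\\"', '"', val, fixed = TRUE)
      val <- gsub("\\n", "\n", val, fixed = TRUE)
      val <- gsub("\\\\", "\\", val, fixed = TRUE)
      g <- rbind(g, triple(m[2], m[3], val, "literal"))
    }
  }
  g
}

#' Match a triple pattern against a graph
#'
#' `NA` in a position acts as a wildcard, mirroring a single SPARQL basic
#' graph pattern.
#'
#' @param graph Triple data.frame.
#' @param subject,predicate,object Pattern terms (NA = wildcard).
#' @return The matching rows.
#' @export
query_triples <- function(graph, subject = NA, predicate = NA, object = NA) {
  keep <- rep(TRUE, nrow(graph))
  if (!is.na(subject)) keep <- keep & graph$subject == subject
  if (!is.na(predicate)) keep <- keep & graph$predicate == predicate
  if (!is.na(object)) keep <- keep & graph$object == object
  out <- graph[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Are two triple graphs isomorphic?
#'
#' With deterministic IRIs and no blank nodes, graph isomorphism reduces to
#' set equality of triples.
#' @param g1,g2 Triple data.frames.
#' @export
graphs_isomorphic <- function(g1, g2) {
  key <- function(g) sort(paste(g$subject, g$predicate, g$object,
                                g$object_kind, sep = "\r"))
  identical(key(unique(g1)), key(unique(g2)))
}

#' Find mutants with a given impact direction on a given property
#'
#' Convenience query mirroring "which proteins have been mutated so that
#' there is a `direction` impact on property `property_node`": follows
#' MutationImpact nodes with the requested direction and property to their
#' ProteinMutant and its mutated sequence.
#'
#' @param graph Triple data.frame.
#' @param direction Direction category (e.g. "negative").
#' @param property_node Property IRI (GO IRI or kinetic-variable individual).
#' @return Data.frame with `mutant` (IRI) and `sequence` (literal).
#' @export
query_impacted_mutants <- function(graph, direction, property_node) {
  dir_node <- paste0(MI_ID, "direction/", direction)
  imp1 <- query_triples(graph, predicate = paste0(MI_NS, "hasDirection"),
                        object = dir_node)$subject
  imp2 <- query_triples(graph, predicate = paste0(MI_NS, "affectsProperty"),
                        object = property_node)$subject
  imps <- intersect(imp1, imp2)
  out <- data.frame(mutant = character(), sequence = character(),
                    stringsAsFactors = FALSE)
  for (imp in imps) {
    mutants <- query_triples(graph, predicate = paste0(MI_NS, "hasImpact"),
                             object = imp)$subject
    for (mt in mutants) {
      seqs <- query_triples(graph, subject = mt,
                            predicate = paste0(MI_NS, "hasSequence"))$object
      out <- rbind(out, data.frame(mutant = mt,
                                   sequence = if (length(seqs)) seqs[1] else NA_character_,
                                   stringsAsFactors = FALSE))
    }
  }
  unique(out)
}
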