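test_that("one-letter, three-letter and series mutation mentions are found and normalized", {
  doc <- mi_document(paste(
    "The W125F mutant showed only a slight reduction of activity.",
    "The double mutant Arg172Lys+His65Ala lost binding.",
    "Mutation of Asp260 to asparagine resulted in an inactive D260N mutant."),
    "d1")
  m <- find_mutation_mentions(doc)
  expect_setequal(m$normalized, c("W125F", "R172K", "H65A", "D260N"))
  # the frame-based and the literal D260N mention collapse to the same form
  expect_equal(sum(m$normalized == "D260N"), 2L)
  # spans carry the true surface
  for (i in seq_len(nrow(m)))
    expect_identical(substr(doc$text, m$start[i] + 1L, m$end[i]),
                     m$surface[i])
  # no two mention spans overlap
  m <- m[order(m$start), ]
  if (nrow(m) > 1L) expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
})

test_that("the word-boundary guard rejects identifiers and strain names", {
  doc <- mi_document(paste(
    "Xanthobacter autotrophicus GJ10 degrades haloalkanes;",
    "plasmid pW125F was not a mutation, nor is H2O2 or T7A1 polymerase."),
    "d2")
  m <- find_mutation_mentions(doc)
  expect_false(any(grepl("GJ", m$surface)))
  expect_false("W125F" %in% m$normalized)   # embedded in pW125F
  expect_false("H2O" %in% m$surface)
  # T7A is followed by an alphanumeric ('1'), so it must not match
  expect_false("T7A" %in% m$normalized)
})

test_that("natural-language replacement frames yield one mention per residue item", {
  doc <- mi_document(
    "Replacement of Trp-125 or Trp-175 with arginine leads to a nonactive enzyme.",
    "d3")
  m <- find_mutation_mentions(doc)
  expect_setequal(m$normalized, c("W125R", "W175R"))
})

test_that("normalization is idempotent and rejects unknown or identity substitutions", {
  n1 <- normalize_mutation("Trp125Phe")
  expect_equal(n1$normalized, "W125F")
  n2 <- normalize_mutation(n1$normalized)
  expect_equal(n2$normalized, "W125F")
  expect_equal(normalize_mutation("D260N")$normalized, "D260N")
  expect_null(normalize_mutation("Xyz123Abc"))
  expect_null(normalize_mutation("A123A"))     # wildtype == mutant
  expect_null(normalize_mutation("B12C"))      # not an amino-acid code
})

test_that("gazetteer matching follows the case rules and longest-match-wins", {
  lex <- make_test_lexicon()
  # add an overlapping shorter protein name for the same accession
  lex <- lexicon_add_record(lex, accession = "TST00001",
                            protein_names = "dehalogenase",
                            sequence = make_dhl_sequence())
  doc <- mi_document(
    "Haloalkane dehalogenase (DhlA) from Xanthobacter autotrophicus was pure.",
    "d4")
  e <- find_entity_mentions(doc, lex)
  expect_setequal(e$kind, c("Protein", "Gene", "Organism"))
  expect_equal(e$name[e$kind == "Protein"], "Haloalkane dehalogenase")
  expect_equal(e$surface[e$kind == "Gene"], "DhlA")
  expect_equal(tolower(e$name[e$kind == "Organism"]),
               "xanthobacter autotrophicus")
  # multiword names match case-insensitively
  doc2 <- mi_document("HALOALKANE DEHALOGENASE was assayed.", "d5")
  e2 <- find_entity_mentions(doc2, lex)
  expect_equal(e2$kind, "Protein")
  # single-word names are case-sensitive: lowercase gene form must not match
  doc3 <- mi_document("The dhla gene product was assayed.", "d6")
  e3 <- find_entity_mentions(doc3, lex)
  expect_false("Gene" %in% e3$kind)
  # no same-kind overlaps
  prot <- e[e$kind == "Protein", ]
  if (nrow(prot) > 1L) expect_true(all(prot$start[-1] >= prot$end[-nrow(prot)]))
})

test_that("function noun phrases end at a head noun and exclude direction and stop words", {
  dlex <- build_direction_lexicon()
  doc <- mi_document(
    "The mutant had reduced catalytic activity (30-40%) compared to controls.",
    "d7")
  p <- find_property_mentions(doc, 0L, dlex)
  fun <- p[p$kind == "function", ]
  expect_equal(nrow(fun), 1L)
  expect_equal(fun$head, "activity")
  expect_equal(fun$np_tokens[[1]], c("catalytic", "activity"))

  doc2 <- mi_document(
    "A slight reduction of activity (Vmax) and a larger increase of Km were seen.",
    "d8")
  p2 <- find_property_mentions(doc2, 0L, dlex)
  expect_equal(p2$head[p2$kind == "function"], "activity")
  expect_equal(p2$variable[p2$kind == "kinetic"], "KM")

  # "binding affinity" is one noun phrase headed by "affinity"
  doc3 <- mi_document("The mutant showed weaker substrate binding affinity.", "d9")
  p3 <- find_property_mentions(doc3, 0L, dlex)
  expect_equal(nrow(p3), 1L)
  expect_equal(p3$head, "affinity")
  expect_true("binding" %in% p3$np_tokens[[1]])
})

test_that("kinetic variables match whole tokens with compound precedence", {
  dlex <- build_direction_lexicon()
  doc <- mi_document("The kcat/Km of the mutant fell while K_m rose; kcat was stable.",
                     "d10")
  p <- find_property_mentions(doc, 0L, dlex)
  kin <- p[p$kind == "kinetic", ]
  expect_equal(sort(kin$variable), c("KCAT", "KCAT_OVER_KM", "KM"))
  # the compound token yields no separate KM or KCAT mention
  expect_equal(sum(kin$variable == "KM"), 1L)
  expect_equal(sum(kin$variable == "KCAT"), 1L)
  # variables fused into equations are rejected
  doc2 <- mi_document("We fixed Km=5 and computed kcat2 values.", "d11")
  p2 <- find_property_mentions(doc2, 0L, dlex)
  expect_equal(nrow(p2[p2$kind == "kinetic", ]), 0L)
})

test_that("direction terms match whole tokens case-insensitively with categories", {
  dlex <- build_direction_lexicon()
  doc <- mi_document("A Reduction of activity and an increase of Km, with no effect elsewhere.",
                     "d12")
  d <- find_direction_terms(doc, 0L, dlex)
  expect_equal(d$category[tolower(d$surface) == "reduction"], "negative")
  expect_equal(d$category[d$surface == "increase"], "positive")
  expect_equal(d$category[d$surface == "no"], "negation")
  expect_equal(d$category[d$surface == "effect"], "non_neutral")
  # words not in the shipped lists do not match
  doc2 <- mi_document("The conformation stayed intact throughout.", "d13")
  d2 <- find_direction_terms(doc2, 0L, dlex)
  expect_equal(nrow(d2), 0L)
})

test_that("NER recall is 1.0 on planted synthetic documents", {
  w <- generate_world(fixture_spec(seed = 42L, n_docs = 6L))
  dlex <- build_direction_lexicon()
  for (id in names(w$texts)) {
    doc <- mi_document(w$texts[[id]], id)
    m <- find_mutation_mentions(doc)
    planted <- w$gold$mutations$mutation[w$gold$mutations$doc_id == id]
    expect_true(all(planted %in% m$normalized))
    e <- find_entity_mentions(doc, w$lexicon)
    expect_true(all(c("Protein", "Gene", "Organism") %in% e$kind))
  }
})
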