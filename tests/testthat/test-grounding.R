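mention_df <- function(...) {
  # build a mention data.frame from wNm strings
  wnm <- c(...)
  rows <- lapply(wnm, function(x) {
    n <- normalize_mutation(x)
    data.frame(wildtype = n$wildtype, position = n$position,
               mutant = n$mutant, normalized = n$normalized,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

simple_pool <- function(accs) {
  structure(list(accessions = data.frame(accession = accs,
                                         support = 1L,
                                         stringsAsFactors = FALSE),
                 organism_filtered = FALSE), class = "candidate_pool")
}

seq_lexicon <- function(seqs) {
  lex <- empty_protein_lexicon()
  for (a in names(seqs))
    lex <- lexicon_add_record(lex, accession = a,
                              protein_names = paste("protein", a),
                              sequence = seqs[[a]])
  lex
}

test_that("candidate pools trim by frequency, expand suffixes and cross-check organisms", {
  lex <- make_test_lexicon()
  doc <- mi_document(paste(
    "DhlA was expressed. DhlA was assayed. DhlA was pure.",
    "LinB served as a control. Xanthobacter autotrophicus was the host."),
    "d1")
  e <- find_entity_mentions(doc, lex)
  pool <- build_candidate_pool(e, lex, f = 0.5)
  # DhlA support 3, LinB support 1 -> threshold ceil(1.5)=2 keeps only DhlA;
  # organism check keeps it too
  expect_equal(pool$accessions$accession, "TST00001")
  expect_true(pool$organism_filtered)

  # suffix expansion: a name extending a matched name joins the pool
  lex2 <- lexicon_add_record(lex, accession = "TST00003",
                             protein_names = character(0),
                             gene_names = "DhlA2",
                             sequence = strrep("ACDEFGHIKL", 4L))
  doc2 <- mi_document("DhlA was assayed.", "d2")
  e2 <- find_entity_mentions(doc2, lex2)
  pool2 <- build_candidate_pool(e2, lex2, f = 0.5)
  expect_setequal(pool2$accessions$accession, c("TST00001", "TST00003"))

  # organism filter discards candidates from unmentioned organisms
  doc3 <- mi_document(paste(
    "DhlA was compared with LinB. Xanthobacter autotrophicus was the source."),
    "d3")
  e3 <- find_entity_mentions(doc3, lex)
  pool3 <- build_candidate_pool(e3, lex, f = 0.5)
  expect_equal(pool3$accessions$accession, "TST00001")

  # when the filter would empty the pool, the unfiltered pool survives
  doc4 <- mi_document("DhlA was studied. Homo sapiens cells were separate.", "d4")
  e4 <- find_entity_mentions(doc4, lex)
  expect_warning(pool4 <- build_candidate_pool(e4, lex, f = 0.5),
                 "organism filter")
  expect_equal(pool4$accessions$accession, "TST00001")
})

test_that("pairwise regular expressions encode the wildtypes and the gap", {
  expect_equal(build_pair_regex(list(wildtype = "A", position = 378),
                                list(wildtype = "S", position = 381)),
               "A..S")
  expect_equal(build_pair_regex(list(wildtype = "A", position = 5),
                                list(wildtype = "G", position = 6)),
               "AG")
  # unsorted input gives the same pattern
  expect_equal(build_pair_regex(list(wildtype = "S", position = 381),
                                list(wildtype = "A", position = 378)),
               "A..S")
  # equal positions: the pair is skipped
  expect_null(build_pair_regex(list(wildtype = "A", position = 5),
                               list(wildtype = "G", position = 5)))
})

test_that("mutation sets ground with displacement detection and discards", {
  lex <- seq_lexicon(list(X1 = "MAVSTLAG"))
  g <- ground_mutations(mention_df("A2G", "T5P"), simple_pool("X1"), lex)
  expect_equal(g$accession, "X1")
  expect_equal(g$displacement, 0L)
  expect_setequal(g$grounded$normalized, c("A2G", "T5P"))
  expect_equal(g$grounded$seq_position[g$grounded$normalized == "A2G"], 2L)

  # initiator Met absent: same mentions ground at displacement -1
  lex2 <- seq_lexicon(list(X1 = "AVSTLAG"))
  g2 <- ground_mutations(mention_df("A2G", "T5P"), simple_pool("X1"), lex2)
  expect_equal(g2$displacement, -1L)
  expect_setequal(g2$grounded$normalized, c("A2G", "T5P"))

  # a third, inconsistent mention is discarded
  g3 <- ground_mutations(mention_df("A2G", "T5P", "W40F"),
                         simple_pool("X1"), lex2)
  expect_setequal(g3$grounded$normalized, c("A2G", "T5P"))
  expect_equal(g3$discarded$normalized, "W40F")

  # least displacement wins between two equally grounding sequences
  lex3 <- seq_lexicon(list(D0 = "MAVSTLAG", D1 = "AVSTLAG"))
  g4 <- ground_mutations(mention_df("A2G", "T5P"),
                         simple_pool(c("D0", "D1")), lex3)
  expect_equal(g4$accession, "D0")
  expect_equal(g4$displacement, 0L)

  # fewer than two distinct mentions violate the algorithm's precondition
  expect_error(ground_mutations(mention_df("A2G"), simple_pool("X1"), lex),
               "at least two")

  # no match anywhere: empty grounding, everything discarded
  lex4 <- seq_lexicon(list(X1 = strrep("G", 50L)))
  g5 <- ground_mutations(mention_df("A2C", "T5P"), simple_pool("X1"), lex4)
  expect_true(is.na(g5$accession))
  expect_equal(nrow(g5$grounded), 0L)
  expect_setequal(g5$discarded$normalized, c("A2C", "T5P"))
})

test_that("prepending residues shifts the displacement and nothing else", {
  base <- "MAVSTLAGWKLDERFYHIPC"
  mentions <- mention_df("A2G", "T5P", "W9F")
  for (k in c(1L, 3L, 7L)) {
    lex <- seq_lexicon(list(S = paste0(strrep("Q", k), base)))
    g <- ground_mutations(mentions, simple_pool("S"), lex)
    expect_equal(g$displacement, k)
    expect_setequal(g$grounded$normalized, c("A2G", "T5P", "W9F"))
  }
})

test_that("grounding equals the exhaustive brute-force oracle on random instances", {
  set.seed(101)
  n_mismatch <- 0L
  for (rep in seq_len(200L)) {
    inst <- random_grounding_instance()
    if (nrow(inst$mentions) < 2L) next
    got <- ground_mutations(inst$mentions, inst$pool, inst$lex,
                            max_displacement = 10L)
    want <- brute_force_grounding(inst$mentions, inst$pool, inst$lex,
                                  bound = 10L)
    same <- identical(got$accession, want$accession) &&
      identical(as.integer(got$displacement), as.integer(want$displacement)) &&
      identical(sort(got$grounded$normalized), want$grounded)
    if (!same) n_mismatch <- n_mismatch + 1L
  }
  expect_equal(n_mismatch, 0L)
})

test_that("token preparation lowercases, removes stop words and stems", {
  expect_equal(prepare_tokens(c("the", "activity")), "activ")
  expect_equal(prepare_tokens(character(0)), character(0))
  expect_setequal(prepare_tokens(c("binding", "of", "zinc")),
                  c("bind", "zinc"))
  # splitting applies to whole phrases too
  expect_setequal(prepare_tokens("zinc ion binding"),
                  c("zinc", "ion", "bind"))
})

test_that("relative intersection is symmetric, bounded and matches hand values", {
  n <- c("zinc", "ion", "bind"); g <- c("zinc", "bind")
  expect_equal(relative_intersection(n, g), 2 / 3)
  expect_equal(relative_intersection(g, n), 2 / 3)
  expect_equal(relative_intersection(n, n), 1.0)
  expect_equal(relative_intersection(n, c("other")), 0.0)
  expect_equal(relative_intersection(character(0), character(0)), 0)
  expect_equal(relative_intersection(n, g, method = "over_g"), 1.0)
  expect_equal(relative_intersection(n, g, method = "over_n"), 2 / 3)
  set.seed(7)
  words <- c("alpha", "beta", "gamma", "delta", "epsilon")
  for (i in 1:20) {
    a <- sample(words, sample(0:5, 1))
    b <- sample(words, sample(0:5, 1))
    s <- relative_intersection(a, b)
    expect_true(s >= 0 && s <= 1)
    expect_equal(s, relative_intersection(b, a))
  }
})

test_that("function mentions ground to the best-scoring annotated GO concept", {
  lex <- make_test_lexicon()
  go <- make_test_go()
  pool <- simple_pool("TST00002")   # annotated with carbonate dehydratase
  gf <- ground_function(c("carbonic", "anhydrase", "activity"), pool, lex, go)
  expect_equal(gf$go_id, "GO:0004089")
  expect_equal(gf$similarity, 1.0)
  # no overlap with any synonym: no grounding
  expect_null(ground_function(c("unrelated", "words"), pool, lex, go))
  # accessions without GO annotations: no grounding
  lex2 <- lexicon_add_record(lex, accession = "TST00009",
                             protein_names = "Bare protein",
                             sequence = strrep("A", 40L))
  expect_null(ground_function(c("activity"), simple_pool("TST00009"),
                              lex2, go))
})

test_that("ancestor synonyms join the candidate set", {
  lex <- make_test_lexicon()
  go <- structure(list(concepts = list(
    "GO:0018786" = list(name = "haloalkane dehalogenase activity",
                        synonyms = "haloalkane dehalogenase activity",
                        parents = "GO:0016787"),
    "GO:0016787" = list(name = "hydrolase activity",
                        synonyms = "hydrolase activity",
                        parents = character(0))
  )), class = "go_graph")
  pool <- simple_pool("TST00001")   # annotated with GO:0018786 only
  gf <- ground_function(c("hydrolase", "activity"), pool, lex, go)
  expect_equal(gf$go_id, "GO:0016787")
  expect_equal(gf$similarity, 1.0)
})
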