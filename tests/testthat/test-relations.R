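dlex <- build_direction_lexicon()

props_for <- function(doc, s = 0L) find_property_mentions(doc, s, dlex)
dirs_for <- function(doc, s = 0L) find_direction_terms(doc, s, dlex)

test_that("sentences split into one-property segments at comma/'and' or before the next property", {
  doc <- mi_document(paste(
    "The mutant showed a slight reduction of activity (Vmax) and a larger",
    "increase of Km with 1,2-dibromoethane."), "d1")
  props <- props_for(doc)
  expect_equal(nrow(props), 2L)
  segs <- segment_properties(doc, 0L, props)
  expect_equal(length(segs), 2L)
  # the "and" delimiter separates the two properties
  expect_true(segs[[1]]$end <= props$start[2])
  expect_true(segs[[1]]$end >= props$end[1])
  seg1_text <- substr(doc$text, segs[[1]]$start + 1, segs[[1]]$end)
  expect_match(seg1_text, "activity")
  expect_false(grepl("Km", seg1_text))

  # one property: one segment spanning the sentence
  doc2 <- mi_document("The mutant lost all activity rapidly.", "d2")
  segs2 <- segment_properties(doc2, 0L, props_for(doc2))
  expect_equal(length(segs2), 1L)
  expect_equal(segs2[[1]]$start, doc2$sentences$start[1])
  expect_equal(segs2[[1]]$end, doc2$sentences$end[1])

  # no comma or "and" between properties: split immediately before the later
  doc3 <- mi_document("The mutant showed reduced activity increased Km here.",
                      "d3")
  props3 <- props_for(doc3)
  expect_equal(nrow(props3), 2L)
  segs3 <- segment_properties(doc3, 0L, props3)
  expect_equal(segs3[[1]]$end, props3$start[2])
  expect_equal(segs3[[2]]$start, props3$start[2])
})

test_that("the nearest direction term classifies the impact with 1/tokenDistance scoring", {
  doc <- mi_document("A slight reduction of activity (Vmax) was seen.", "d4")
  props <- props_for(doc)
  segs <- segment_properties(doc, 0L, props)
  imp <- classify_impact(doc, segs[[1]], props[1, ], dirs_for(doc))
  expect_equal(imp$direction, "negative")
  expect_equal(imp$token_distance, 2L)
  expect_equal(imp$impact_score, 0.5)

  # a direction word adjacent to (or inside) the noun phrase scores 1
  doc2 <- mi_document("The mutant showed increased catalytic activity today.",
                      "d5")
  props2 <- props_for(doc2)
  segs2 <- segment_properties(doc2, 0L, props2)
  imp2 <- classify_impact(doc2, segs2[[1]], props2[1, ], dirs_for(doc2))
  expect_equal(imp2$direction, "positive")
  expect_equal(imp2$token_distance, 1L)
  expect_equal(imp2$impact_score, 1.0)

  # no direction term in the segment: no impact
  doc3 <- mi_document("The assay measured activity in duplicate.", "d6")
  props3 <- props_for(doc3)
  segs3 <- segment_properties(doc3, 0L, props3)
  expect_null(classify_impact(doc3, segs3[[1]], props3[1, ], dirs_for(doc3)))
})

test_that("negation within two tokens remaps the direction category", {
  # "no effect on ... activity": negation of non_neutral -> neutral
  doc <- mi_document("There was no effect on catalytic activity here.", "d7")
  props <- props_for(doc)
  segs <- segment_properties(doc, 0L, props)
  imp <- classify_impact(doc, segs[[1]], props[1, ], dirs_for(doc))
  expect_equal(imp$direction, "neutral")

  # "not ... increased": negation of positive -> neutral
  doc2 <- mi_document("Binding was not significantly increased by the change.",
                      "d8")
  props2 <- props_for(doc2)
  segs2 <- segment_properties(doc2, 0L, props2)
  imp2 <- classify_impact(doc2, segs2[[1]], props2[1, ], dirs_for(doc2))
  expect_equal(imp2$direction, "neutral")

  # negation too far from the direction word leaves it untouched
  doc3 <- mi_document("No buffer control was used; the assay showed increased activity.",
                      "d9")
  props3 <- props_for(doc3)
  segs3 <- segment_properties(doc3, 0L, props3)
  imp3 <- classify_impact(doc3, segs3[[1]], props3[1, ], dirs_for(doc3))
  expect_equal(imp3$direction, "positive")

  # negated negative and negated neutral remaps
  doc4 <- mi_document("Activity was not reduced by the substitution.", "d10")
  props4 <- props_for(doc4)
  segs4 <- segment_properties(doc4, 0L, props4)
  imp4 <- classify_impact(doc4, segs4[[1]], props4[1, ], dirs_for(doc4))
  expect_equal(imp4$direction, "neutral")
})

test_that("impacts link to the nearest grounded mutants within three previous sentences", {
  mk_impacts <- function(sentence) {
    data.frame(sentence = sentence, direction = "negative",
               token_distance = 1L, impact_score = 1,
               prop_start = 0L, prop_end = 5L, prop_kind = "kinetic",
               prop_head = "Km", variable = "KM",
               stringsAsFactors = FALSE)
  }
  mentions <- data.frame(normalized = "W125F", sentence = 0L,
                         stringsAsFactors = FALSE)
  for (k in 0:3) {
    rel <- link_mutants(mk_impacts(k), mentions)
    expect_equal(nrow(rel), 1L)
    expect_equal(rel$sentence_distance, k + 1L)
    expect_equal(rel$relation_score, 1 / (k + 1L))
  }
  # four or more sentences back: never linked
  expect_equal(nrow(link_mutants(mk_impacts(4L), mentions)), 0L)
  expect_equal(nrow(link_mutants(mk_impacts(9L), mentions)), 0L)
  # mentions in FOLLOWING sentences are never linked
  expect_equal(nrow(link_mutants(mk_impacts(0L),
                                 data.frame(normalized = "W125F",
                                            sentence = 1L))),
               0L)
  # only the minimal-distance set is linked
  both <- data.frame(normalized = c("W125F", "D170N"), sentence = c(2L, 1L))
  rel2 <- link_mutants(mk_impacts(2L), both)
  expect_equal(rel2$mutation, "W125F")
})

test_that("contradictions resolve to the highest combined mean score", {
  rel <- data.frame(
    mutation = "W125F",
    direction = c("positive", "negative"),
    property_key = "GO:0000001",
    relation_score = c(1, 1),
    impact_score = c(1, 0.5),
    similarity = c(0.6, 0.1),
    sentence = c(0L, 1L), prop_start = c(0L, 10L),
    stringsAsFactors = FALSE)
  out <- resolve_contradictions(rel)
  expect_equal(nrow(out), 1L)
  expect_equal(out$direction, "positive")
  expect_equal(out$combined_score, mean(c(1, 1, 0.6)))

  # a single uncontradicted relation passes through
  out2 <- resolve_contradictions(rel[1, , drop = FALSE])
  expect_equal(nrow(out2), 1L)

  # kinetic contradictions use the mean of two scores (similarity NA)
  rel3 <- data.frame(
    mutation = "A2G", direction = c("positive", "negative"),
    property_key = "KM", relation_score = c(0.5, 1),
    impact_score = c(0.5, 0.5), similarity = NA_real_,
    sentence = c(0L, 0L), prop_start = c(0L, 10L),
    stringsAsFactors = FALSE)
  out3 <- resolve_contradictions(rel3)
  expect_equal(out3$direction, "negative")
  expect_equal(out3$combined_score, 0.75)

  # relations on different properties never compete
  rel4 <- rel
  rel4$property_key <- c("GO:0000001", "GO:0000002")
  expect_equal(nrow(resolve_contradictions(rel4)), 2L)

  # ties keep the earliest relation in the document
  rel5 <- rel
  rel5$impact_score <- c(1, 1); rel5$similarity <- c(0.6, 0.6)
  out5 <- resolve_contradictions(rel5)
  expect_equal(out5$sentence, 0L)
})

test_that("scores are monotone in their distances", {
  d <- 1:10
  expect_true(all(diff(1 / d) < 0))
  # token_distance of a term further away is never smaller
  doc <- mi_document("reduced levels of the overall catalytic activity", "d11")
  props <- props_for(doc)
  segs <- segment_properties(doc, 0L, props)
  imp <- classify_impact(doc, segs[[1]], props[1, ], dirs_for(doc))
  expect_true(imp$token_distance >= 1L)
  expect_true(imp$impact_score <= 1)
})
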