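# Shared fixtures: a tiny hand-built lexicon and GO graph, plus an
# independent brute-force grounding oracle.

# Dehalogenase-flavoured mini lexicon. The sequence is deterministic filler
# with the residues the tests rely on planted at fixed positions.
make_dhl_sequence <- function() {
  # 200 residues: repeat of a fixed 20-mer, then plant W at 125, D at 170,
  # A at 30, S at 33
  base <- strsplit(strrep("MKLVNSTEGQRFYHIPCWDA", 10L), "")[[1]]
  base[125] <- "W"; base[170] <- "D"; base[30] <- "A"; base[33] <- "S"
  paste0(base, collapse = "")
}

make_test_lexicon <- function() {
  lex <- empty_protein_lexicon()
  lex <- lexicon_add_record(
    lex, accession = "TST00001",
    protein_names = "Haloalkane dehalogenase",
    gene_names = "DhlA",
    organisms = "Xanthobacter autotrophicus",
    go_ids = "GO:0018786",
    sequence = make_dhl_sequence())
  lex <- lexicon_add_record(
    lex, accession = "TST00002",
    protein_names = "Carbonic anhydrase",
    gene_names = "LinB",
    organisms = "Homo sapiens",
    go_ids = "GO:0004089",
    sequence = paste0(strrep("ACDEFGHIKLMNPQRSTVWY", 5L)))
  lex
}

make_test_go <- function() {
  structure(list(concepts = list(
    "GO:0018786" = list(name = "haloalkane dehalogenase activity",
                        synonyms = "haloalkane dehalogenase activity",
                        parents = character(0)),
    "GO:0004089" = list(name = "carbonate dehydratase activity",
                        synonyms = c("carbonate dehydratase activity",
                                     "carbonic anhydrase activity"),
                        parents = character(0)),
    "GO:0008270" = list(name = "zinc ion binding",
                        synonyms = "zinc ion binding",
                        parents = character(0))
  )), class = "go_graph")
}

# Exhaustive grounding oracle: enumerate every (accession, displacement)
# with |d| <= bound, count mentions verifying on the sequence; candidates
# need at least two verified mentions (the unit the pairwise algorithm can
# anchor); rank by count desc, |d|, accession, d.
brute_force_grounding <- function(mentions, pool, lex, bound = 10L) {
  uniq <- mentions[!duplicated(mentions$normalized), , drop = FALSE]
  best <- NULL
  for (acc in sort(pool$accessions$accession)) {
    seq <- lex$accession_to_sequence[[acc]]
    if (is.null(seq)) next
    for (d in -bound:bound) {
      ok <- vapply(seq_len(nrow(uniq)), function(i) {
        p <- uniq$position[i] + d
        p >= 1L && p <= nchar(seq) && substr(seq, p, p) == uniq$wildtype[i]
      }, logical(1))
      # the pairwise algorithm anchors on a pair of distinct positions
      if (sum(ok) < 2L || length(unique(uniq$position[ok])) < 2L) next
      cand <- list(accession = acc, d = d, count = sum(ok), ok = ok)
      if (is.null(best) ||
          cand$count > best$count ||
          (cand$count == best$count && abs(cand$d) < abs(best$d)) ||
          (cand$count == best$count && abs(cand$d) == abs(best$d) &&
           cand$accession < best$accession) ||
          (cand$count == best$count && abs(cand$d) == abs(best$d) &&
           cand$accession == best$accession && cand$d < best$d)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(list(accession = NA_character_, displacement = NA_integer_,
                grounded = character(0)))
  }
  list(accession = best$accession, displacement = best$d,
       grounded = sort(uniq$normalized[best$ok]))
}

# random grounding instance: a small lexicon plus mentions partly consistent
# with one sequence at one displacement, partly noise
random_grounding_instance <- function() {
  n_seq <- sample(1:4, 1)
  lex <- empty_protein_lexicon()
  accs <- sprintf("RND%04d", seq_len(n_seq))
  for (a in accs) {
    lex <- lexicon_add_record(lex, accession = a, protein_names = paste("p", a),
                              sequence = paste0(
                                sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                       sample(40:200, 1), replace = TRUE),
                                collapse = ""))
  }
  k <- sample(2:5, 1)
  target <- sample(accs, 1)
  seq <- lex$accession_to_sequence[[target]]
  d <- sample(-10:10, 1)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rows <- lapply(seq_len(k), function(i) {
    if (stats::runif(1) < 0.7) {
      p <- sample(seq_len(nchar(seq)), 1)
      n_auth <- p - d
      if (n_auth >= 1L) {
        w <- substr(seq, p, p)
        m <- sample(setdiff(aa, w), 1)
        return(data.frame(wildtype = w, position = n_auth, mutant = m,
                          normalized = paste0(w, n_auth, m),
                          stringsAsFactors = FALSE))
      }
    }
    w <- sample(aa, 1); m <- sample(setdiff(aa, w), 1)
    n_auth <- sample(1:210, 1)
    data.frame(wildtype = w, position = n_auth, mutant = m,
               normalized = paste0(w, n_auth, m), stringsAsFactors = FALSE)
  })
  mentions <- unique(do.call(rbind, rows))
  pool <- structure(list(
    accessions = data.frame(accession = accs, support = 1L,
                            stringsAsFactors = FALSE),
    organism_filtered = FALSE), class = "candidate_pool")
  list(lex = lex, mentions = mentions, pool = pool)
}
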