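# Synthetic test worlds: a mini protein lexicon, a mini molecular-function
# ontology, template documents with planted mutations/properties/directions,
# and the matching gold standard. Everything is a pure function of the seed.

FIXTURE_ADJECTIVES <- c("alkane", "ester", "amide", "halide", "sulfate",
                        "peptide", "lactone", "epoxide", "nitrile", "phenol",
                        "glycoside", "thioester")
FIXTURE_NOUNS <- c("hydrolase", "transferase", "esterase", "oxidase",
                   "reductase", "isomerase", "synthase", "lyase", "ligase",
                   "dehydratase")
FIXTURE_GENERA <- c("Fictibacter", "Synthomonas", "Modelococcus",
                    "Simulobium", "Exemplaria", "Mockella")
FIXTURE_SPECIES <- c("aquaticus", "luteus", "simulans", "arenarius",
                     "viridis", "montanus")

# filler sentences: no gazetteer names, no mutation patterns, no property
# head nouns, no kinetic variables, no directionality or negation words
FIXTURE_DISTRACTORS <- c(
  "The purified enzyme was stored frozen prior to assays.",
  "Crystals grew within several days under standard conditions.",
  "All reagents were obtained from commercial suppliers.",
  "Assays were performed in triplicate at ambient temperature.",
  "The buffer contained glycerol and trace salts.",
  "Samples were dialyzed overnight against fresh buffer.",
  "Protein concentration was determined spectrophotometrically.")

#' Specification of a synthetic test world
#'
#' @param seed Integer RNG seed; the generated world is a pure function of
#'   this specification (same seed, byte-identical corpus).
#' @param n_proteins Number of lexicon proteins (each with its own organism).
#' @param n_docs Number of documents.
#' @param seq_length Length range (min, max) of random sequences; min >= 30.
#' @param mutations_per_doc Range (min, max) of planted mutations per
#'   document; the grounding algorithm needs at least 2.
#' @param displacement Constant offset between author numbering and the
#'   stored sequence (e.g. -1 emulates N-terminal methionine cleavage).
#' @param distractor_rate Expected density of decoy filler sentences
#'   inserted between template sentences (0 = noise-free).
#' @param p_separated Probability that a planted impact sits in the sentence
#'   after its mutant mention instead of the same sentence.
#' @export
fixture_spec <- function(seed = 1L, n_proteins = 6L, n_docs = 10L,
                         seq_length = c(60L, 120L),
                         mutations_per_doc = c(2L, 4L),
                         displacement = 0L, distractor_rate = 0,
                         p_separated = 0.5) {
  stopifnot(n_proteins >= 1L, n_docs >= 1L, seq_length[1] >= 30L,
            mutations_per_doc[1] >= 2L, distractor_rate >= 0,
            distractor_rate <= 1)
  list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
       n_docs = as.integer(n_docs), seq_length = as.integer(seq_length),
       mutations_per_doc = as.integer(mutations_per_doc),
       displacement = as.integer(displacement),
       distractor_rate = distractor_rate, p_separated = p_separated)
}

# run expr under a locally seeded RNG, restoring the caller's RNG state
with_fixture_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_sequence <- function(len) {
  paste0(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# verify that (accession, displacement) is the unique best grounding for the
# planted mutation set across the whole lexicon within the search bound;
# author_pos are the positions as they will appear in the text, so the
# planted solution is displacement d_true
planting_is_unique <- function(lex, accession, d_true, author_pos, wildtypes,
                               bound = 10L) {
  k <- length(author_pos)
  for (acc in names(lex$accession_to_sequence)) {
    seq <- lex$accession_to_sequence[[acc]]
    for (d in -bound:bound) {
      if (acc == accession && d == d_true) next
      cnt <- 0L
      for (i in seq_len(k)) {
        p <- author_pos[i] + d
        if (p >= 1L && p <= nchar(seq) && substr(seq, p, p) == wildtypes[i])
          cnt <- cnt + 1L
      }
      if (cnt >= k) return(FALSE)
    }
  }
  TRUE
}

#' Generate a synthetic test world
#'
#' Builds `n_proteins` random sequences with invented protein, gene and
#' organism names, a mini molecular-function ontology (one activity and one
#' binding concept per protein under a shared root), and `n_docs` template
#' documents. Each document introduces one protein and plants 2 or more
#' mutations consistent with that protein's sequence at the requested
#' displacement; every mutation carries one impact sentence drawn from
#' templates (same-sentence or following-sentence style) whose direction
#' word, property mention and relation are recorded in the gold standard.
#' Planted mutation sets are re-drawn until they ground uniquely to the
#' intended (accession, displacement) across the whole lexicon, so the gold
#' grounding is unambiguous by construction. Decoy filler sentences are
#' interleaved at `distractor_rate`; they contain no entities, properties or
#' direction words, but push mutation mentions and impacts apart.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Optional directory: writes `lexicon.txt` (simplified
#'   flat-file), `go.obo`, one `docs/<doc_id>.txt` per document and
#'   `gold.tsv`.
#' @return A list with `lexicon`, `go`, `texts` (named character vector),
#'   `gold` and `spec`.
#' @export
generate_world <- function(spec = fixture_spec(), out_dir = NULL) {
  with_fixture_rng(spec$seed, {
    n <- spec$n_proteins
    combos <- expand.grid(adj = FIXTURE_ADJECTIVES, noun = FIXTURE_NOUNS,
                          stringsAsFactors = FALSE)
    if (n > nrow(combos)) stop("too many proteins requested")
    pick <- sample(nrow(combos), n)
    adjs <- combos$adj[pick]; nouns <- combos$noun[pick]

    cap <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
    protein_names <- paste(cap(adjs), nouns)
    gene_names <- vapply(seq_len(n), function(i) {
      paste0(paste0(sample(letters, 3L, replace = TRUE), collapse = ""),
             LETTERS[i])
    }, character(1))
    organisms <- paste(
      FIXTURE_GENERA[((seq_len(n) - 1L) %% length(FIXTURE_GENERA)) + 1L],
      FIXTURE_SPECIES[((seq_len(n) - 1L) %/% length(FIXTURE_GENERA)) %%
                        length(FIXTURE_SPECIES) + 1L])
    accessions <- sprintf("SYN%04d", seq_len(n))

    # mini GO: shared root plus one activity and one binding concept per protein
    go_concepts <- list()
    root <- "GO:7000000"
    go_concepts[[root]] <- list(name = "molecular function",
                                synonyms = "molecular function",
                                parents = character(0))
    go_act <- sprintf("GO:%07d", 7000000L + seq_len(n))
    go_bind <- sprintf("GO:%07d", 7000000L + n + seq_len(n))
    for (i in seq_len(n)) {
      act_name <- paste(adjs[i], nouns[i], "activity")
      bind_name <- paste(adjs[i], nouns[i], "binding")
      go_concepts[[go_act[i]]] <- list(name = act_name, synonyms = act_name,
                                       parents = root)
      go_concepts[[go_bind[i]]] <- list(name = bind_name,
                                        synonyms = bind_name, parents = root)
    }
    go <- structure(list(concepts = go_concepts), class = "go_graph")

    lex <- empty_protein_lexicon()
    seqs <- character(n)
    for (i in seq_len(n)) {
      seqs[i] <- random_sequence(
        sample(spec$seq_length[1]:spec$seq_length[2], 1L))
      lex <- lexicon_add_record(lex, accession = accessions[i],
                                protein_names = protein_names[i],
                                gene_names = gene_names[i],
                                organisms = organisms[i],
                                go_ids = c(go_act[i], go_bind[i]),
                                sequence = seqs[i])
    }

    gold_mut <- NULL
    gold_rel <- NULL
    texts <- character(spec$n_docs)
    ids <- sprintf("doc%03d", seq_len(spec$n_docs))

    for (di in seq_len(spec$n_docs)) {
      pi <- ((di - 1L) %% n) + 1L
      seq <- seqs[pi]
      d <- spec$displacement
      k <- sample(spec$mutations_per_doc[1]:spec$mutations_per_doc[2], 1L)
      lo <- max(1L, 1L + d)       # author position must be >= 1
      avail <- lo:nchar(seq)
      if (length(avail) < k) stop("sequence too short for requested mutations")

      # re-draw until the planted set grounds uniquely across the lexicon
      for (attempt in seq_len(200L)) {
        positions <- sort(sample(avail, k))
        wildtypes <- vapply(positions, function(p) substr(seq, p, p),
                            character(1))
        mutants <- vapply(wildtypes, function(w)
          sample(setdiff(AA_ALPHABET, w), 1L), character(1))
        author_pos <- positions - d
        if (planting_is_unique(lex, accessions[pi], d, author_pos, wildtypes))
          break
        if (attempt == 200L)
          stop("could not plant a uniquely groundable mutation set")
      }
      wnm <- paste0(wildtypes, author_pos, mutants)

      sentences <- sprintf(
        "%s (%s) from %s catalyzes the conversion of model substrates.",
        protein_names[pi], gene_names[pi], organisms[pi])

      for (mi in seq_len(k)) {
        dir_cat <- sample(c("positive", "negative", "neutral"), 1L)
        is_kinetic <- stats::runif(1) < 0.4
        if (is_kinetic) {
          variable <- sample(c("KM", "KCAT", "KCAT_OVER_KM"), 1L)
          prop_surface <- switch(variable, KM = "Km", KCAT = "kcat",
                                 KCAT_OVER_KM = "kcat/Km")
          prop_key <- variable
        } else {
          use_bind <- stats::runif(1) < 0.5
          prop_key <- if (use_bind) go_bind[pi] else go_act[pi]
          prop_surface <- go$concepts[[prop_key]]$name
        }
        phr <- switch(dir_cat,
                      positive = paste0("an increase of ", prop_surface),
                      negative = paste0("a reduction of ", prop_surface),
                      neutral = paste0("similar ", prop_surface))
        separated <- stats::runif(1) < spec$p_separated
        if (separated) {
          sentences <- c(sentences,
            sprintf("The %s mutant was constructed by targeted mutagenesis.",
                    wnm[mi]),
            paste0(cap(phr), " was observed."))
        } else {
          sentences <- c(sentences,
            sprintf("The %s mutant showed %s.", wnm[mi], phr))
        }
        gold_rel <- rbind(gold_rel, data.frame(
          doc_id = ids[di], mutation = wnm[mi], direction = dir_cat,
          property_key = prop_key, stringsAsFactors = FALSE))
      }

      gold_mut <- rbind(gold_mut, data.frame(
        doc_id = ids[di], mutation = wnm, accession = accessions[pi],
        position = positions, stringsAsFactors = FALSE))

      # interleave decoy sentences between template sentences
      if (spec$distractor_rate > 0) {
        with_noise <- character(0)
        for (s in sentences) {
          with_noise <- c(with_noise, s)
          n_decoy <- stats::rpois(1L, lambda = 3 * spec$distractor_rate)
          if (n_decoy > 0L)
            with_noise <- c(with_noise,
                            sample(FIXTURE_DISTRACTORS, n_decoy,
                                   replace = TRUE))
        }
        sentences <- with_noise
      }
      texts[di] <- paste(sentences, collapse = " ")
    }
    names(texts) <- ids
    gold <- list(mutations = gold_mut, relations = gold_rel)

    world <- list(lexicon = lex, go = go, texts = texts, gold = gold,
                  spec = spec)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_protein_lexicon(lex, file.path(out_dir, "lexicon.txt"))
      write_go_obo(go, file.path(out_dir, "go.obo"))
      dir.create(file.path(out_dir, "docs"), showWarnings = FALSE)
      for (id in names(texts))
        writeLines(texts[[id]], file.path(out_dir, "docs", paste0(id, ".txt")))
      write_gold_standard(gold, file.path(out_dir, "gold.tsv"))
    }
    world
  })
}
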