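# mutimpact

Rule-based extraction and grounding of protein mutation impacts from text.

Experimental papers describe point mutations and what they do to a protein
— "The W125F mutant showed only a slight reduction of activity" — but that
knowledge is locked in prose. `mutimpact` is for protein engineers, curation
teams and text-mining researchers who want those statements as structured,
queryable assertions: which mutation, on which database sequence, changed
which property, in which direction.

## What the pipeline computes

Given plain-text documents, a protein lexicon (a simplified
Swiss-Prot-style flat file mapping names ↔ accessions ↔ sequences ↔ GO
annotations) and a Gene Ontology OBO file, the pipeline:

1. **Finds mentions** — point mutations normalized to wNm form (wildtype
   residue, position, mutant residue: `Trp125Phe` → `W125F`; series like
   `Arg172Lys+His65Ala` split into members), protein/gene/organism names by
   gazetteer (multiword names case-insensitive, single-word names
   case-sensitive), property noun phrases headed by *activity / binding /
   affinity / specificity*, the kinetic variables K_M, k_cat and k_cat/K_M,
   and directionality words in five categories (positive, negative,
   neutral, negation, non-neutral).

2. **Grounds mutations to sequences.** For each pair of mentions
   w1N1m1, w2N2m2 (N1 < N2) it builds the regular expression

       w1 .{N2 - N1 - 1} w2        e.g.  A378C + S381L  →  "A..S"

   and scans every candidate sequence at all offsets. Each match proposes a
   numbering displacement d = offset − N1 (d = −1 is initiator-Met
   cleavage); all mentions are verified at N + d, and the
   (accession, displacement) grounding the most mentions wins, ties broken
   by least |d|. Unverifiable mentions are discarded.

3. **Grounds function mentions to GO** by Jaccard similarity of stop-word
   filtered, Porter-stemmed token sets between the mention and the synonyms
   of concepts annotated to the pooled accessions (plus is_a ancestors).

4. **Extracts relations.** Within one-property sentence segments, the
   nearest direction word classifies the impact with score
   1/tokenDistance; impacts link to the nearest grounded mutants within
   the same or up to three previous sentences with score
   1/sentenceDistance; contradictions resolve by the arithmetic mean of
   the scores (similarity omitted for kinetic variables).

5. **Publishes** the result as RDF triples (Turtle / N-Triples) over a
   small mutation-impact vocabulary and as standoff JSON, and can score
   itself against gold-standard TSV annotations (precision/recall for
   grounding and for complete mutation–direction–property triples).

A synthetic-corpus generator (`generate_world()`) builds closed test
worlds — lexicon, mini-ontology, template documents, gold standard — so
the whole pipeline is testable offline.

## Worked example

```r
library(mutimpact)

# a 200-residue sequence with W at 125 and D at 170
base <- strsplit(strrep("MKLVNSTEGQRFYHIPCWDA", 10), "")[[1]]
base[125] <- "W"; base[170] <- "D"
seq200 <- paste0(base, collapse = "")

lex <- lexicon_add_record(
  empty_protein_lexicon(),
  accession     = "EX00001",
  protein_names = "Haloalkane dehalogenase",
  gene_names    = "DhlA",
  organisms     = "Xanthobacter autotrophicus",
  go_ids        = "GO:0018786",
  sequence      = seq200)

go <- structure(list(concepts = list(
  "GO:0018786" = list(name = "haloalkane dehalogenase activity",
                      synonyms = "haloalkane dehalogenase activity",
                      parents = character(0)))), class = "go_graph")

text <- paste(
  "Haloalkane dehalogenase (DhlA) from Xanthobacter autotrophicus",
  "hydrolyses terminally chlorinated and brominated n-alkanes.",
  "The D170N mutant was described previously.",
  "The W125F mutant showed only a slight reduction of activity (Vmax)",
  "and a larger increase of Km with 1,2-dibromoethane.")

res <- annotate_document(text, "example", lex, go)
res$grounding
res$relations[, c("mutation", "direction", "property_key",
                  "impact_score", "relation_score", "similarity",
                  "combined_score")]
```

prints

```
<grounding_result: EX00001 (d=0), 2 grounded, 0 discarded>
  mutation direction property_key impact_score relation_score similarity
1    W125F  negative   GO:0018786          0.5              1  0.3333333
2    W125F  positive           KM          0.5              1         NA
  combined_score
1      0.6111111
2      0.7500000
```

Both mutation mentions ground on the lexicon sequence with displacement 0.
The W125F sentence splits at "and" into two one-property segments:
"reduction" (negative) scores 1/2 against *activity* (two space tokens
apart), which grounds to GO:0018786 with Jaccard 1/3 ({activ} vs
{haloalkan, dehalogenas, activ}); "increase" (positive) scores 1/2 against
K_M. Both impacts sit in the same sentence as W125F
(relation score 1), and D170N — one sentence further — is not the nearest
mutant, so exactly two relations emerge. `emit_triples(res)` turns the
result into RDF; `write_standoff_json(res)` into standoff JSON.

A shell front end wraps the same functions:

```sh
Rscript inst/scripts/mutimpact.R make-fixtures --seed 1 --out-dir world
Rscript inst/scripts/mutimpact.R annotate --lexicon world/lexicon.txt \
    --go world/go.obo --out-dir out world/docs
Rscript inst/scripts/mutimpact.R evaluate --lexicon world/lexicon.txt \
    --go world/go.obo --gold world/gold.tsv world/docs
```

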