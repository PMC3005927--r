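---
title: "Extracting and grounding mutation impacts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and grounding mutation impacts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutimpact)
```

## The problem

Protein engineering studies report point mutations and their consequences in
free text: "The W125F mutant showed only a slight reduction of activity".
Turning such sentences into structured assertions requires four coupled
subtasks, each implemented as a rule-based module in this package:

1. **Mention detection** — point mutations in wNm form (wildtype residue,
   author position, mutant residue), protein/gene/organism names,
   protein-property phrases, and directionality words.
2. **Grounding** — resolving a document's mutation set to a residue position
   on a specific database sequence (accession), and a function phrase to a
   Gene Ontology molecular-function concept.
3. **Relation detection** — pairing directionality words with properties
   into impact statements, and impacts with the mutants that cause them.
4. **Publication** — RDF instance triples over a small concept vocabulary,
   plus standoff JSON.

Everything is deterministic: identical input text and lexicons always
produce identical annotations.

## Text model

Tokens are whitespace-delimited chunks with edge punctuation
(`. , ; : ( ) [ ]`) detached into separate tokens. `/`, `-` and `+` stay
inside tokens so that `kcat/Km`, `30-40%` and mutation series like
`Arg172Lys+His65Ala` survive intact; internal punctuation
(`1,2-dibromoethane`) is never split. Detached punctuation tokens are
excluded from *token distance*, which counts space-delimited tokens only.

Sentences open after `.?!` followed by whitespace and an uppercase letter or
digit. A configurable protected-abbreviation list (`e.g.`, `i.e.`,
`et al.`, `Fig.`, ...) blocks spurious boundaries; decimal numbers cannot
split because a digit follows the period without whitespace. Character
offsets are 0-based and half-open; sequence positions are 1-based, the
convention that wNm mentions use.

## Mention detection

**Mutations.** Three pattern families are matched in order of precedence:
one-letter wNm (`W125F`), three-letter wNm (`Trp125Phe`, with `+`-joined
series split into individual mentions), and three-letter residue-position
items (`Trp-125`, `Asp260`) inside a
"replacement/mutation/substitution of ... with/to/by *residue name*" frame.
A word-boundary guard rejects candidates embedded in longer alphanumeric
identifiers, which keeps strain names (`GJ10`) and plasmid names (`pW125F`)
out. Mentions whose wildtype equals the mutant are rejected during
normalization. These three families cover the mention forms the package
targets; the long tail of natural-language paraphrases ("the tryptophan at
position 125 was changed ...") is out of scope.

**Proteins, genes, organisms.** Gazetteer matching against a lexicon
derived from a simplified Swiss-Prot-style flat file. Names of two or more
words match case-insensitively (longer names are unambiguous, so recall is
cheap); single-word names match case-sensitively (short symbols like `DhlA`
are precision-critical); organism names always match case-insensitively.
At each position the longest matching name wins and matched spans are not
re-entered. All `DE` and `GN` names of a record are ingested — the package
does not try to distinguish recommended from alternative names.

**Properties.** Function mentions are noun phrases ending in one of the
head nouns *activity*, *binding*, *affinity* or *specificity*. The chunker
is deliberately shallow: the noun phrase is the maximal contiguous run of
content words (no stop words, no detached punctuation, no directionality
words, no digit-bearing tokens) ending at the head noun, with the rightmost
head of a run acting as its head. A part-of-speech tagger would be more
general, but the head-noun anchor makes this dictionary-driven
approximation deterministic and adequate for the constructions the
pipeline targets. Kinetic variables — the Michaelis constant
K~M~, the turnover constant k~cat~ and the efficiency
k~cat~/K~M~ — are matched as whole-token surface
variants (`Km`, `K_m`, `K(m)`, `kcat`, `k_cat`, `kcat/Km`). Whole-token
anchoring gives the compound precedence over its parts and automatically
rejects variables fused into larger expressions (`Km=5`). Stability and
other non-function properties are not modeled.

**Directionality.** Five disjoint categories — positive, negative, neutral,
negation, non-neutral — seeded from compact word lists (`increase`,
`reduce`, `similar`, `not`, `affect`, ...) and expanded with deterministic
orthographic rules (plural, past, gerund, and `-tion`/`-ion`
nominalizations such as `reduce → reduction`). Matching is token-exact and
case-insensitive against the expanded list, so no stemmer runs at match
time. Negation words and very short words are not expanded. If an
expansion collides across categories the first category in the fixed order
wins, with a warning. The shipped vocabulary is intentionally small; words
like *intact* that arguably signal neutrality are not included, which
costs recall but never precision.

## Grounding

**Candidate pool.** Accessions of all matched protein/gene names are
pooled, together with accessions of lexicon names equal to a matched name
plus an alphanumeric suffix (a mention of `DhlA` also pulls in `DhlA2`;
this compensates for the absence of co-reference resolution between short
and long forms). The pool is trimmed to accessions whose mention support is
at least `ceiling(f * max_support)` with `f = 0.5` by default — "the most
frequent names win, but a near-tie survives". When the document mentions
organisms, accessions not associated with any mentioned organism are
discarded; if that empties the pool the unfiltered pool is restored with a
warning, since a wrong organism tag should not silence grounding entirely.

**Mutation grounding.** For each pair of mentions
w~1~N~1~m~1~, w~2~N~2~m~2~ (sorted, N~1~ < N~2~) the pairwise pattern is
`w1 .{N2-N1-1} w2` — for A378C and S381L, `A..S`. Every overlapping match
offset on a candidate sequence proposes a displacement
`d = offset − N1`, the constant shift between author numbering and
database numbering (−1 is the classic initiator-methionine cleavage).
All mentions are verified at `N + d`; the (accession, d) candidate
grounding the most mentions wins, with ties broken by smaller |d|, then
lexicographic accession, then smaller d. Unverified mentions are
discarded. The displacement search is bounded at ±10 by default: large
enough for Met cleavage and short tag/signal-peptide offsets, small enough
that an exhaustive oracle stays cheap. The algorithm needs at least two
distinct mentions to anchor a pair, and refuses to run below that — a
single mention matches far too many offsets to disambiguate. The test
suite checks the implementation against an independent brute-force search
over every (sequence, displacement) pair on hundreds of random instances.

**Function grounding.** Candidate concepts are the GO molecular-function
annotations of the pooled accessions plus all their is_a ancestors
(ancestors widen the synonym pool for generic mentions like "hydrolase
activity"; descendants are not added, since annotations are already the
most specific assertion available). Mention tokens and concept synonyms
are lowercased, stop-word-filtered and stemmed with an English Porter
stemmer implemented in the package. The similarity of two prepared sets is
their *relative intersection*; the package uses the Jaccard index
|N∩G| / |N∪G| by default because it is symmetric and bounded in [0,1], and
exposes |N∩G|/|G| and |N∩G|/|N| as configurable alternatives behind the
same function. The best-scoring concept is attached; zero-overlap mentions
stay ungrounded.

## Relation detection

Sentences with several properties are split into one-property segments at
a comma or *and* between consecutive properties, falling back to a cut
immediately before the later property. Within a segment, the non-negation
direction term nearest the property determines the direction (leftmost
wins ties), and the impact score is

> impactScore = 1 / tokenDistance,

where tokenDistance is 1 plus the number of space tokens strictly between
term and property, and exactly 1 when the term lies inside the property
noun phrase. A negation term within two space tokens before the chosen
term remaps the category: positive → neutral, negative → neutral,
neutral → non-neutral, non-neutral → neutral (so "no effect on activity"
comes out neutral).

Each grounded mutation mention constitutes one mutant. An impact links to
the nearest grounded mentions, searching the same sentence and then at
most three previous sentences:

> relationScore = 1 / sentenceDistance, sentenceDistance ∈ {1, 2, 3, 4}.

Mentions in following sentences are never linked. All mentions at the
minimal distance receive the relation. The combined score of a relation is
the arithmetic mean of relation score, impact score and — for grounded
function properties — the GO similarity; kinetic variables have no
similarity term. When relations on the same (mutant, property) key
disagree in direction, only the highest combined score survives, earliest
relation winning ties. Both score formulas are the simplest bounded,
monotone functions that equal 1 in the same-phrase/same-sentence base
case; they are isolated behind single functions and easy to swap.

## The synthetic corpus generator

`generate_world()` builds a closed world: random sequences over the
20-letter alphabet with invented multiword protein names, single-word gene
symbols and organism binomials; a mini molecular-function ontology with
one activity and one binding concept per protein under a shared root; and
template documents. Each document introduces one protein and plants two to
four mutations; each mutation carries one impact sentence, either
same-sentence ("The A12G mutant showed a reduction of ...") or
following-sentence ("The A12G mutant was constructed ... A reduction of
... was observed."). Planted mutation sets are re-drawn until they ground
uniquely to the intended (accession, displacement) across the whole
lexicon, so the gold standard is unambiguous by construction and a
noise-free run must reach precision = recall = 1.0. Decoy filler
sentences — guaranteed free of entities, properties and direction words —
are interleaved at a configurable rate; they push mutants and impacts
apart, degrading recall (relations fall out of the sentence window) while
leaving precision untouched, the profile a distance-based linker should
show. The generator is a pure function of its specification: same seed,
byte-identical corpus.

What the generator does **not** emulate: realistic scientific prose,
co-reference ("the double mutant"), nickname mutants ("Mut1"), tables and
figures, total-loss-of-function phrasing ("catalytically inactive"),
DNA-level variation, ambiguous protein naming across databases, and
stability properties. Perfect scores on synthetic corpora therefore
demonstrate internal consistency of rules, grounding and scoring — not
performance on real articles, where exactly those phenomena dominate the
error budget.

## Problem sizes and numerical choices

The shipped test suite and the acceptance script use 50-document synthetic
corpora (roughly 150–160 planted relations), 500 random grounding
instances with up to 5 mutations on sequences of at most 200 residues, and
displacement worlds of 20 documents; these sizes give stable metrics while
keeping a full run in the order of a minute. Other fixed choices:
candidate-pool fraction 0.5; displacement bound ±10; negation window 2
space tokens; grounding correctness in evaluation requires accession *and*
position (the stricter reading); micro-averaged metrics with set
semantics, zero-prediction precision reported as 0 with an explicit
`precision_defined = FALSE` flag; empty gold standards are an error rather
than a silent 0/0.

## Known limitations

* Only the three mutation mention families above; insertions, deletions
  and DNA-level mentions are out of scope.
* No co-reference resolution; pronominal and nickname mutants never link.
* The shallow noun-phrase chunker can truncate phrases containing
  modifiers it classifies as non-content.
* The direction vocabulary is small by design; unseen directionality words
  cost recall.
* GO grounding is limited to concepts annotated to the pooled accessions
  (plus ancestors); a correct mention of an unannotated function stays
  ungrounded.
* The RDF vocabulary lives in a package-local namespace; the seven concept
  classes and the impact-linking predicates are fixed, the remaining
  predicates are minted by this package and documented in one place
  (`mi_vocabulary()` in the source).
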