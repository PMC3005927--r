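Package: mutimpact
Title: Rule-Based Extraction and Grounding of Protein Mutation Impacts from Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A rule-based text-mining pipeline that extracts protein point
    mutation mentions from plain-text documents, normalizes them to wNm form,
    grounds them to protein sequences and accessions via pairwise
    regular-expression matching with numbering-displacement detection, tags
    protein/gene/organism names with gazetteers built from a simplified
    Swiss-Prot-style lexicon, detects protein-property mentions (function noun
    phrases and the kinetic variables KM, kcat and kcat/KM) and directionality
    words, grounds function mentions to Gene Ontology molecular-function
    concepts by stemmed-token similarity, links mutants to impacts by sentence
    distance, and emits the results as RDF triples (Turtle/N-Triples) and
    standoff JSON. Includes a synthetic-corpus generator and an evaluation
    module computing precision and recall against gold-standard annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
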