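Package: cnvdisplace
Title: Copy-Number Displacement Scans from Pooled Paired-End Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects deletions and tandem duplications from pooled paired-end
    sequencing (Pool-Seq) alignments using discordant read-pair signatures
    (unusually distant inserts for deletions, everted pairs for tandem
    duplications), and isolates variants showing copy-number displacement,
    that is consistent, directional allele-frequency divergence between two
    behavioural classes of populations across replicate pairwise comparisons.
    Includes a synthetic Pool-Seq read-pair generator with planted truth
    variants, per-pool insert-size profiling and CNV calling with a minimum
    supporting-pair threshold, dual-criterion divergence tests against
    length-matched empirical read-depth-ratio nulls, replicate-consistency and
    control-test filtering of candidates, and masked-genome-aware permutation
    tests for spatial clustering and annotation-track enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    withr
Config/testthat/edition: 3
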