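Package: nmdscreen
Title: Screen Spliced Transcripts for NMD Immunity and Polycistronic Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies spliced human transcripts as eliciting or immune to
    nonsense-mediated mRNA decay (NMD) under the 55-nucleotide rule, in its
    classic 3'-UTR form and extended to the 5' UTR. Enumerates ATG-initiated
    open reading frames in three reading frames, evaluates minimal Kozak
    context, searches 3' UTRs for rescuing ORFs that neutralize exon-junction
    complexes left after the pioneer round of translation, and scores
    polycistronic transcript candidates with homology, protein-evidence and
    domain-sufficiency decision rules. Includes expression-based validation
    (Welch t-test verdicts for gene identification by NMD inhibition) and
    translation-initiation-site matching, plus deterministic synthetic fixture
    generators covering every transcript architecture the screen distinguishes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
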