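Package: xenocross
Title: Cross-Hybridization and Cross-Alignment Analysis for
    Pseudo-Xenograft Titration Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies microarray probes that cross-hybridize and RNA-Seq
    gene models that cross-align between human and mouse in mixed
    ("pseudo-xenograft") samples. Implements replicate-aware present/absent
    detection calls, the titration set-algebra definition of a crosser
    ((B u C u D) - A over a 25%-step mixture series) alongside the simpler
    pure-sample definition, normalization of platform catalogs to a unified
    CCDS identifier space, ortholog-content summaries of crosser lists, and
    exact Venn region counts across samples and technologies. A synthetic
    titration-experiment generator with planted crossers makes every stage
    of the pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
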