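Package: minsynr
Title: Design and Scoring of Minimal Synthetic Plant Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing minimal synthetic plant promoters (MinSyns)
    from catalogues of candidate cis-regulatory elements (CREs). Provides
    position-weight-matrix scanning of promoter sequences with exact
    p-value score thresholds, in-silico promoter dissection (CRE deletion
    and relocation variants), stochastic assembly of MinSyn sequences from
    a CRE pool under a fixed architecture (random prefix, CRE-bearing
    variable region, TATA box, minimal core), a per-base promoter-strength
    model with TATA-proximity weighting and experimental calibration, and
    an audit for transcription-factor binding sites created unintentionally
    at sequence junctions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    rtracklayer,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
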