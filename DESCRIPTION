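Package: switchsim
Title: Stochastic Modeling of Reverse-Transcriptase Template Switching and
    Nontemplated Addition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative model and analysis toolkit for the template-switching
    chemistry of MMLV-type reverse transcriptases. Simulates first-strand cDNA
    synthesis as a per-step competition among nontemplated nucleotide addition,
    template switching onto a template-switching oligo (TSO), and termination;
    emits synthetic FASTQ libraries with ground-truth logs, capillary
    electrophoresis peak tables, and intact-mass lists. Companion analysis code
    implements anchored parsing of three amplicon library designs,
    composition-bias normalization, nontemplated-addition and cDNA-cTSO junction
    profiling, ladder-calibrated CE efficiency quantification, and enumeration of
    nucleotide compositions consistent with deconvoluted intact masses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
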