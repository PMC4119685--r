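Package: srnaprof
Title: Small RNA-Seq Quality Evaluation and miRNA Expression Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A two-stage pipeline for single-end small RNA sequencing
    libraries. The read-processing stage collapses raw FASTQ reads into
    unique tags, detects and trims the 3' sequencing adaptor, flags
    adaptor self-ligation products, and reports library quality indices
    (self-ligation rate, read length distribution, qualified-read yield).
    The mapping stage places qualified tags on miRNA hairpin precursors
    with 3' soft-clipping, classifies the remaining tags hierarchically
    against rRNA, tRNA, mRNA, ncRNA and genome references, and reports
    miRNA expression profiles in transcripts per million, 3' end
    modification patterns, isomiR tables, opposite-arm miRNA candidates
    and detection counts. A deterministic library simulator with full
    per-read ground truth makes every stage testable offline.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
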