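Package: equilnc
Title: Candidate Long Non-Coding RNA Discovery from Multi-Tissue
    RNA-Seq Transcriptomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A stepwise filtering pipeline for annotating candidate long
    non-coding RNA (lncRNA) in assembled transcriptomes: removal of lowly
    expressed transcripts (mean TPM across tissues, with a stricter
    per-tissue rule for single-exon models), removal of short transcripts,
    removal of transcripts with protein-coding capability (open reading
    frame detection plus protein-database and motif homology), and removal
    of likely UTR fragments lying within a fixed flank of protein-coding
    genes on the same strand.  Transcripts lost to the coding-potential
    filter can be rescued by nucleotide homology to known lncRNA of
    another species.  Also provides a sequence-conservation statistic
    (best-hit identity times query coverage, summarised as a cumulative
    frequency curve), tissue-specificity calculus (expressed sets,
    uniquely present/absent transcripts, variable-transcript selection and
    correlation-based bi-clustering), and a seeded synthetic-transcriptome
    generator with planted ground truth so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    methods,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr
Config/testthat/edition: 3
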