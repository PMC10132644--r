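Package: crisprEscape
Title: Quantifying Phage Escape from CRISPR-Cas Targeting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for measuring bacteriophage escape from
    CRISPR-Cas (Cas12a/Cas9) targeting. Classifies amplicon deep-sequencing
    read pairs over a protospacer+PAM target window into mutation categories
    with PAM-relative position labels, computes positional mutation-enrichment
    Z-scores against a non-targeted control and haplotype nucleotide
    diversity, detects large deletions with junction microhomology in
    long reads, fits first-order cleavage kinetics (k_obs) from gel
    densitometry time courses, and quantifies mutant competition read
    ratios. Includes seeded synthetic-data generators (phage populations
    under selection, paired-end amplicon reads, long reads with planted
    deletions, kinetics time courses) so the full pipeline is testable
    end-to-end without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
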