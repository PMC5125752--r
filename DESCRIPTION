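Package: tajimascan
Title: Windowed Tajima's D Scans, Shared-Haplotype Signatures and
    Within-Species dN/dS for Inbred Strain Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide selection scans for panels of inbred (effectively
    haploid) wild strains. Computes segregating sites, nucleotide diversity,
    Watterson's theta and Tajima's D in fixed-size genomic windows from a
    multi-sample VCF; quantifies enrichment of gene families (for example
    chemoreceptors) in the extreme tails of the D distribution; detects a
    balancing-selection signature in which most SNPs of a gene segregate on
    one shared strain bipartition (two deep haplotype lineages); and computes
    within-species counting dN/dS on the substitutions that distinguish the
    two lineages. Includes a seeded coalescent-style simulator that generates
    neutral, sweep-like and balanced two-lineage panels plus toy gene
    annotations and coding sequences with planted substitutions, so every
    stage of the pipeline can be verified against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    ape,
    Biostrings,
    jsonlite,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
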