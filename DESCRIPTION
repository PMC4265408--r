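Package: AlloSNP
Title: In Silico SNP and InDel Marker Discovery from Allotetraploid EST Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Polyploid-aware SNP detection and classification from
    species- and genotype-labelled EST cluster alignments, for
    allotetraploid species such as tetraploid cotton. Distinguishes
    inter-homoeologous (subgenome-fixed) variants from true
    interspecific (inter) and hemi SNPs, applies reliability and
    eligibility filters, designs PCR marker candidates under standard
    primer constraints, mines 3'UTR InDel marker templates from
    CDS-annotated mRNA (complete-CDS and cross-species homology
    routes), and computes base-variation spectrum, marker-panel
    polymorphism and linkage-map summary statistics. Includes an
    allotetraploid EST cluster simulator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
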