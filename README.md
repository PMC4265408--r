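# AlloSNP

In-silico SNP and InDel marker development from allotetraploid EST
clusters.

## The problem

EST collections from allotetraploids (cultivated cotton being the classic
case: two species, *G. hirsutum* and *G. barbadense*, each carrying A and
D subgenomes) mix transcripts of homoeologous gene copies. A polymorphic
column in an aligned EST cluster can therefore be a subgenome-fixed
**inter-homoeologous SNP** (a pseudo-SNP, useless as a marker), a true
**inter-SNP** (disjoint allele sets between species), a **hemi-SNP** (one
species monomorphic, the other polymorphic with partial overlap), or
ordinary **allelic variation** between genotypes within a species. Marker
pipelines that ignore this taxonomy design primers against differences
that do not segregate.

AlloSNP is for researchers developing PCR-based SNP/InDel markers from
transcript alignments in polyploids. It provides:

* **Variant detection** — column-wise allele tallies on species/genotype
  labelled alignments, with a two-read reliability rule separating
  reliable from putative SNPs (`detectSites()`, `reliableSites()`);
* **Polyploid-aware classification** — with `S1`, `S2` the reliable
  allele sets of the two species at a column:
  `S1 = S2, |S1| ≥ 2` → inter-homoeologous; `S1 ∩ S2 = ∅` → inter;
  unequal overlapping sets with one species polymorphic → hemi
  (`classifySite()`, `classifyCluster()`), plus the eligibility filters
  that decide which clusters/unigenes proceed to design
  (`checkInterspecificEligibility()`, `checkIntraspecificEligibility()`);
* **Marker design** — consensus templates and a deterministic
  constraint-based primer picker (length 18–24 bp, GC 40–60% / 35–60%,
  product 100–300 / 100–500 bp; Tm = 64.9 + 41·(GC − 16.4)/len used for
  ranking) (`consensusTemplate()`, `designPrimers()`);
* **3'UTR InDel mining** — complete-CDS UTR extraction (> 100 bp strict),
  redundancy removal, and a cross-species homology screen
  (Smith–Waterman, aligned length ≥ 100 bp, Karlin–Altschul E ≤ 1e-10)
  (`extractUtr3()`, `removeRedundancy()`, `homologyScreen()`,
  `groupIntoContigs()`);
* **Summary statistics** — ten-category base-variation spectrum with
  transition/transversion/indel aggregates, SNPs-per-gene by function
  category, marker-panel polymorphism rates, and linkage-map interval
  summaries (`computeSpectrum()`, `snpsPerGene()`, `panelRates()`,
  `mapSummary()`);
* **A ground-truth simulator** — allotetraploid cluster generator
  (ancestor → homoeologs → species → genotypes → reads, transition bias
  κ, per-base error) with per-event truth records (`simulateCluster()`,
  `simulateUnigene()`, `simulateMrnaSet()`, `evolveSequence()`).

## Worked example

Simulate a cluster, screen it, and design a marker:

```r
library(AlloSNP)

p <- simParams(seed = 42, nPerHaplotype = 2, dHomoeolog = 0.004,
               dSpecies = 0.004, dIntra = 0, indelRate = 0.001)
sim <- simulateCluster(p, clusterId = "demo")
sim$cluster
#> ESTCluster 'demo': 16 sequences x 500 columns
#>   species: Gb (8), Gh (8)
#>   genotypes: 4 distinct

res <- checkInterspecificEligibility(sim$cluster)
res$eligible; res$cluster_class
#> [1] TRUE
#> [1] "HEMI_ONLY"
res$sites[, c("position", "kind", "alleles", "site_class")]
#>   position         kind alleles         site_class
#> 1        4 substitution     A,T               HEMI
#> 2       37 substitution     A,C INTER_HOMOEOLOGOUS
#> 3       74        indel   C,GAP INTER_HOMOEOLOGOUS
#> 4      171 substitution     C,T               HEMI
#> ...
```

The cluster is eligible (both species have ≥ 2 sequences; it carries
reliable hemi-SNPs). The inter-homoeologous sites at columns 37, 74 and
340 are pseudo-SNPs — identical in both species — and are never targeted.
Design primers around the usable sites on the majority-rule consensus:

```r
ct <- consensusTemplate(sim$cluster)
targets <- na.omit(ct$map[res$sites$position[res$sites$site_class %in%
                                               c("INTER", "HEMI")]])
vars <- na.omit(ct$map[res$sites$position])
designPrimers(ct$template, targets, primerPreset("snp"),
              variantColumns = vars, clusterId = "demo", k = 1)[,
  c("marker_id", "fwd_seq", "rev_seq", "product_length", "covered_sites")]
#>     marker_id                  fwd_seq              rev_seq product_length
#> 1 M_demo_t2_1 TCTTCAACTTCATGACCCTCGTGC AGTCTGTAGGAGCCGTTGGT            299
#>         covered_sites
#> 1 289,304,340,394,452
```

One amplicon (299 bp, inside the 100–300 bp gate) covers five variant
columns; both primers sit on variant-free, N-free windows within the
length/GC constraints. Summaries follow the same pattern:

```r
spectrumFromCounts(c(CT = 2134, GA = 2030, CG = 533, AT = 768, CA = 599,
                     TG = 646, A_GAP = 251, C_GAP = 125, G_GAP = 144,
                     T_GAP = 235))$aggregates
#>                    family count percent
#> transition     transition  4164   55.78
#> transversion transversion  2546   34.11
#> indel               indel   755   10.11
#>                     total  7465  100.00
```

i.e. transitions account for 55.78% of these 7,465 base variations — the
transition preference typical of plant EST SNP spectra.

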