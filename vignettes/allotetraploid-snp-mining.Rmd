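---
title: "Mining SNP and InDel markers from allotetraploid EST clusters"
author: "AlloSNP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining SNP and InDel markers from allotetraploid EST clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AlloSNP)
```

## The problem

Expressed sequence tag (EST) collections are a cheap substrate for marker
development, but in an allotetraploid such as cultivated cotton
(*Gossypium hirsutum* × *G. barbadense* comparisons, AADD genomes) a naive
SNP caller is badly misled. ESTs from one gene mix transcripts of the two
homoeologous copies carried by the A and D subgenomes, so an apparently
polymorphic alignment column may be:

* an **inter-homoeologous SNP** (pseudo-SNP): a difference fixed between
  subgenomes, present identically in both species — useless as a
  species-distinguishing marker;
* an **inter-SNP**: the two species carry disjoint allele sets — a true
  interspecific marker;
* a **hemi-SNP**: one species is monomorphic while the other shows two
  alleles that partially overlap the first — usable, with caveats;
* an **intraspecific (allelic) SNP**: variation between genotypes within
  one species.

AlloSNP implements this taxonomy on aligned, species- and
genotype-labelled EST clusters, the reliability and eligibility filters
around it, constraint-based PCR marker design, 3'UTR InDel template
mining, and the usual summary statistics (variation spectrum, panel
polymorphism rates, map-interval summaries). A ground-truth simulator
generates allotetraploid clusters so the whole pipeline is testable
without any external data.

## Site classification model

For one alignment column, let $S_1$ and $S_2$ be the sets of *reliable*
alleles observed in species 1 and 2 (states $\{A,C,G,T,\text{GAP}\}$; an
allele is reliable when at least `minAlleleSupport` sequences — default 2 —
carry it, pooled over the whole column). The rules are:

| condition | class |
|---|---|
| $S_1 = S_2$, $|S_1| \ge 2$ | `INTER_HOMOEOLOGOUS` |
| $S_1 \cap S_2 = \emptyset$ | `INTER` |
| sets unequal, overlapping, exactly one polymorphic | `HEMI` |
| anything else | `UNCLASSIFIED` (defensive; unreachable for biallelic sites) |

The two-read confirmation rule for "reliable" follows common EST-SNP
practice: a singleton allele in error-prone single-pass reads is as likely
a sequencing artifact as a variant, so a singleton can never create a
site, flip a site's class, or rescue an otherwise monomorphic species.
Classification consumes reliable alleles only.

Cluster-level rollup is deterministic: no reliable sites → `NO_SNP`; any
`INTER` site → `INTER_HEMI`; otherwise any `HEMI` → `HEMI_ONLY`; otherwise
→ `HOMOEO_ONLY`. Only `INTER_HEMI` and `HEMI_ONLY` clusters proceed to
interspecific marker design, and only when each species contributes at
least `minSeqsPerSpecies` (default 2) sequences. Intraspecific unigenes
need at least `minEstsPerUnigene` (default 4) ESTs from more than one
genotype, plus at least one reliable site. The "more than one genotype"
reading of the same-genotype removal rule is deliberate: discarding every
unigene that contains any two same-genotype ESTs would discard essentially
all deep unigenes, so the filter removes unigenes whose ESTs *all* share
one genotype — those cannot show allelic variation at all.

## Variant detection conventions

* A column is a variant site when it shows ≥ 2 distinct states after
  excluding missing data. `N` and the other IUPAC ambiguity codes are
  missing data everywhere: they never contribute support and never block
  a site.
* Gap columns are independent single-base indel events; runs of gap
  columns are *not* merged. This matches spectrum bookkeeping that counts
  `A/-`, `C/-`, `G/-`, `T/-` per base, and keeps indel counting
  column-local and deterministic.
* Columns with ≥ 3 states are `complex`: excluded from classification and
  from the spectrum (no category exists for them).
* All coordinates, internal and reported, are 1-based inclusive — the
  R/Bioconductor convention used by every container this package builds
  on. Report files (`writeReport()`) are likewise 1-based.

## Marker design

`consensusTemplate()` collapses a cluster to a majority-rule consensus
(ties broken by the fixed order A < C < G < T; gap-majority columns
dropped with a retained column→template map). `designPrimers()` then
enumerates all primer windows flanking the target sites and keeps pairs
meeting the preset constraints:

* `snp` preset: length 18–24 bp (optimum 20), GC 40–60% (optimum 50),
  annealing optimum 58 °C, product 100–300 bp;
* `indel` preset: GC 35–60%, optimum 55 °C, product 100–500 bp.

Melting temperature uses the GC-method closed form
$T_m = 64.9 + 41\,(n_{GC} - 16.4)/L$. It ranks candidates against the
preset optimum but is not a hard gate, because the design criteria state
optima, not admissible ranges. Candidates are ranked by
$|T_m - T_{opt}| + |GC - 50| + |len - 20|$ summed over both primers; ties
break by leftmost forward start, then window lengths, so identical inputs
give byte-identical output. Primers may not contain `N` and may not
overlap any detected variant column (a polymorphic primer site would
compromise amplification); this is enforced even though classical design
tools leave it implicit. Targets too distant to share an amplicon are
split greedily into groups designed independently, so one template with
distant SNPs yields several markers. `k = 3` candidates per group is a
reporting choice; downstream users typically synthesize one.

## 3'UTR InDel mining

Route 1 takes mRNAs with annotated complete CDSs (`complete` flag and CDS
length divisible by 3; start/stop codon identity is deliberately not
enforced, since truncated terminal codons are common in EST-derived
records) and extracts the suffix after `cds_end`. UTRs must be *strictly*
longer than `utrMinLength` (default 100 bp). Redundancy removal is
single-linkage at ≥ 95% global identity computed over the shorter
sequence, keeping the longest member (ties: smallest id) — the criterion
is exposed as a parameter because redundancy removal is rarely specified
precisely in marker papers.

Route 2 screens sequences against a reference 3'UTR set (e.g. the
*Arabidopsis* 3'UTR collection) with Smith–Waterman local alignment
(match +1, mismatch −2, gap open −5, gap extend −2) and keeps hits with
aligned length ≥ 100 bp and Karlin–Altschul expectation
$E = K m n e^{-\lambda S} \le 10^{-10}$, with the ungapped parameters for
+1/−2 scoring ($\lambda = 1.33$, $K = 0.621$) applied to the gapped score
as a documented approximation. "Matched sequence length" is read as
alignment length (including gaps), not query coverage. Retained queries
are grouped into contigs and singlets by single-linkage over ≥ 40 bp
overlaps at ≥ 95% identity — a deliberate lightweight stand-in for an
overlap-layout assembler, adequate for template selection but not claimed
to reproduce any particular assembly.

## Summary statistics

The variation spectrum uses ten categories: the six unordered base pairs
on the sense strand (`CT`, `GA`, `CG`, `AT`, `CA`, `TG`) plus four
single-base indels. `CT` and `GA` are the transitions. A
complement-collapsed six-kind rollup (`A/- or T/-`, `C/- or G/-`,
transitions, `A>C or T>G`, `A>T`, `C>G`) is emitted alongside, because
both groupings are in circulation; the ten-category table is primary
since its aggregate arithmetic is exact. One variation is counted per
variant column.

Rates and ratios round half-up to two decimals. The linkage-map average
marker interval is `length / loci` (not `loci − 1`); genome and total
rows aggregate lengths and loci first, then recompute — this convention
reproduces standard published map summaries exactly.

## The simulator and what it does (not) emulate

`simulateCluster()` generates: ancestral transcript → two homoeologs
(per-base divergence `dHomoeolog` on the second) → species lineages
(`dSpecies` applied to the second species' copies) → genotype haplotypes
(`dIntra`) → `nPerHaplotype` reads each with per-base `errorRate`.
Substitutions are transitions with probability $\kappa/(\kappa+2)$;
deletions occur at `indelRate` and become gap states *in place*, so
clusters are born aligned on a fixed coordinate frame. This sidesteps
assembly/alignment (out of scope) while preserving exactly the
column-wise statistical structure the classifier consumes.

Every mutation event yields a truth record whose expected by-species
class is derived from provenance and the retained-homoeolog
configuration by rules written independently of the classifier — e.g.
homoeolog divergence visible to a two-homoeolog species and a
one-homoeolog species is `HEMI`; species divergence on a single-homoeolog
background is `INTER`. Columns hit by more than one event are `COMPLEX`
and excluded from recovery scoring.

Defaults: `seqLength` 500 bp, 2 species × 2 homoeologs × 2 genotypes ×
`nPerHaplotype` (8 reads at the default 1, within the 4–20 range typical
of EST clusters); `kappa = 2.523`, chosen so the expected transition
share $\kappa/(\kappa+2)$ equals the ~55.8% observed in cotton EST SNP
spectra; `dHomoeolog = 0.02`, `dSpecies = 0.01`, `dIntra = 0.002` —
plausible magnitudes reflecting that subgenome divergence predates
speciation, which predates cultivar divergence; they are placeholders,
not fitted estimates. `indelRate = 0.003` gives indels roughly the ~10%
share of variation events seen in EST spectra; `errorRate = 0.001` is a
mild single-pass error rate. The simulator does **not** emulate realistic
EST length/quality profiles, chimeras, paralog contamination, or
alignment error — so passing recovery tests demonstrate the correctness
of the classification logic under the model's assumptions, not
performance on raw NCBI ESTs.

## Numerical and degenerate-input choices

* Half-up rounding (`roundHalfUp()`) everywhere a value is reported to 2
  decimals; R's banker's rounding would disagree on exact halves.
* Consensus ties break A < C < G < T; gap-majority requires the gap count
  to strictly exceed the best base count.
* Empty spectrum input yields an all-zero table flagged `empty` with
  percentages reported as 0.
* Monomorphic clusters produce an empty site table, not an error;
  one-species input to interspecific eligibility is a grouping error.
* A species with no reliable allele at a reliable site makes that site
  unclassifiable (`NA`); it is skipped rather than guessed.
* Seeds: every simulation entry point takes an explicit integer seed
  (`SimParams@seed` or a `seed` argument) and fixes the full output
  stream.

## Problem sizes used by the test suite

The shipped tests run the classification-recovery grid at 100 clusters ×
3 regimes × 300 bp with 2 reads per haplotype, the transition-share check
on ~120,000 simulated substitutions (3σ binomial tolerance), and the
primer-constraint sweep on 1,000 random templates of 200–320 bp; the
acceptance script uses 40 clusters per regime and 200 templates. These
sizes give stable statistics at interactive runtimes; all scale linearly
if larger grids are wanted.

## Known limitations

* Site-level `INTER` vs `HEMI` is reconstructed from per-species allele
  sets; cluster types observed in real data mix both, and a hemi call can
  reflect residual homoeologous transcripts rather than allelic variation.
* The homology screen's E-values borrow ungapped Karlin–Altschul
  parameters for gapped scores; they gate strongly (1e-10) so the
  approximation is inconsequential for the filter, but the absolute
  E-values are not BLAST-comparable.
* No secondary-structure, dimer or hairpin screening in primer design.
* Redundancy removal is all-pairs ($O(n^2)$ alignments) — intended for
  the hundreds-of-records scale of UTR candidate sets, not genome-scale
  input.
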