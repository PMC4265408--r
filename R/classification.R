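# The allotetraploid SNP taxonomy. In an allotetraploid, an apparent SNP in
# an EST cluster can be a fixed difference between the A and D subgenomes
# (an inter-homoeologous or "pseudo" SNP, identical in both species and
# useless as a species-distinguishing marker), a true interspecific
# difference (disjoint allele sets between species), or a hemi-SNP (one
# species monomorphic, the other polymorphic with partial overlap).

#' Classify a reliable variant site from per-species allele sets
#'
#' With `s1`, `s2` the *reliable* allele sets observed in the two species at
#' one column:
#' * equal sets with two or more alleles -> `INTER_HOMOEOLOGOUS` (both
#'   species carry the same two base types: a subgenome-fixed difference);
#' * disjoint sets -> `INTER` (the species harbour different base types);
#' * unequal, overlapping sets with exactly one species polymorphic ->
#'   `HEMI`;
#' * anything else -> `UNCLASSIFIED` (defensive; impossible for biallelic
#'   sites).
#'
#' @param s1,s2 character vectors of reliable states (`A/C/G/T/GAP`) for
#'   species 1 and species 2; both must be non-empty.
#' @return One of `"INTER_HOMOEOLOGOUS"`, `"INTER"`, `"HEMI"`,
#'   `"UNCLASSIFIED"`.
#' @examples
#' classifySite(c("C", "T"), c("C", "T"))  # INTER_HOMOEOLOGOUS
#' classifySite("C", "T")                  # INTER
#' classifySite("C", c("C", "T"))          # HEMI
#' @export
classifySite <- function(s1, s2) {
  s1 <- unique(s1); s2 <- unique(s2)
  if (length(s1) == 0L || length(s2) == 0L)
    stop("precondition error: a species has no reliable allele at this column")
  if (setequal(s1, s2) && length(s1) >= 2L) return("INTER_HOMOEOLOGOUS")
  if (length(intersect(s1, s2)) == 0L) return("INTER")
  if (!setequal(s1, s2) && xor(length(s1) > 1L, length(s2) > 1L))
    return("HEMI")
  "UNCLASSIFIED"
}

#' Classify all reliable sites of a cluster by species
#'
#' Convenience wrapper: runs [detectSites()], keeps reliable non-complex
#' sites, intersects each species' observed alleles with the column's
#' reliable alleles and calls [classifySite()]. Sites where one species has
#' no reliable allele (e.g. a species-private polymorphism) are skipped, as
#' are sites where a species is entirely missing: their class is `NA` and
#' they do not enter cluster-level classification.
#'
#' @param cluster an [ESTCluster-class] carrying exactly two species labels.
#' @param minAlleleSupport see [detectSites()].
#' @return Site table (reliable, non-complex sites) with a `site_class`
#'   column.
#' @export
classifySites <- function(cluster, minAlleleSupport = 2L) {
  if (length(unique(cluster@species)) != 2L)
    stop("grouping error: exactly two species labels are required")
  sites <- reliableSites(detectSites(cluster, "by_species", minAlleleSupport))
  sites$site_class <- vapply(seq_len(nrow(sites)), function(i) {
    tly <- tallyColumn(cluster, sites$position[i], "by_species")
    rel <- alleleSet(sites$reliable_alleles[i])
    sets <- lapply(tly$countsByGroup, function(cnt) intersect(names(cnt), rel))
    if (length(sets) < 2L || any(lengths(sets) == 0L)) return(NA_character_)
    classifySite(sets[[1L]], sets[[2L]])
  }, character(1))
  sites
}

#' Roll site classes up to a cluster class
#'
#' Deterministic rollup of a cluster's reliable-site classes: no sites ->
#' `NO_SNP`; any `INTER` -> `INTER_HEMI`; else any `HEMI` -> `HEMI_ONLY`;
#' else -> `HOMOEO_ONLY`. Permutation-invariant; `NA` (unclassifiable) and
#' `UNCLASSIFIED` entries are dropped first.
#'
#' @param siteClasses character vector of site classes.
#' @return One of `"NO_SNP"`, `"HOMOEO_ONLY"`, `"INTER_HEMI"`, `"HEMI_ONLY"`.
#' @examples
#' classifyCluster(character(0))                     # NO_SNP
#' classifyCluster(c("HEMI", "INTER_HOMOEOLOGOUS"))  # HEMI_ONLY
#' classifyCluster(c("HEMI", "INTER"))               # INTER_HEMI
#' @export
classifyCluster <- function(siteClasses) {
  siteClasses <- siteClasses[!is.na(siteClasses) &
                               siteClasses != "UNCLASSIFIED"]
  if (length(siteClasses) == 0L) return("NO_SNP")
  if (any(siteClasses == "INTER")) return("INTER_HEMI")
  if (any(siteClasses == "HEMI")) return("HEMI_ONLY")
  "HOMOEO_ONLY"
}

#' Interspecific marker eligibility of a cluster
#'
#' A cluster qualifies for interspecific marker design when it has at least
#' `minSeqsPerSpecies` sequences from *each* species
#' (`MIN_SEQS_PER_SPECIES`), at least one reliable `INTER` or `HEMI` site
#' (`NO_RELIABLE_SNP`), and its reliable sites are not exclusively
#' inter-homoeologous (`HOMOEO_ONLY` — such clusters carry only
#' subgenome-fixed pseudo-SNPs and are discarded).
#'
#' @param cluster an [ESTCluster-class] with exactly two species labels.
#' @param cfg a [runConfig()].
#' @return A list with `cluster_id`, `eligible`, `reasons` (character vector
#'   of failed rule identifiers; empty iff eligible), `cluster_class`, and
#'   the classified site table as `sites`.
#' @export
checkInterspecificEligibility <- function(cluster, cfg = runConfig()) {
  spTab <- table(cluster@species)
  if (length(spTab) != 2L)
    stop("grouping error: expected exactly two species labels, got ",
         length(spTab))
  reasons <- character(0)
  if (any(spTab < cfg@minSeqsPerSpecies))
    reasons <- c(reasons, "MIN_SEQS_PER_SPECIES")
  sites <- classifySites(cluster, cfg@minAlleleSupport)
  cls <- sites$site_class
  usable <- cls[!is.na(cls) & cls != "UNCLASSIFIED"]
  if (!any(usable %in% c("INTER", "HEMI"))) {
    reasons <- c(reasons,
                 if (length(usable) && all(usable == "INTER_HOMOEOLOGOUS"))
                   "HOMOEO_ONLY" else "NO_RELIABLE_SNP")
  }
  list(cluster_id = cluster@clusterId,
       eligible = length(reasons) == 0L,
       reasons = reasons,
       cluster_class = classifyCluster(cls),
       sites = sites)
}

#' Intraspecific marker eligibility of a unigene
#'
#' A single-species unigene qualifies when it holds at least
#' `minEstsPerUnigene` ESTs (`MIN_ESTS`), its ESTs come from more than one
#' genotype (`SINGLE_GENOTYPE` — a one-genotype unigene cannot show allelic
#' variation), and it carries at least one reliable substitution or indel
#' site (`NO_RELIABLE_SNP` — unigenes with only putative SNPs are removed).
#' Reliable sites of an eligible unigene are allelic variants within the
#' species and are labelled `INTRA`.
#'
#' @param unigene an [ESTCluster-class] (single species, multiple genotypes).
#' @param cfg a [runConfig()].
#' @return A list with `cluster_id`, `eligible`, `reasons`, and the reliable
#'   site table (`sites`, with `site_class = "INTRA"` when eligible).
#' @export
checkIntraspecificEligibility <- function(unigene, cfg = runConfig()) {
  reasons <- character(0)
  if (nSeq(unigene) < cfg@minEstsPerUnigene)
    reasons <- c(reasons, "MIN_ESTS")
  if (length(unique(unigene@genotype)) == 1L)
    reasons <- c(reasons, "SINGLE_GENOTYPE")
  sites <- reliableSites(detectSites(unigene, "by_genotype",
                                     cfg@minAlleleSupport))
  if (nrow(sites) == 0L)
    reasons <- c(reasons, "NO_RELIABLE_SNP")
  eligible <- length(reasons) == 0L
  sites$site_class <- if (nrow(sites)) {
    if (eligible) "INTRA" else NA_character_
  } else character(0)
  list(cluster_id = unigene@clusterId, eligible = eligible,
       reasons = reasons, sites = sites)
}

#' Summarise cluster classes over a collection
#'
#' Counts and percentages (half-up, 2 decimals) of the four cluster classes
#' over a set of clusters — the screening summary of an interspecific mining
#' run.
#'
#' @param clusterClasses character vector of cluster classes.
#' @return data.frame with `class`, `count`, `percent`, in the fixed order
#'   `NO_SNP`, `HOMOEO_ONLY`, `INTER_HEMI`, `HEMI_ONLY`.
#' @export
clusterClassSummary <- function(clusterClasses) {
  bad <- setdiff(unique(clusterClasses), CLUSTER_CLASSES)
  if (length(bad)) stop("unknown cluster class: ", paste(bad, collapse = ", "))
  counts <- table(factor(clusterClasses, levels = CLUSTER_CLASSES))
  data.frame(class = CLUSTER_CLASSES,
             count = as.integer(counts),
             percent = roundHalfUp(100 * as.integer(counts) /
                                     max(1L, length(clusterClasses)), 2),
             stringsAsFactors = FALSE)
}
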