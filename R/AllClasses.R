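#' @import methods
#' @importFrom Biostrings DNAStringSet readBStringSet readDNAMultipleAlignment
#'   pairwiseAlignment nucleotideSubstitutionMatrix nmatch unaligned width
#'   alignedPattern score writeXStringSet
NULL

VALID_STATES <- c("A", "C", "G", "T", "GAP")
SITE_CLASSES <- c("INTER_HOMOEOLOGOUS", "INTER", "HEMI", "INTRA", "UNCLASSIFIED")
CLUSTER_CLASSES <- c("NO_SNP", "HOMOEO_ONLY", "INTER_HEMI", "HEMI_ONLY")

#' ESTCluster: an aligned EST cluster with species/genotype labels
#'
#' The unit of SNP mining: a gapped multiple alignment of EST reads from one
#' putative gene, each read labelled with its species of origin (e.g. `"Gh"`,
#' `"Gb"` for the two cultivated tetraploid cottons) and its genotype
#' (cultivar/accession). Residues are `A/C/G/T`, `-` for alignment gaps and
#' IUPAC ambiguity codes (treated as missing data downstream).
#'
#' @slot clusterId single string identifying the cluster.
#' @slot alignment [Biostrings::DNAStringSet] of equal widths (the alignment);
#'   names are the per-sequence identifiers, unique within the cluster.
#' @slot species character vector, one species label per member.
#' @slot genotype character vector, one genotype label per member.
#'
#' @seealso [readAlignedCluster()], [detectSites()], [simulateCluster()]
#' @export
setClass("ESTCluster",
  representation(
    clusterId = "character",
    alignment = "DNAStringSet",
    species = "character",
    genotype = "character"
  )
)

setValidity("ESTCluster", function(object) {
  msg <- character(0)
  n <- length(object@alignment)
  if (length(object@clusterId) != 1L || !nzchar(object@clusterId))
    msg <- c(msg, "clusterId must be a single non-empty string")
  if (n < 2L)
    msg <- c(msg, "a cluster needs at least 2 member sequences")
  if (n >= 1L && length(unique(width(object@alignment))) != 1L)
    msg <- c(msg, "all members must have identical aligned length")
  if (length(object@species) != n || length(object@genotype) != n)
    msg <- c(msg, "species and genotype labels must match the number of members")
  if (any(!nzchar(object@species)) || any(is.na(object@species)))
    msg <- c(msg, "species labels must be non-empty")
  if (any(!nzchar(object@genotype)) || any(is.na(object@genotype)))
    msg <- c(msg, "genotype labels must be non-empty")
  ids <- names(object@alignment)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    msg <- c(msg, "sequence ids must be present and unique within the cluster")
  if (length(msg)) msg else TRUE
})

#' Construct an ESTCluster
#'
#' @param clusterId single string.
#' @param alignment a [Biostrings::DNAStringSet] (or named character vector of
#'   aligned sequences, all the same length; `U` is mapped to `T` and residues
#'   are upper-cased).
#' @param species,genotype character vectors parallel to `alignment`.
#' @return An [ESTCluster-class] object.
#' @examples
#' cl <- ESTCluster("c1",
#'   c(s1 = "ACGT", s2 = "ACGT", s3 = "ACTT", s4 = "ACTT"),
#'   species  = c("Gh", "Gh", "Gb", "Gb"),
#'   genotype = c("g1", "g2", "g3", "g4"))
#' alignmentWidth(cl)
#' @export
ESTCluster <- function(clusterId, alignment, species, genotype) {
  if (is.character(alignment)) {
    alignment <- Biostrings::DNAStringSet(chartr("uU", "tT", toupper(alignment)))
  }
  new("ESTCluster", clusterId = as.character(clusterId), alignment = alignment,
      species = as.character(species), genotype = as.character(genotype))
}

#' Run configuration for the marker-development pipeline
#'
#' Bundles every tunable threshold with defaults reproducing the published
#' pipeline settings: alleles must be confirmed by two reads to count as
#' reliable, interspecific clusters need two or more sequences from each
#' species, intraspecific unigenes need at least four ESTs, mined 3'UTRs must
#' be strictly longer than 100 bp, and cross-species homology hits must align
#' over at least 100 bp at an E-value of 1e-10 or better.
#'
#' @slot minAlleleSupport integer, reads required to call an allele reliable.
#' @slot minSeqsPerSpecies integer, per-species floor for interspecific clusters.
#' @slot minEstsPerUnigene integer, EST floor for intraspecific unigenes.
#' @slot primerPreset `"snp"` or `"indel"` (see [primerPreset()]).
#' @slot utrMinLength integer, 3'UTRs must exceed this length (strict).
#' @slot homologyEvalueMax numeric, E-value ceiling for homology hits.
#' @slot homologyMinLength integer, minimum aligned length for homology hits.
#' @slot redundancyIdentity numeric percent, single-linkage identity threshold
#'   for redundancy removal.
#' @slot seed integer RNG seed.
#' @export
setClass("RunConfig",
  representation(
    minAlleleSupport = "integer",
    minSeqsPerSpecies = "integer",
    minEstsPerUnigene = "integer",
    primerPreset = "character",
    utrMinLength = "integer",
    homologyEvalueMax = "numeric",
    homologyMinLength = "integer",
    redundancyIdentity = "numeric",
    seed = "integer"
  )
)

setValidity("RunConfig", function(object) {
  msg <- character(0)
  pos <- c(minAlleleSupport = object@minAlleleSupport,
           minSeqsPerSpecies = object@minSeqsPerSpecies,
           minEstsPerUnigene = object@minEstsPerUnigene,
           utrMinLength = object@utrMinLength,
           homologyMinLength = object@homologyMinLength)
  bad <- names(pos)[pos < 1L | is.na(pos)]
  if (length(bad))
    msg <- c(msg, paste0("thresholds must be positive: ", paste(bad, collapse = ", ")))
  if (object@homologyEvalueMax <= 0)
    msg <- c(msg, "homologyEvalueMax must be positive")
  if (object@redundancyIdentity <= 0 || object@redundancyIdentity > 100)
    msg <- c(msg, "redundancyIdentity must be in (0, 100]")
  if (!object@primerPreset %in% c("snp", "indel"))
    msg <- c(msg, "primerPreset must be 'snp' or 'indel'")
  if (length(msg)) msg else TRUE
})

#' @rdname RunConfig-class
#' @param minAlleleSupport,minSeqsPerSpecies,minEstsPerUnigene,primerPreset,utrMinLength,homologyEvalueMax,homologyMinLength,redundancyIdentity,seed
#'   see slot documentation; defaults are the published settings.
#' @return A `RunConfig` object.
#' @examples
#' cfg <- runConfig()
#' cfg@minSeqsPerSpecies
#' @export
runConfig <- function(minAlleleSupport = 2L, minSeqsPerSpecies = 2L,
                      minEstsPerUnigene = 4L, primerPreset = "snp",
                      utrMinLength = 100L, homologyEvalueMax = 1e-10,
                      homologyMinLength = 100L, redundancyIdentity = 95,
                      seed = 1L) {
  new("RunConfig",
      minAlleleSupport = as.integer(minAlleleSupport),
      minSeqsPerSpecies = as.integer(minSeqsPerSpecies),
      minEstsPerUnigene = as.integer(minEstsPerUnigene),
      primerPreset = primerPreset,
      utrMinLength = as.integer(utrMinLength),
      homologyEvalueMax = as.numeric(homologyEvalueMax),
      homologyMinLength = as.integer(homologyMinLength),
      redundancyIdentity = as.numeric(redundancyIdentity),
      seed = as.integer(seed))
}

#' Read a RunConfig from a YAML file
#'
#' Keys mirror the [runConfig()] arguments (snake_case also accepted, e.g.
#' `min_allele_support`); absent keys keep their defaults.
#'
#' @param path path to a YAML file.
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  camel <- function(x) gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
  names(raw) <- camel(names(raw))
  known <- names(formals(runConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(runConfig, raw)
}

#' Simulation parameters for the allotetraploid EST cluster generator
#'
#' Describes the generative model behind [simulateCluster()]: an ancestral
#' transcript splits into two homoeologous copies (A/D subgenomes, per-base
#' divergence `dHomoeolog`), each homoeolog splits into two species lineages
#' (divergence `dSpecies`, applied to the second species), each species copy
#' is replicated per genotype (divergence `dIntra`), and each genotype
#' haplotype yields `nPerHaplotype` reads with per-base error `errorRate`.
#' Substitutions follow a transition bias `kappa` (transition chosen with
#' probability `kappa/(kappa + 2)`); single-base deletions occur at
#' `indelRate` and appear as gap characters, so clusters are born aligned.
#'
#' @slot nPerHaplotype integer, reads per (species x homoeolog x genotype).
#' @slot seqLength integer, transcript length in bp.
#' @slot dHomoeolog,dSpecies,dIntra numeric per-base divergence rates in `[0,1)`.
#' @slot kappa numeric > 0, transition/transversion rate ratio.
#' @slot indelRate,errorRate numeric per-base rates in `[0,1)`.
#' @slot species character vector of two species labels.
#' @slot homoeologs named list: homoeolog labels retained per species.
#' @slot genotypes named list: genotype labels per species.
#' @slot seed integer RNG seed; fixes the full output stream.
#' @export
setClass("SimParams",
  representation(
    nPerHaplotype = "integer",
    seqLength = "integer",
    dHomoeolog = "numeric",
    dSpecies = "numeric",
    dIntra = "numeric",
    kappa = "numeric",
    indelRate = "numeric",
    errorRate = "numeric",
    species = "character",
    homoeologs = "list",
    genotypes = "list",
    seed = "integer"
  )
)

setValidity("SimParams", function(object) {
  msg <- character(0)
  rates <- c(dHomoeolog = object@dHomoeolog, dSpecies = object@dSpecies,
             dIntra = object@dIntra, indelRate = object@indelRate,
             errorRate = object@errorRate)
  if (any(rates < 0 | rates >= 1))
    msg <- c(msg, "all rates must lie in [0, 1)")
  if (object@kappa <= 0) msg <- c(msg, "kappa must be positive")
  if (object@nPerHaplotype < 1L) msg <- c(msg, "nPerHaplotype must be >= 1")
  if (object@seqLength < 1L) msg <- c(msg, "seqLength must be >= 1")
  if (length(object@species) != 2L || anyDuplicated(object@species))
    msg <- c(msg, "exactly two distinct species labels are required")
  if (!all(object@species %in% names(object@homoeologs)) ||
      !all(object@species %in% names(object@genotypes)))
    msg <- c(msg, "homoeologs and genotypes must be named by species")
  if (any(!vapply(object@homoeologs, length, 1L)) ||
      any(!vapply(object@genotypes, length, 1L)))
    msg <- c(msg, "each species needs at least one homoeolog and one genotype")
  if (length(msg)) msg else TRUE
})

#' @rdname SimParams-class
#' @param nPerHaplotype,seqLength,dHomoeolog,dSpecies,dIntra,kappa,indelRate,errorRate,species,homoeologs,genotypes,seed
#'   see slot documentation.
#' @return A `SimParams` object.
#' @examples
#' p <- simParams(seed = 7)
#' p@kappa
#' @export
simParams <- function(nPerHaplotype = 1L, seqLength = 500L,
                      dHomoeolog = 0.02, dSpecies = 0.01, dIntra = 0.002,
                      kappa = 2.523, indelRate = 0.003, errorRate = 0.001,
                      species = c("Gh", "Gb"),
                      homoeologs = list(Gh = c("A", "D"), Gb = c("A", "D")),
                      genotypes = list(Gh = c("Gh_g1", "Gh_g2"),
                                       Gb = c("Gb_g1", "Gb_g2")),
                      seed = 1L) {
  new("SimParams",
      nPerHaplotype = as.integer(nPerHaplotype), seqLength = as.integer(seqLength),
      dHomoeolog = dHomoeolog, dSpecies = dSpecies, dIntra = dIntra,
      kappa = kappa, indelRate = indelRate, errorRate = errorRate,
      species = species, homoeologs = homoeologs, genotypes = genotypes,
      seed = as.integer(seed))
}
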