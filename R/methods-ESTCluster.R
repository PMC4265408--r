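#' @describeIn ESTCluster-class number of member sequences
#' @param x,object an `ESTCluster`
#' @export
setGeneric("nSeq", function(x) standardGeneric("nSeq"))

#' @rdname ESTCluster-class
#' @export
setMethod("nSeq", "ESTCluster", function(x) length(x@alignment))

#' @describeIn ESTCluster-class alignment length (columns)
#' @export
setGeneric("alignmentWidth", function(x) standardGeneric("alignmentWidth"))

#' @rdname ESTCluster-class
#' @export
setMethod("alignmentWidth", "ESTCluster",
          function(x) unique(Biostrings::width(x@alignment)))

#' @describeIn ESTCluster-class cluster identifier
#' @export
setGeneric("clusterId", function(x) standardGeneric("clusterId"))

#' @rdname ESTCluster-class
#' @export
setMethod("clusterId", "ESTCluster", function(x) x@clusterId)

#' @describeIn ESTCluster-class per-member species labels (named by sequence id)
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))

#' @rdname ESTCluster-class
#' @export
setMethod("speciesLabels", "ESTCluster",
          function(x) stats::setNames(x@species, names(x@alignment)))

#' @describeIn ESTCluster-class per-member genotype labels (named by sequence id)
#' @export
setGeneric("genotypeLabels", function(x) standardGeneric("genotypeLabels"))

#' @rdname ESTCluster-class
#' @export
setMethod("genotypeLabels", "ESTCluster",
          function(x) stats::setNames(x@genotype, names(x@alignment)))

#' @describeIn ESTCluster-class the gapped alignment as a `DNAStringSet`
#' @export
setGeneric("clusterAlignment", function(x) standardGeneric("clusterAlignment"))

#' @rdname ESTCluster-class
#' @export
setMethod("clusterAlignment", "ESTCluster", function(x) x@alignment)

setMethod("show", "ESTCluster", function(object) {
  sp <- table(object@species)
  cat("ESTCluster '", object@clusterId, "': ", nSeq(object),
      " sequences x ", alignmentWidth(object), " columns\n", sep = "")
  cat("  species: ",
      paste(sprintf("%s (%d)", names(sp), as.integer(sp)), collapse = ", "),
      "\n  genotypes: ", length(unique(object@genotype)), " distinct\n", sep = "")
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig: minAlleleSupport=", object@minAlleleSupport,
      ", minSeqsPerSpecies=", object@minSeqsPerSpecies,
      ", minEstsPerUnigene=", object@minEstsPerUnigene,
      ", primerPreset='", object@primerPreset,
      "', utrMinLength=", object@utrMinLength,
      ", homology E<=", format(object@homologyEvalueMax),
      " len>=", object@homologyMinLength,
      ", redundancyIdentity=", object@redundancyIdentity,
      "%, seed=", object@seed, "\n", sep = "")
})

setMethod("show", "SimParams", function(object) {
  nh <- vapply(object@species, function(s)
    length(object@homoeologs[[s]]) * length(object@genotypes[[s]]), 1L)
  cat("SimParams: ", sum(nh) * object@nPerHaplotype, " reads (",
      paste(sprintf("%s: %d", object@species, nh * object@nPerHaplotype),
            collapse = ", "),
      "), L=", object@seqLength, "\n", sep = "")
  cat("  divergence homoeolog/species/intra = ", object@dHomoeolog, "/",
      object@dSpecies, "/", object@dIntra,
      "; kappa=", object@kappa, "; indel=", object@indelRate,
      "; error=", object@errorRate, "; seed=", object@seed, "\n", sep = "")
})

# Character matrix view of an alignment; the workhorse for column scans.
alignmentMatrix <- function(cluster) {
  m <- matrix(unlist(strsplit(as.character(cluster@alignment), "",
                              fixed = TRUE), use.names = FALSE),
              nrow = nSeq(cluster), ncol = alignmentWidth(cluster),
              byrow = TRUE)
  rownames(m) <- names(cluster@alignment)
  m
}
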