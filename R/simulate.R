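# Ground-truth simulator for allotetraploid EST clusters. Mutations are
# applied on a fixed coordinate frame (substitutions in place, single-base
# deletions as gap states), so clusters are born aligned and every column
# keeps its ancestral coordinate — the column-wise statistical structure the
# classifier consumes, without an assembler.

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

#' Evolve a sequence under a transition-biased substitution/deletion model
#'
#' Each non-gap base independently becomes a single-base deletion (gap) with
#' probability `indelRate`, else a substitution with probability `rate`.
#' Substitutions are transitions with probability `kappa / (kappa + 2)` and
#' each of the two transversions with probability `1 / (kappa + 2)`, i.e.
#' transition : single-transversion odds of `kappa : 1`. Uses the current
#' RNG state; callers seed it.
#'
#' @param seq sequence string over `A/C/G/T/-` (gaps are never re-mutated).
#' @param rate per-base substitution probability in `[0, 1)`.
#' @param kappa transition/transversion rate ratio (> 0).
#' @param indelRate per-base deletion probability; `rate + indelRate` must
#'   not exceed 1.
#' @return A list: `seq` (mutated string) and `events` (data.frame
#'   `position`, `type` (`substitution`/`deletion`), `from`, `to`).
#' @examples
#' set.seed(1)
#' evolveSequence("ACGTACGT", rate = 0)$events  # identity: zero rows
#' @export
evolveSequence <- function(seq, rate, kappa = 2.523, indelRate = 0) {
  stopifnot(rate >= 0, rate < 1, indelRate >= 0, indelRate < 1, kappa > 0,
            rate + indelRate <= 1)
  chars <- strsplit(seq, "")[[1]]
  mutable <- which(chars %in% c("A", "C", "G", "T"))
  u <- stats::runif(length(mutable))
  del <- mutable[u < indelRate]
  sub <- mutable[u >= indelRate & u < indelRate + rate]
  events <- list()
  if (length(del)) {
    events[[1L]] <- data.frame(position = del, type = "deletion",
                               from = chars[del], to = "-",
                               stringsAsFactors = FALSE)
    chars[del] <- "-"
  }
  if (length(sub)) {
    isTs <- stats::runif(length(sub)) < kappa / (kappa + 2)
    pickTv <- 1L + (stats::runif(length(sub)) < 0.5)
    to <- character(length(sub))
    from <- chars[sub]
    to[isTs] <- TRANSITION_OF[from[isTs]]
    if (any(!isTs))
      to[!isTs] <- vapply(which(!isTs), function(k)
        TRANSVERSIONS_OF[[from[k]]][pickTv[k]], "")
    events[[length(events) + 1L]] <- data.frame(
      position = sub, type = "substitution", from = from, to = to,
      stringsAsFactors = FALSE)
    chars[sub] <- to
  }
  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(position = integer(0), type = character(0),
                        from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
  ev <- ev[order(ev$position), , drop = FALSE]
  rownames(ev) <- NULL
  list(seq = paste(chars, collapse = ""), events = ev)
}

randomSequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Expected by-species site class of a single event, derived from its
# provenance and the retained-homoeolog/genotype configuration — written
# independently of classifySite so recovery tests are a genuine dual route.
# Returns NA_character_ for events invisible in the by-species view.
truthClassOf <- function(event, params) {
  homs <- params@homoeologs
  sp <- params@species
  if (event$origin == "homoeolog_divergence") {
    hasMut <- vapply(sp, function(s) event$homoeolog %in% homs[[s]], TRUE)
    hasAnc <- vapply(sp, function(s)
      length(setdiff(homs[[s]], event$homoeolog)) > 0, TRUE)
    sizes <- hasMut + hasAnc
    if (all(sizes == 2L)) return("INTER_HOMOEOLOGOUS")
    if (any(sizes == 2L)) return("HEMI")
    # both species carry one homoeolog each
    if (hasMut[1L] == hasMut[2L]) return(NA_character_)  # invisible
    return("INTER")
  }
  if (event$origin == "species_divergence") {
    # applied to every copy of one homoeolog in the second species
    if (length(homs[[sp[2L]]]) >= 2L) return("HEMI")
    return("INTER")
  }
  if (event$origin == "intra_divergence") {
    s <- event$species
    ancPresent <- length(params@genotypes[[s]]) > 1L || length(homs[[s]]) > 1L
    if (ancPresent) return("HEMI")
    return("INTER")
  }
  NA_character_
}

#' Simulate an allotetraploid EST cluster with ground truth
#'
#' Generative model (see [simParams()]): ancestral transcript -> two
#' homoeologs (`dHomoeolog` on the second) -> species lineages (`dSpecies`
#' on the second species' copies) -> genotype haplotypes (`dIntra`) ->
#' `nPerHaplotype` reads each with per-base `errorRate` substitutions.
#' Every mutation event yields one truth record; its expected by-species
#' site class is derived from the event's provenance and which homoeologs
#' each species retains (e.g. homoeolog divergence seen by both species in
#' both subgenomes is `INTER_HOMOEOLOGOUS`; species divergence on a species
#' retaining both homoeologs is `HEMI`, on single-homoeolog species
#' `INTER`). Columns hit by more than one non-error event are flagged
#' `COMPLEX` and excluded from recovery scoring; sequencing-error events
#' carry no class.
#'
#' @param params a [simParams()]; its seed fixes the full output stream.
#' @param clusterId identifier for the generated cluster.
#' @return A list: `cluster` (an [ESTCluster-class]) and `truth`
#'   (data.frame `cluster_id`, `position`, `kind`, `true_class`, `event`).
#' @examples
#' sim <- simulateCluster(simParams(seed = 42))
#' sim$cluster
#' head(sim$truth)
#' @export
simulateCluster <- function(params, clusterId = "sim") {
  validObject(params)
  set.seed(params@seed)
  sp <- params@species
  homLabels <- unique(unlist(params@homoeologs))
  anc <- randomSequence(params@seqLength)

  events <- list()
  addEvents <- function(ev, origin, species = NA, homoeolog = NA,
                        genotype = NA) {
    if (nrow(ev) == 0L) return(invisible())
    ev$origin <- origin; ev$species <- species
    ev$homoeolog <- homoeolog; ev$genotype <- genotype
    events[[length(events) + 1L]] <<- ev
  }

  # homoeolog split: first label keeps the ancestral state
  homSeq <- list()
  homSeq[[homLabels[1L]]] <- anc
  for (h in homLabels[-1L]) {
    m <- evolveSequence(anc, params@dHomoeolog, params@kappa, params@indelRate)
    homSeq[[h]] <- m$seq
    addEvents(m$events, "homoeolog_divergence", homoeolog = h)
  }

  # species split: divergence applied to the second species' lineage
  spSeq <- list()
  for (s in sp) {
    spSeq[[s]] <- list()
    for (h in params@homoeologs[[s]]) {
      if (s == sp[2L] && params@dSpecies > 0) {
        m <- evolveSequence(homSeq[[h]], params@dSpecies, params@kappa,
                            params@indelRate)
        spSeq[[s]][[h]] <- m$seq
        addEvents(m$events, "species_divergence", species = s, homoeolog = h)
      } else {
        spSeq[[s]][[h]] <- homSeq[[h]]
      }
    }
  }

  # genotype haplotypes, then reads
  reads <- character(0); readSp <- character(0); readGt <- character(0)
  for (s in sp) {
    for (h in params@homoeologs[[s]]) {
      for (g in params@genotypes[[s]]) {
        if (params@dIntra > 0) {
          m <- evolveSequence(spSeq[[s]][[h]], params@dIntra, params@kappa,
                              params@indelRate)
          hap <- m$seq
          addEvents(m$events, "intra_divergence", species = s,
                    homoeolog = h, genotype = g)
        } else hap <- spSeq[[s]][[h]]
        for (i in seq_len(params@nPerHaplotype)) {
          if (params@errorRate > 0) {
            m <- evolveSequence(hap, params@errorRate, params@kappa, 0)
            rd <- m$seq
            addEvents(m$events, "error", species = s, homoeolog = h,
                      genotype = g)
          } else rd <- hap
          reads <- c(reads, rd)
          readSp <- c(readSp, s)
          readGt <- c(readGt, g)
          names(reads)[length(reads)] <- sprintf("%s_%s_r%d", g, h, i)
        }
      }
    }
  }
  cluster <- ESTCluster(clusterId, reads, readSp, readGt)

  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(position = integer(0), type = character(0),
                        from = character(0), to = character(0),
                        origin = character(0), species = character(0),
                        homoeolog = character(0), genotype = character(0),
                        stringsAsFactors = FALSE)
  truth <- if (nrow(ev)) {
    nonError <- ev$origin != "error"
    multi <- table(ev$position[nonError])
    complexCols <- as.integer(names(multi)[multi > 1L])
    rows <- lapply(seq_len(nrow(ev)), function(i) {
      e <- ev[i, ]
      cls <- if (e$origin == "error") NA_character_
             else if (e$position %in% complexCols) "COMPLEX"
             else truthClassOf(e, params)
      data.frame(cluster_id = clusterId, position = e$position,
                 kind = if (e$type == "deletion") "indel" else "substitution",
                 true_class = cls, event = e$origin,
                 stringsAsFactors = FALSE)
    })
    t0 <- do.call(rbind, rows)
    t0 <- t0[order(t0$position, t0$event), , drop = FALSE]
    rownames(t0) <- NULL
    t0
  } else data.frame(cluster_id = character(0), position = integer(0),
                    kind = character(0), true_class = character(0),
                    event = character(0), stringsAsFactors = FALSE)
  list(cluster = cluster, truth = truth)
}

#' Simulate a single-species unigene with intraspecific variation
#'
#' Convenience wrapper for the intraspecific mining route: reads from one
#' species, one homoeolog, several genotypes diverged at `dIntra`. Truth
#' classes are `INTRA` (allelic variation within the species).
#'
#' @param params a [simParams()]; only the first species, its first
#'   homoeolog, its genotypes, `dIntra`, `errorRate`, `kappa`, `indelRate`,
#'   `seqLength`, `nPerHaplotype` and `seed` are used.
#' @param clusterId identifier.
#' @return As [simulateCluster()]: `cluster` and `truth`.
#' @export
simulateUnigene <- function(params, clusterId = "unigene") {
  validObject(params)
  set.seed(params@seed)
  s <- params@species[1L]
  gts <- params@genotypes[[s]]
  anc <- randomSequence(params@seqLength)
  events <- list()
  reads <- character(0); readGt <- character(0)
  for (g in gts) {
    if (params@dIntra > 0) {
      m <- evolveSequence(anc, params@dIntra, params@kappa, params@indelRate)
      hap <- m$seq
      if (nrow(m$events)) {
        m$events$genotype <- g
        events[[length(events) + 1L]] <- m$events
      }
    } else hap <- anc
    for (i in seq_len(params@nPerHaplotype)) {
      rd <- if (params@errorRate > 0)
        evolveSequence(hap, params@errorRate, params@kappa, 0)$seq else hap
      reads <- c(reads, rd)
      readGt <- c(readGt, g)
      names(reads)[length(reads)] <- sprintf("%s_r%d", g, i)
    }
  }
  cluster <- ESTCluster(clusterId, reads, rep(s, length(reads)), readGt)
  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(position = integer(0), type = character(0),
                        genotype = character(0), stringsAsFactors = FALSE)
  truth <- if (nrow(ev)) {
    multi <- table(ev$position)
    data.frame(cluster_id = clusterId, position = ev$position,
               kind = ifelse(ev$type == "deletion", "indel", "substitution"),
               true_class = ifelse(ev$position %in%
                                     as.integer(names(multi)[multi > 1L]),
                                   "COMPLEX", "INTRA"),
               event = "intra_divergence", stringsAsFactors = FALSE)
  } else data.frame(cluster_id = character(0), position = integer(0),
                    kind = character(0), true_class = character(0),
                    event = character(0), stringsAsFactors = FALSE)
  truth <- truth[order(truth$position), , drop = FALSE]
  rownames(truth) <- NULL
  list(cluster = cluster, truth = truth)
}

#' Simulate an annotated mRNA set for 3'UTR mining
#'
#' Generates mRNAs as 5'UTR + complete CDS (length a multiple of 3) + 3'UTR
#' with lengths drawn from `utrLengths` (by default straddling the 100-bp
#' acceptance threshold), plus a controllable fraction of near-duplicate
#' records (about 1% substitutions) to exercise redundancy removal.
#'
#' @param n number of distinct records.
#' @param utrLengths integer vector of candidate 3'UTR lengths.
#' @param cdsCodons integer vector of candidate CDS lengths in codons.
#' @param utr5Lengths integer vector of candidate 5'UTR lengths.
#' @param dupFraction fraction of records that are near-duplicates of
#'   another record (default 0).
#' @param seed RNG seed.
#' @return A list: `sequences` (named character vector) and `annotations`
#'   (data.frame `seq_id`, `cds_start`, `cds_end`, `complete`).
#' @examples
#' sim <- simulateMrnaSet(5, seed = 3)
#' sim$annotations
#' @export
simulateMrnaSet <- function(n, utrLengths = 60:160, cdsCodons = 100:300,
                            utr5Lengths = 20:50, dupFraction = 0, seed = 1L) {
  stopifnot(n >= 1, dupFraction >= 0, dupFraction < 1)
  set.seed(seed)
  pick <- function(v) v[sample.int(length(v), 1L)]
  nDup <- floor(n * dupFraction)
  nBase <- n - nDup
  seqs <- character(0)
  ann <- list()
  for (i in seq_len(nBase)) {
    id <- sprintf("m%03d", i)
    u5 <- pick(utr5Lengths)
    cds <- 3L * pick(cdsCodons)
    u3 <- pick(utrLengths)
    seqs[id] <- randomSequence(u5 + cds + u3)
    ann[[id]] <- data.frame(seq_id = id, cds_start = u5 + 1L,
                            cds_end = u5 + cds, complete = TRUE,
                            stringsAsFactors = FALSE)
  }
  for (k in seq_len(nDup)) {
    src <- pick(names(seqs)[seq_len(nBase)])
    id <- sprintf("m%03d_dup", nBase + k)
    seqs[id] <- evolveSequence(seqs[[src]], 0.01)$seq
    a <- ann[[src]]
    a$seq_id <- id
    ann[[id]] <- a
  }
  list(sequences = seqs, annotations = do.call(rbind, c(ann,
         list(make.row.names = FALSE))))
}
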