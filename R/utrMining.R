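# 3'UTR InDel marker template mining. Route 1 extracts 3'UTRs from mRNAs
# with annotated complete CDSs; route 2 screens sequences against a
# reference 3'UTR set (cross-species homology) by Smith-Waterman local
# alignment gated on aligned length and a Karlin-Altschul E-value.

#' Extract the 3'UTR from an mRNA given its CDS annotation
#'
#' The 3'UTR is the suffix from `cds_end + 1` to the sequence end. Records
#' are rejected (`NO_UTR`) when the CDS runs to the sequence end, rejected
#' (`UTR_TOO_SHORT`) when the UTR is not *strictly* longer than
#' `utrMinLength`, and rejected (`INCOMPLETE_CDS`) when the annotation is
#' not flagged complete.
#'
#' @param mrna mRNA sequence (string).
#' @param ann one-row data.frame (or list) with `seq_id`, `cds_start`,
#'   `cds_end`, `complete`.
#' @param utrMinLength strict lower bound on UTR length (default 100).
#' @return A list: `accepted` (logical), `reason` (`NA` if accepted), and on
#'   acceptance `seq_id`, `utr_sequence`, `utr_start` (= `cds_end + 1`,
#'   1-based in the parent mRNA), `source_route = "complete_cds"`.
#' @examples
#' ann <- list(seq_id = "m1", cds_start = 10, cds_end = 309, complete = TRUE)
#' mrna <- paste(rep("ACGT", 105), collapse = "")  # 420 nt
#' extractUtr3(mrna, ann)$accepted  # UTR length 111 > 100
#' @export
extractUtr3 <- function(mrna, ann, utrMinLength = 100L) {
  reject <- function(reason) list(accepted = FALSE, reason = reason,
                                  seq_id = ann$seq_id)
  if (!isTRUE(as.logical(ann$complete))) return(reject("INCOMPLETE_CDS"))
  L <- nchar(mrna)
  if (ann$cds_end >= L) return(reject("NO_UTR"))
  utr <- substring(mrna, ann$cds_end + 1L, L)
  if (nchar(utr) <= utrMinLength) return(reject("UTR_TOO_SHORT"))
  list(accepted = TRUE, reason = NA_character_, seq_id = ann$seq_id,
       utr_sequence = utr, utr_start = as.integer(ann$cds_end + 1L),
       source_route = "complete_cds")
}

# Global pairwise identity over the shorter sequence, percent.
pairIdentityPct <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 1)
  100 * Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Remove redundant (near-duplicate) 3'UTR records
#'
#' Single-linkage clusters of records whose pairwise global identity —
#' matches divided by the *shorter* sequence length — meets
#' `identityThreshold`; the longest member of each cluster survives (ties:
#' lexicographically smallest `seq_id`). Idempotent and deterministic.
#'
#' @param records data.frame with columns `seq_id` and `utr_sequence` (e.g.
#'   stacked accepted results of [extractUtr3()]).
#' @param identityThreshold percent identity linking two records (default 95).
#' @return The surviving rows, ordered by `seq_id`.
#' @export
removeRedundancy <- function(records, identityThreshold = 95) {
  n <- nrow(records)
  if (n <= 1L) return(records)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (pairIdentityPct(records$utr_sequence[i],
                          records$utr_sequence[j]) >= identityThreshold) {
        from <- c(from, i); to <- c(to, j)
      }
    }
  }
  comp <- singleLinkage(n, from, to)
  keep <- vapply(split(seq_len(n), comp), function(idx) {
    lens <- nchar(records$utr_sequence[idx])
    best <- idx[lens == max(lens)]
    best[order(records$seq_id[best])][1L]
  }, 1L)
  out <- records[sort(keep), , drop = FALSE]
  out <- out[order(out$seq_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Karlin-Altschul parameters for ungapped +1/-2 nucleotide scoring; the
# gapped alignment is scored with these as a documented approximation.
KA_LAMBDA <- 1.33
KA_K <- 0.621

#' Screen query sequences against a reference 3'UTR set by local alignment
#'
#' Smith-Waterman local alignment (match +1, mismatch -2, gap open -5, gap
#' extend -2) of every query against every reference; the best local hit per
#' query-reference pair is kept when its aligned length (including gaps)
#' reaches `cfg@homologyMinLength` *and* its Karlin-Altschul expectation
#' `E = K * m * n * exp(-lambda * S)` (ungapped parameters for +1/-2
#' scoring: lambda = 1.33, K = 0.621; `m`, `n` the query and reference
#' lengths) is at most `cfg@homologyEvalueMax`.
#'
#' @param queries,references named character vectors of DNA sequences.
#' @param cfg a [runConfig()]; the published gates are length >= 100 bp and
#'   E <= 1e-10.
#' @return data.frame of retained hits: `query_id`, `reference_id`,
#'   `aligned_length`, `identity` (percent of aligned length), `score`,
#'   `e_value`; ordered by `query_id`, `reference_id`. Empty for an empty
#'   reference set.
#' @export
homologyScreen <- function(queries, references, cfg = runConfig()) {
  empty <- data.frame(query_id = character(0), reference_id = character(0),
                      aligned_length = integer(0), identity = numeric(0),
                      score = numeric(0), e_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(queries) == 0L || length(references) == 0L) return(empty)
  subMat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -2, baseOnly = FALSE)
  rows <- list()
  for (q in names(queries)) {
    for (r in names(references)) {
      aln <- Biostrings::pairwiseAlignment(
        queries[[q]], references[[r]], type = "local",
        substitutionMatrix = subMat, gapOpening = 5, gapExtension = 2)
      alnLen <- nchar(as.character(Biostrings::alignedPattern(aln)))
      S <- Biostrings::score(aln)
      ev <- KA_K * nchar(queries[[q]]) * nchar(references[[r]]) *
        exp(-KA_LAMBDA * S)
      if (alnLen >= cfg@homologyMinLength && ev <= cfg@homologyEvalueMax) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = q, reference_id = r, aligned_length = alnLen,
          identity = 100 * Biostrings::nmatch(aln) / alnLen,
          score = S, e_value = ev, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(rows, list(empty)))
  out <- out[order(out$query_id, out$reference_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group homologous query sequences into contigs and singlets
#'
#' Single-linkage grouping of sequences sharing a local-alignment overlap of
#' at least `overlapMin` bp at `overlapIdentity` percent identity or better.
#' Groups of two or more are contigs (represented for primer design by their
#' longest member, ties by smallest id); groups of one are singlets. The
#' output is a partition: every query lands in exactly one group.
#'
#' @param queries named character vector of DNA sequences.
#' @param overlapMin minimum overlap length in bp (default 40).
#' @param overlapIdentity minimum percent identity of the overlap (default 95).
#' @return A list: `membership` (named integer vector of group ids),
#'   `contigs` (list of id vectors, size >= 2), `singlets` (character vector
#'   of ids), `representatives` (named character vector: one representative
#'   sequence id per contig).
#' @export
groupIntoContigs <- function(queries, overlapMin = 40L, overlapIdentity = 95) {
  n <- length(queries)
  if (n == 0L)
    return(list(membership = integer(0), contigs = list(),
                singlets = character(0), representatives = character(0)))
  subMat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -2, baseOnly = FALSE)
  from <- integer(0); to <- integer(0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        aln <- Biostrings::pairwiseAlignment(
          queries[[i]], queries[[j]], type = "local",
          substitutionMatrix = subMat, gapOpening = 5, gapExtension = 2)
        alnLen <- nchar(as.character(Biostrings::alignedPattern(aln)))
        if (alnLen >= overlapMin &&
            100 * Biostrings::nmatch(aln) / alnLen >= overlapIdentity) {
          from <- c(from, i); to <- c(to, j)
        }
      }
    }
  }
  comp <- singleLinkage(n, from, to)
  ids <- names(queries)
  membership <- stats::setNames(match(comp, sort(unique(comp))), ids)
  groups <- split(ids, membership)
  sizes <- lengths(groups)
  contigs <- unname(groups[sizes >= 2L])
  reps <- vapply(contigs, function(g) {
    lens <- nchar(queries[g])
    cand <- g[lens == max(lens)]
    sort(cand)[1L]
  }, "")
  names(reps) <- vapply(contigs, `[[`, "", 1L)
  list(membership = membership, contigs = contigs,
       singlets = as.character(unlist(groups[sizes == 1L], use.names = FALSE)),
       representatives = reps)
}
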