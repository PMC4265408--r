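# Column-wise allele tallying and variant site detection on aligned clusters.
#
# Conventions: residues A/C/G/T are alleles, "-" is the GAP state (a
# single-base indel allele), and N or any other IUPAC ambiguity code is
# missing data — it never contributes support and never blocks a site.

# Map aligned residues to tally states; NA = missing.
residueState <- function(res) {
  s <- ifelse(res %in% c("A", "C", "G", "T"), res,
              ifelse(res == "-", "GAP", NA_character_))
  s
}

#' Tally alleles in one alignment column, grouped by species or genotype
#'
#' Every cluster member contributes exactly one count: an allele (`A`, `C`,
#' `G`, `T`), the `GAP` state, or missing (ambiguity codes).
#'
#' @param cluster an [ESTCluster-class].
#' @param column 1-based column index.
#' @param grouping `"by_species"` or `"by_genotype"`.
#' @return A list with `column`, `countsByGroup` (named list of named integer
#'   vectors, alleles with non-zero counts only) and `missing` (count of
#'   ambiguous residues).
#' @examples
#' cl <- ESTCluster("c1",
#'   c(s1 = "C", s2 = "C", s3 = "T", s4 = "T"),
#'   species  = c("Gh", "Gh", "Gb", "Gb"),
#'   genotype = c("g1", "g2", "g3", "g4"))
#' tallyColumn(cl, 1)$countsByGroup
#' @export
tallyColumn <- function(cluster, column, grouping = c("by_species", "by_genotype")) {
  grouping <- match.arg(grouping)
  w <- alignmentWidth(cluster)
  if (column < 1L || column > w)
    stop("index error: column ", column, " outside 1..", w)
  res <- substring(as.character(cluster@alignment), column, column)
  states <- residueState(res)
  groups <- if (grouping == "by_species") cluster@species else cluster@genotype
  countsByGroup <- lapply(split(states, groups), function(s) {
    tab <- table(factor(s[!is.na(s)], levels = VALID_STATES))
    tab <- tab[tab > 0L]
    stats::setNames(as.integer(tab), names(tab))
  })
  list(column = column, countsByGroup = countsByGroup,
       missing = sum(is.na(states)))
}

#' Detect variant sites in an aligned cluster
#'
#' Scans every column and reports those with at least two distinct states
#' (alleles or gap) after excluding missing data. Allele reliability is
#' pooled over the whole column: an allele is *reliable* when supported by at
#' least `minAlleleSupport` sequences, and a site is reliable when two or
#' more of its alleles are. Sites with a singleton second allele are the
#' "putative" SNPs that downstream filters discard.
#'
#' Site kinds: `substitution` (two base alleles, no gap), `indel` (one base
#' vs gap; each gap column is an independent single-base indel event), and
#' `complex` (three or more states — excluded from classification and from
#' the variation spectrum).
#'
#' @param cluster an [ESTCluster-class].
#' @param grouping passed through to the per-column tallies retained in the
#'   result attributes (reliability itself is grouping-independent).
#' @param minAlleleSupport reads required for a reliable allele (default 2).
#' @return A data.frame with one row per variant site: `cluster_id`,
#'   `position` (1-based column), `kind`, `alleles` and `reliable_alleles`
#'   (comma-joined, sorted, `GAP` for the gap state) and `reliable`.
#' @examples
#' cl <- ESTCluster("c1",
#'   c(s1 = "CAG", s2 = "CAG", s3 = "TAG", s4 = "TA-"),
#'   species  = c("Gh", "Gh", "Gb", "Gb"),
#'   genotype = c("g1", "g2", "g3", "g4"))
#' detectSites(cl)
#' @export
detectSites <- function(cluster, grouping = c("by_species", "by_genotype"),
                        minAlleleSupport = 2L) {
  grouping <- match.arg(grouping)
  stopifnot(minAlleleSupport >= 1L)
  m <- alignmentMatrix(cluster)
  rows <- lapply(seq_len(ncol(m)), function(j) {
    states <- residueState(m[, j])
    counts <- table(factor(states[!is.na(states)], levels = VALID_STATES))
    counts <- counts[counts > 0L]
    if (length(counts) < 2L) return(NULL)
    alleles <- sort(names(counts))
    relAlleles <- sort(names(counts)[counts >= minAlleleSupport])
    kind <- if (length(alleles) > 2L) "complex"
            else if ("GAP" %in% alleles) "indel"
            else "substitution"
    data.frame(cluster_id = cluster@clusterId, position = j, kind = kind,
               alleles = paste(alleles, collapse = ","),
               reliable_alleles = paste(relAlleles, collapse = ","),
               reliable = length(relAlleles) >= 2L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(emptySiteTable())))
  rownames(out) <- NULL
  attr(out, "grouping") <- grouping
  out
}

emptySiteTable <- function() {
  data.frame(cluster_id = character(0), position = integer(0),
             kind = character(0), alleles = character(0),
             reliable_alleles = character(0), reliable = logical(0),
             stringsAsFactors = FALSE)
}

#' Keep reliable, non-complex sites
#'
#' Filters a site table to the sites usable for classification and marker
#' design: `reliable = TRUE` and kind `substitution` or `indel`. Order is
#' preserved.
#'
#' @param sites a site table from [detectSites()].
#' @return The filtered site table.
#' @export
reliableSites <- function(sites) {
  out <- sites[sites$reliable & sites$kind != "complex", , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Split a comma-joined allele string back into a state vector.
alleleSet <- function(x) {
  if (!nzchar(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
}
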