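# Amplicon window selection and constraint-based primer picking around
# target SNP/InDel sites: a lightweight, deterministic stand-in for a full
# thermodynamic primer designer, enforcing the published length/GC/product
# criteria.

#' Primer design presets
#'
#' Two presets matching the published marker-design criteria. Both use
#' primer length 18-24 bp (optimum 20) and optimum GC 50%. The `snp` preset
#' gates GC to 40-60% with an annealing optimum of 58 degrees C and product
#' size 100-300 bp; the `indel` preset gates GC to 35-60% with an optimum of
#' 55 degrees C and product size 100-500 bp. The temperature optimum ranks
#' candidates but is not a hard gate.
#'
#' @param name `"snp"` or `"indel"`.
#' @return A list with `name`, `lenRange`, `lenOpt`, `gcRange`, `gcOpt`,
#'   `tmOpt`, `productRange`.
#' @examples
#' primerPreset("indel")$productRange
#' @export
primerPreset <- function(name = c("snp", "indel")) {
  name <- match.arg(name)
  if (name == "snp")
    list(name = "snp", lenRange = c(18L, 24L), lenOpt = 20L,
         gcRange = c(40, 60), gcOpt = 50, tmOpt = 58,
         productRange = c(100L, 300L))
  else
    list(name = "indel", lenRange = c(18L, 24L), lenOpt = 20L,
         gcRange = c(35, 60), gcOpt = 50, tmOpt = 55,
         productRange = c(100L, 500L))
}

#' Majority-rule consensus template of an aligned cluster
#'
#' Per column, the most frequent base wins; ties break by the fixed base
#' order A < C < G < T. Ambiguity codes are ignored in the vote. Columns
#' whose majority state is the gap (gap count strictly greater than the best
#' base count, or no base at all) are removed from the template; a
#' column-to-template coordinate map is retained so alignment columns can be
#' located on the template.
#'
#' @param cluster an [ESTCluster-class].
#' @return A list: `template` (character string), `map` (integer vector of
#'   length `alignmentWidth(cluster)`, giving each alignment column's 1-based
#'   template position or `NA` for dropped columns).
#' @examples
#' cl <- ESTCluster("c1", c(a = "AC", b = "AC", c = "AT", d = "AT"),
#'                  species = c("Gh", "Gh", "Gb", "Gb"),
#'                  genotype = c("g1", "g2", "g3", "g4"))
#' consensusTemplate(cl)$template  # "AC": C/T tie broken by base order
#' @export
consensusTemplate <- function(cluster) {
  m <- alignmentMatrix(cluster)
  w <- ncol(m)
  bases <- c("A", "C", "G", "T")
  pick <- character(w)
  for (j in seq_len(w)) {
    col <- m[, j]
    cnt <- table(factor(col[col %in% bases], levels = bases))
    gapN <- sum(col == "-")
    if (all(cnt == 0L) || gapN > max(cnt)) {
      pick[j] <- NA_character_
    } else {
      pick[j] <- bases[which.max(cnt)]  # which.max takes the first = A<C<G<T
    }
  }
  keep <- !is.na(pick)
  map <- rep(NA_integer_, w)
  map[keep] <- seq_len(sum(keep))
  list(template = paste(pick[keep], collapse = ""), map = map)
}

#' GC content of primer-sized sequences
#'
#' @param seq character vector of sequences over `A/C/G/T`.
#' @return Percent GC, `100 * (#G + #C) / length`; `NA` for sequences
#'   containing any other residue (such primers are rejected, not errors).
#' @examples
#' gcContent("ATGCATGCATGCATGCATGC")  # 50
#' @export
gcContent <- function(seq) {
  n <- nchar(seq)
  clean <- grepl("^[ACGT]+$", seq)
  gc <- nchar(gsub("[^GC]", "", seq))
  ifelse(clean & n > 0, 100 * gc / n, NA_real_)
}

#' Melting temperature (GC-method closed form)
#'
#' `Tm = 64.9 + 41 * ((#G + #C) - 16.4) / length`, the standard GC-count
#' approximation for short oligos. Used to rank primer candidates against
#' the preset's annealing optimum; not a hard gate.
#'
#' @param seq character vector of sequences over `A/C/G/T`, length >= 8.
#' @return Tm in degrees C; `NA` for sequences with non-ACGT residues.
#' @examples
#' meltingTemp("ATGCATGCATGCATGCATGC")  # 51.78
#' @export
meltingTemp <- function(seq) {
  n <- nchar(seq)
  if (any(n < 8 & grepl("^[ACGT]+$", seq)))
    stop("melting temperature is defined here for sequences of length >= 8")
  gc <- nchar(gsub("[^GC]", "", seq))
  ifelse(grepl("^[ACGT]+$", seq), 64.9 + 41 * (gc - 16.4) / n, NA_real_)
}

revComp <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(seq, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""), "",
           USE.NAMES = FALSE))
}

# Enumerate single-primer candidates on template positions [lo, hi] (window
# fully inside), rejecting windows with N or overlapping a variant column.
primerCandidates <- function(template, lo, hi, preset, variantCols) {
  L <- nchar(template)
  lo <- max(1L, lo); hi <- min(L, hi)
  if (hi - lo + 1L < preset$lenRange[1]) return(NULL)
  chars <- strsplit(template, "")[[1]]
  isGC <- cumsum(chars %in% c("G", "C"))
  isBad <- cumsum(!chars %in% c("A", "C", "G", "T"))
  isVar <- cumsum(seq_len(L) %in% variantCols)
  cum <- function(v, s, e) v[e] - ifelse(s > 1L, v[s - 1L], 0L)
  out <- list()
  for (len in preset$lenRange[1]:preset$lenRange[2]) {
    starts <- lo:(hi - len + 1L)
    if (length(starts) == 0L || starts[1] > starts[length(starts)]) next
    ends <- starts + len - 1L
    ok <- cum(isBad, starts, ends) == 0L & cum(isVar, starts, ends) == 0L
    gc <- 100 * cum(isGC, starts, ends) / len
    ok <- ok & gc >= preset$gcRange[1] & gc <= preset$gcRange[2]
    if (!any(ok)) next
    tm <- 64.9 + 41 * (cum(isGC, starts, ends)[ok] - 16.4) / len
    out[[length(out) + 1L]] <- data.frame(
      start = starts[ok], len = len, end = ends[ok], gc = gc[ok], tm = tm,
      score = abs(tm - preset$tmOpt) + abs(gc[ok] - preset$gcOpt) +
        abs(len - preset$lenOpt))
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# Greedily split sorted targets into groups a single amplicon can span.
groupTargets <- function(targets, preset) {
  targets <- sort(unique(targets))
  span <- preset$productRange[2] - 2L * preset$lenRange[1]
  groups <- list()
  cur <- targets[1]
  for (t in targets[-1]) {
    if (t - cur[1] + 1L <= span) cur <- c(cur, t)
    else { groups[[length(groups) + 1L]] <- cur; cur <- t }
  }
  groups[[length(groups) + 1L]] <- cur
  groups
}

#' Design primer pairs flanking target variant columns
#'
#' Enumerates all primer pairs whose amplicon covers the target columns,
#' keeps pairs meeting the preset's length, GC and product-size constraints
#' (primers may not contain `N` and may not overlap *any* variant column),
#' ranks them by `|Tm - tmOpt| + |GC - 50| + |len - 20|` summed over both
#' primers (lower is better) and returns the best `k`. Targets too far apart
#' to share an amplicon are split into separate groups, each designed
#' independently — distant SNPs on one template yield multiple markers.
#' Output is deterministic: ties break by leftmost forward start, then
#' forward length, reverse start, reverse length.
#'
#' @param template template sequence (string), e.g. from
#'   [consensusTemplate()].
#' @param targetColumns 1-based template positions the amplicon must cover.
#' @param preset a [primerPreset()].
#' @param variantColumns all variant template positions (default: the
#'   targets) that primers must avoid.
#' @param k maximum candidates returned per target group (default 3).
#' @param clusterId,markerPrefix identifiers used to label candidates.
#' @return data.frame of marker candidates (schema `markers`; positions
#'   1-based; `rev_start` is the 5' end of the reverse primer on the
#'   template's reverse complement, i.e. the rightmost template base of the
#'   amplicon). Zero rows (with a `reason` attribute) when no pair is
#'   feasible.
#' @examples
#' set.seed(1)
#' tpl <- paste(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = "")
#' cands <- designPrimers(tpl, 125, primerPreset("snp"))
#' @export
designPrimers <- function(template, targetColumns, preset = primerPreset("snp"),
                          variantColumns = targetColumns, k = 3L,
                          clusterId = "template", markerPrefix = "M") {
  stopifnot(length(targetColumns) >= 1L)
  L <- nchar(template)
  if (L < preset$productRange[1]) {
    out <- emptyMarkerTable()
    attr(out, "reason") <- "TEMPLATE_SHORTER_THAN_MIN_PRODUCT"
    return(out)
  }
  res <- list()
  groups <- groupTargets(targetColumns, preset)
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    fwd <- primerCandidates(template, 1L, min(g) - 1L, preset, variantColumns)
    rev <- primerCandidates(template, max(g) + 1L, L, preset, variantColumns)
    if (is.null(fwd) || is.null(rev)) next
    # pair: product = rev_end - fwd_start + 1 within the preset range
    pairIdx <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
    prod <- rev$end[pairIdx$r] - fwd$start[pairIdx$f] + 1L
    keep <- prod >= preset$productRange[1] & prod <= preset$productRange[2]
    if (!any(keep)) next
    pairIdx <- pairIdx[keep, , drop = FALSE]
    prod <- prod[keep]
    sc <- fwd$score[pairIdx$f] + rev$score[pairIdx$r]
    ord <- order(sc, fwd$start[pairIdx$f], fwd$len[pairIdx$f],
                 rev$start[pairIdx$r], rev$len[pairIdx$r])
    take <- ord[seq_len(min(k, length(ord)))]
    f <- fwd[pairIdx$f[take], ]; r <- rev[pairIdx$r[take], ]
    covered <- vapply(seq_along(take), function(i) {
      v <- variantColumns[variantColumns >= f$start[i] &
                            variantColumns <= r$end[i]]
      paste(sort(v), collapse = ",")
    }, "")
    res[[length(res) + 1L]] <- data.frame(
      marker_id = sprintf("%s_%s_t%d_%d", markerPrefix, clusterId, gi,
                          seq_along(take)),
      cluster_id = clusterId,
      fwd_seq = substring(template, f$start, f$end),
      fwd_start = f$start, fwd_len = f$len,
      fwd_gc = f$gc, fwd_tm = f$tm,
      rev_seq = revComp(substring(template, r$start, r$end)),
      rev_start = r$end, rev_len = r$len,
      rev_gc = r$gc, rev_tm = r$tm,
      product_length = as.integer(prod[take]),
      covered_sites = covered,
      site_classes = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) {
    out <- emptyMarkerTable()
    attr(out, "reason") <- "NO_FEASIBLE_PRIMER_PAIR"
    return(out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

emptyMarkerTable <- function() {
  data.frame(marker_id = character(0), cluster_id = character(0),
             fwd_seq = character(0), fwd_start = integer(0),
             fwd_len = integer(0), fwd_gc = numeric(0), fwd_tm = numeric(0),
             rev_seq = character(0), rev_start = integer(0),
             rev_len = integer(0), rev_gc = numeric(0), rev_tm = numeric(0),
             product_length = integer(0), covered_sites = character(0),
             site_classes = character(0), stringsAsFactors = FALSE)
}
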