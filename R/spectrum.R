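# Summary statistics: the ten-category base-variation spectrum with
# transition/transversion/indel aggregates, SNPs per gene by function
# category, marker-panel polymorphism rates and linkage-map summaries.

# The ten categories: six unordered base pairs on the sense strand plus the
# four single-base indels. CT and GA are the transitions.
SPECTRUM_CATEGORIES <- data.frame(
  category = c("CT", "GA", "CG", "AT", "CA", "TG",
               "A_GAP", "C_GAP", "G_GAP", "T_GAP"),
  family = c("transition", "transition", "transversion", "transversion",
             "transversion", "transversion", "indel", "indel", "indel",
             "indel"),
  stringsAsFactors = FALSE)

PAIR_TO_CATEGORY <- c("C,T" = "CT", "A,G" = "GA", "C,G" = "CG",
                      "A,T" = "AT", "A,C" = "CA", "G,T" = "TG")

#' Categorize a variant site into the ten base-variation categories
#'
#' Substitutions map to the unordered base pair on the sense strand (e.g.
#' `{C,T}` and `{T,C}` both to `CT`, `{A,G}` to `GA`, `{A,C}` to `CA`,
#' `{G,T}` to `TG`); single-base indels map to the category of their non-gap
#' base (`A_GAP` ... `T_GAP`). Complex sites are a categorization error —
#' callers filter them out first.
#'
#' @param alleles character vector of exactly two states from
#'   `A/C/G/T/GAP`, or a comma-joined string as stored in site tables.
#' @return A list: `category`, `family` (`transition`, `transversion` or
#'   `indel`).
#' @examples
#' categorizeVariation(c("T", "C"))$category   # "CT"
#' categorizeVariation(c("A", "GAP"))$family   # "indel"
#' @export
categorizeVariation <- function(alleles) {
  if (length(alleles) == 1L) alleles <- alleleSet(alleles)
  alleles <- sort(unique(alleles))
  if (length(alleles) != 2L || !all(alleles %in% VALID_STATES))
    stop("categorization error: need exactly two states from A/C/G/T/GAP")
  if ("GAP" %in% alleles) {
    base <- setdiff(alleles, "GAP")
    if (length(base) != 1L)
      stop("categorization error: indel must pair one base with GAP")
    cat <- paste0(base, "_GAP")
  } else {
    cat <- unname(PAIR_TO_CATEGORY[paste(alleles, collapse = ",")])
  }
  list(category = cat,
       family = SPECTRUM_CATEGORIES$family[SPECTRUM_CATEGORIES$category == cat])
}

#' Base-variation spectrum from named category counts
#'
#' Core arithmetic behind [computeSpectrum()], also usable directly on a
#' published count column. Percentages are half-up to 2 decimals of the
#' grand total. Besides the ten-category table the complement-collapsed
#' six-kind rollup is emitted (`A/T indels`, `C/G indels`, transitions,
#' `CA+TG`, `AT`, `CG`).
#'
#' @param counts named numeric vector over the ten categories (missing
#'   categories count 0).
#' @return A list: `table` (category, family, count, percent), `aggregates`
#'   (transitions / transversions / indels / total rows with counts and
#'   percents), `sixKinds` (collapsed rollup), `grand_total`, and `empty`
#'   (flag set when the input has no variants; percentages then report 0).
#' @examples
#' spectrumFromCounts(c(CT = 1, GA = 1, CG = 2))$aggregates
#' @export
spectrumFromCounts <- function(counts) {
  bad <- setdiff(names(counts), SPECTRUM_CATEGORIES$category)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  full <- stats::setNames(numeric(nrow(SPECTRUM_CATEGORIES)),
                          SPECTRUM_CATEGORIES$category)
  full[names(counts)] <- counts
  total <- sum(full)
  pct <- function(x) if (total > 0) roundHalfUp(100 * x / total, 2) else 0
  tab <- data.frame(SPECTRUM_CATEGORIES,
                    count = as.numeric(full),
                    percent = pct(as.numeric(full)),
                    stringsAsFactors = FALSE)
  aggCount <- vapply(c("transition", "transversion", "indel"), function(f)
    sum(full[SPECTRUM_CATEGORIES$category[SPECTRUM_CATEGORIES$family == f]]),
    1.0)
  aggregates <- data.frame(
    family = c("transition", "transversion", "indel", "total"),
    count = c(aggCount, total),
    percent = c(pct(aggCount), if (total > 0) 100 else 0),
    stringsAsFactors = FALSE)
  sixKinds <- data.frame(
    kind = c("A/- or T/-", "C/- or G/-", "A>G or T>C (transitions)",
             "A>C or T>G", "A>T or T>A", "C>G or G>C"),
    count = c(full["A_GAP"] + full["T_GAP"], full["C_GAP"] + full["G_GAP"],
              full["CT"] + full["GA"], full["CA"] + full["TG"],
              full["AT"], full["CG"]),
    stringsAsFactors = FALSE)
  sixKinds$percent <- pct(sixKinds$count)
  rownames(sixKinds) <- NULL
  list(table = tab, aggregates = aggregates, sixKinds = sixKinds,
       grand_total = total, empty = total == 0)
}

#' Base-variation spectrum of a set of variant sites
#'
#' Categorizes each site with [categorizeVariation()] (one variation per
#' variant column) and tabulates. Input must be pre-filtered to reliable,
#' non-complex sites (see [reliableSites()]).
#'
#' @param sites site table with an `alleles` column.
#' @return See [spectrumFromCounts()].
#' @export
computeSpectrum <- function(sites) {
  if (nrow(sites) == 0L) return(spectrumFromCounts(numeric(0)))
  if (any(sites$kind == "complex"))
    stop("categorization error: complex sites must be filtered out first")
  cats <- vapply(sites$alleles, function(a) categorizeVariation(a)$category, "",
                 USE.NAMES = FALSE)
  counts <- table(factor(cats, levels = SPECTRUM_CATEGORIES$category))
  spectrumFromCounts(stats::setNames(as.numeric(counts), names(counts)))
}

#' SNPs per gene by function category
#'
#' Genes may belong to several categories; per category the number of genes,
#' the summed SNPs and the SNPs-per-gene ratio (half-up, 2 decimals) are
#' reported. Genes annotated with a category but absent from the count table
#' are excluded with a warning.
#'
#' @param geneSnpCounts named numeric vector: SNP count per gene.
#' @param geneCategories data.frame with columns `gene` and `category`
#'   (one row per gene-category membership).
#' @return data.frame: `category`, `n_genes`, `n_snps`, `snps_per_gene`,
#'   ordered by category.
#' @examples
#' snpsPerGene(c(g1 = 300, g2 = 35),
#'             data.frame(gene = c("g1", "g2"),
#'                        category = "cellular component"))
#' @export
snpsPerGene <- function(geneSnpCounts, geneCategories) {
  stopifnot(all(c("gene", "category") %in% names(geneCategories)))
  unknown <- !geneCategories$gene %in% names(geneSnpCounts)
  if (any(unknown)) {
    warning("excluding gene(s) with category but no SNP count: ",
            paste(unique(geneCategories$gene[unknown]), collapse = ", "))
    geneCategories <- geneCategories[!unknown, , drop = FALSE]
  }
  rows <- lapply(split(geneCategories$gene, geneCategories$category),
                 function(genes) {
    genes <- unique(genes)
    n <- length(genes)
    s <- sum(geneSnpCounts[genes])
    data.frame(n_genes = n, n_snps = s,
               snps_per_gene = roundHalfUp(s / n, 2))
  })
  out <- do.call(rbind, rows)
  out <- data.frame(category = names(rows), out, stringsAsFactors = FALSE)
  out <- out[order(out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Marker panel polymorphism rates
#'
#' Per-row polymorphic rate `100 * polymorphic / tested` (half-up, 2
#' decimals), plus per-class subtotals and a grand total recomputed from the
#' summed counts.
#'
#' @param rows data.frame with columns `class`, `subclass`, `tested`,
#'   `polymorphic`, `loci`.
#' @return data.frame in report schema `panel` with the input rows followed
#'   by `subtotal` rows per class and one `total` row.
#' @examples
#' panelRates(data.frame(class = "all", subclass = "all",
#'                       tested = 1349, polymorphic = 137, loci = 142))
#' @export
panelRates <- function(rows) {
  stopifnot(all(c("class", "subclass", "tested", "polymorphic", "loci") %in%
                  names(rows)))
  if (any(rows$tested <= 0)) stop("data error: tested must be positive")
  if (any(rows$polymorphic > rows$tested) || any(rows$polymorphic < 0))
    stop("data error: polymorphic must lie in [0, tested]")
  rate <- function(p, t) roundHalfUp(100 * p / t, 2)
  rows$rate_pct <- rate(rows$polymorphic, rows$tested)
  sub <- do.call(rbind, lapply(split(rows, rows$class), function(d)
    data.frame(class = d$class[1L], subclass = "subtotal",
               tested = sum(d$tested), polymorphic = sum(d$polymorphic),
               loci = sum(d$loci),
               rate_pct = rate(sum(d$polymorphic), sum(d$tested)),
               stringsAsFactors = FALSE)))
  tot <- data.frame(class = "total", subclass = "total",
                    tested = sum(rows$tested),
                    polymorphic = sum(rows$polymorphic),
                    loci = sum(rows$loci),
                    rate_pct = rate(sum(rows$polymorphic), sum(rows$tested)),
                    stringsAsFactors = FALSE)
  out <- rbind(rows[names(tot)], sub, tot)
  rownames(out) <- NULL
  out
}

#' Linkage map summary: loci, length and average marker interval
#'
#' Average marker interval per chromosome is `length_cM / n_loci` (half-up,
#' 2 decimals); per-genome and total rows aggregate lengths and loci first
#' and then recompute the interval.
#'
#' @param lociTable data.frame with columns `chromosome`, `genome`,
#'   `length_cM`, `n_loci`.
#' @return data.frame in report schema `map_summary`: chromosome rows, one
#'   row per genome (chromosome `"genome"`), one total row (`"total"`,
#'   genome `"total"`).
#' @examples
#' mapSummary(data.frame(chromosome = "Chr01", genome = "A",
#'                       length_cM = 100, n_loci = 100))
#' @export
mapSummary <- function(lociTable) {
  stopifnot(all(c("chromosome", "genome", "length_cM", "n_loci") %in%
                  names(lociTable)))
  if (any(lociTable$n_loci < 1)) stop("data error: each chromosome needs loci")
  if (any(lociTable$length_cM < 0)) stop("data error: negative map length")
  iv <- function(len, n) roundHalfUp(len / n, 2)
  chrom <- data.frame(lociTable[c("chromosome", "genome", "length_cM",
                                  "n_loci")],
                      interval_cM = iv(lociTable$length_cM, lociTable$n_loci),
                      stringsAsFactors = FALSE)
  gen <- do.call(rbind, lapply(split(chrom, chrom$genome), function(d)
    data.frame(chromosome = "genome", genome = d$genome[1L],
               length_cM = sum(d$length_cM), n_loci = sum(d$n_loci),
               interval_cM = iv(sum(d$length_cM), sum(d$n_loci)),
               stringsAsFactors = FALSE)))
  tot <- data.frame(chromosome = "total", genome = "total",
                    length_cM = sum(chrom$length_cM),
                    n_loci = sum(chrom$n_loci),
                    interval_cM = iv(sum(chrom$length_cM), sum(chrom$n_loci)),
                    stringsAsFactors = FALSE)
  out <- rbind(chrom, gen, tot)
  rownames(out) <- NULL
  out
}
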