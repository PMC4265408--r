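# Readers/writers: aligned clusters (FASTA/CLUSTAL), CDS annotation TSVs and
# the fixed-schema report TSVs consumed by downstream tooling.

IUPAC_OK <- c("A", "C", "G", "T", "N", "-",
              "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

# Parse `key=value` tokens from a FASTA description or a `|`-delimited
# CLUSTAL-safe identifier. Returns list(id, tokens).
parseHeader <- function(header) {
  parts <- strsplit(header, "[ |]+")[[1]]
  parts <- parts[nzchar(parts)]
  kv <- grepl("=", parts, fixed = TRUE)
  tokens <- strsplit(parts[kv], "=", fixed = TRUE)
  vals <- vapply(tokens, function(x) paste(x[-1], collapse = "="), "")
  names(vals) <- vapply(tokens, `[[`, "", 1L)
  list(id = parts[1L], tokens = vals)
}

#' Read an aligned EST cluster with species/genotype metadata
#'
#' Sequence headers must carry `species=` and `genotype=` tokens after the
#' identifier, e.g. `>est1 species=Gh genotype=TM-1` in FASTA. CLUSTAL
#' identifiers cannot contain spaces, so there the tokens are `|`-delimited:
#' `est1|species=Gh|genotype=TM-1`. Residues are upper-cased and `U` is
#' mapped to `T`; IUPAC ambiguity codes are retained (downstream tallies
#' treat them as missing data, never as alleles).
#'
#' @param path file path.
#' @param dialect `"fasta"` (aligned multi-FASTA) or `"clustal"`.
#' @param clusterId cluster identifier; defaults to the file name without
#'   extension.
#' @return An [ESTCluster-class].
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">e1 species=Gh genotype=g1", "ACGT",
#'              ">e2 species=Gh genotype=g2", "ACGT",
#'              ">e3 species=Gb genotype=g3", "ACTT",
#'              ">e4 species=Gb genotype=g4", "ACTT"), tf)
#' cl <- readAlignedCluster(tf)
#' speciesLabels(cl)
#' @export
readAlignedCluster <- function(path, dialect = c("fasta", "clustal"),
                               clusterId = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(clusterId))
    clusterId <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "fasta") {
    raw <- Biostrings::readBStringSet(path)
    seqs <- as.character(raw)
    headers <- names(raw)
  } else {
    aln <- Biostrings::readDNAMultipleAlignment(path, format = "clustal")
    seqs <- as.character(Biostrings::unmasked(aln))
    headers <- names(seqs)
  }
  seqs <- chartr("uU", "tT", toupper(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop("alignment error: ragged sequence lengths (",
         paste(unique(lens), collapse = ", "), ")")
  bad <- !grepl(paste0("^[", paste(setdiff(IUPAC_OK, "-"), collapse = ""),
                       "-]*$"), seqs)
  if (any(bad))
    stop("format error: illegal residue in sequence(s) ",
         paste(vapply(headers[bad], function(h) parseHeader(h)$id, ""),
               collapse = ", "))
  meta <- lapply(headers, parseHeader)
  ids <- vapply(meta, `[[`, "", "id")
  getTok <- function(m, key) {
    v <- m$tokens[key]
    if (is.na(v) || !nzchar(v))
      stop("metadata error: sequence '", m$id, "' lacks a '", key, "=' token")
    unname(v)
  }
  species <- vapply(meta, getTok, "", key = "species")
  genotype <- vapply(meta, getTok, "", key = "genotype")
  names(seqs) <- ids
  ESTCluster(clusterId, seqs, species, genotype)
}

#' Write an aligned cluster as annotated multi-FASTA
#'
#' Inverse of [readAlignedCluster()]: headers carry the `species=` and
#' `genotype=` tokens, so a write/read round trip reproduces labels and
#' residues exactly.
#'
#' @param cluster an [ESTCluster-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAlignedCluster <- function(cluster, path) {
  out <- cluster@alignment
  names(out) <- sprintf("%s species=%s genotype=%s",
                        names(out), cluster@species, cluster@genotype)
  Biostrings::writeXStringSet(out, path, width = 70L)
  invisible(path)
}

#' Load and validate CDS annotations from a TSV
#'
#' Expects columns `seq_id`, `cds_start`, `cds_end`, `complete` (1-based
#' inclusive coordinates). Rows violating the invariants — `cds_start < 1`,
#' `cds_end <= cds_start`, CDS length not divisible by 3 when flagged
#' complete, or `cds_end` beyond the known sequence length — are rejected
#' with per-row reasons.
#'
#' @param path TSV file path.
#' @param seqLengths optional named integer vector of parent sequence lengths,
#'   enabling the coordinate bound check.
#' @return A data.frame of accepted annotations (`seq_id`, `cds_start`,
#'   `cds_end`, `complete`); rejected rows are attached as
#'   `attr(, "rejected")` (with a `reason` column) and reported via warning.
#' @export
loadCdsAnnotations <- function(path, seqLengths = NULL) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_id", "cds_start", "cds_end", "complete")
  if (!all(need %in% names(ann)))
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  ann$cds_start <- as.integer(ann$cds_start)
  ann$cds_end <- as.integer(ann$cds_end)
  ann$complete <- as.logical(ann$complete)
  reason <- rep(NA_character_, nrow(ann))
  flag <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- flag(is.na(ann$cds_start) | ann$cds_start < 1L, "cds_start must be >= 1")
  reason <- flag(is.na(ann$cds_end) | ann$cds_end <= ann$cds_start,
                 "cds_end must exceed cds_start")
  len <- ann$cds_end - ann$cds_start + 1L
  reason <- flag(ann$complete & len %% 3L != 0L,
                 "complete CDS length not divisible by 3")
  if (!is.null(seqLengths)) {
    known <- ann$seq_id %in% names(seqLengths)
    over <- known & ann$cds_end > seqLengths[ann$seq_id]
    over[is.na(over)] <- FALSE
    reason <- flag(over, "cds_end beyond sequence length")
  }
  rejected <- ann[!is.na(reason), , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- reason[!is.na(reason)]
    warning(nrow(rejected), " annotation row(s) rejected: ",
            paste(sprintf("%s (%s)", rejected$seq_id, rejected$reason),
                  collapse = "; "))
  }
  accepted <- ann[is.na(reason), need, drop = FALSE]
  rownames(accepted) <- NULL
  attr(accepted, "rejected") <- rejected
  accepted
}

REPORT_SCHEMAS <- list(
  sites = list(cols = c("cluster_id", "position", "kind", "alleles",
                        "reliable_alleles", "reliable", "site_class"),
               key = c("cluster_id", "position")),
  markers = list(cols = c("marker_id", "cluster_id", "fwd_seq", "fwd_start",
                          "fwd_len", "fwd_gc", "fwd_tm", "rev_seq", "rev_start",
                          "rev_len", "rev_gc", "rev_tm", "product_length",
                          "covered_sites", "site_classes"),
                 key = "marker_id"),
  spectrum = list(cols = c("category", "family", "count", "percent"),
                  key = "category"),
  panel = list(cols = c("class", "subclass", "tested", "polymorphic", "loci",
                        "rate_pct"),
               key = c("class", "subclass")),
  map_summary = list(cols = c("chromosome", "genome", "length_cM", "n_loci",
                              "interval_cM"),
                     key = c("genome", "chromosome")),
  truth = list(cols = c("cluster_id", "position", "kind", "true_class", "event"),
               key = c("cluster_id", "position"))
)

#' Write a report TSV with a fixed schema
#'
#' Each schema has a fixed, documented column order and a primary key used to
#' sort rows, so identical inputs always produce byte-identical files. All
#' positions in reports are 1-based inclusive. Schemas: `sites`, `markers`,
#' `spectrum`, `panel`, `map_summary`, `truth`.
#'
#' @param records data.frame (possibly empty) holding at least the schema's
#'   columns; missing optional columns are filled with `NA`.
#' @param path output file path.
#' @param schema schema name.
#' @return `path`, invisibly.
#' @export
writeReport <- function(records, path, schema) {
  if (!schema %in% names(REPORT_SCHEMAS))
    stop("configuration error: unknown report schema '", schema, "'")
  sch <- REPORT_SCHEMAS[[schema]]
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) {
    records <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(sch$cols)), sch$cols))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in setdiff(sch$cols, names(records))) records[[col]] <- NA
  records <- records[sch$cols]
  ord <- do.call(order, records[sch$key])
  records <- records[ord, , drop = FALSE]
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
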