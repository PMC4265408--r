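# Fixture builders shared across test files. Clusters are built in code so
# the suite ships no binary data.

# A cluster from a named list of aligned sequences plus parallel labels.
makeCluster <- function(seqs, species, genotype, id = "test") {
  ESTCluster(id, seqs, species, genotype)
}

# 2 Gh + 2 Gb reads over explicit per-species haplotypes; each species'
# reads are two exact copies of its haplotype, so every allele is reliable.
twoSpeciesCluster <- function(hapGh, hapGb, id = "c") {
  makeCluster(c(gh1 = hapGh, gh2 = hapGh, gb1 = hapGb, gb2 = hapGb),
              species = c("Gh", "Gh", "Gb", "Gb"),
              genotype = c("ghA", "ghB", "gbA", "gbB"), id = id)
}

# A cluster from explicit per-read column characters: `cols` is a list of
# character vectors (one per column), each of length length(species).
clusterFromColumns <- function(cols, species, genotype, id = "cols") {
  m <- do.call(cbind, cols)
  seqs <- apply(m, 1, paste, collapse = "")
  names(seqs) <- sprintf("r%d", seq_along(seqs))
  makeCluster(seqs, species, genotype, id)
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

writeClusterFasta <- function(lines, ext = ".fasta") {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}
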