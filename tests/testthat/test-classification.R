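# Brute-force oracle for site classification: hand-enumerated truth over
# every ordered pair of non-empty subsets of a biallelic site {X, Y}.
subsetPairTruth <- function() {
  data.frame(
    s1 = c("X", "X", "X", "Y", "Y", "Y", "XY", "XY", "XY"),
    s2 = c("X", "Y", "XY", "X", "Y", "XY", "X", "Y", "XY"),
    expected = c("UNCLASSIFIED",        # monomorphic; caller never reaches
                 "INTER", "HEMI",
                 "INTER",
                 "UNCLASSIFIED",        # monomorphic; caller never reaches
                 "HEMI", "HEMI", "HEMI",
                 "INTER_HOMOEOLOGOUS"),
    stringsAsFactors = FALSE)
}

test_that("site classification matches the exhaustive subset-pair oracle", {
  toSet <- function(code, x = "C", y = "T")
    c(X = x, Y = y)[strsplit(code, "")[[1]]]
  truth <- subsetPairTruth()
  for (i in seq_len(nrow(truth))) {
    got <- classifySite(toSet(truth$s1[i]), toSet(truth$s2[i]))
    expect_equal(got, truth$expected[i],
                 label = sprintf("pair (%s, %s)", truth$s1[i], truth$s2[i]))
  }
  # the same partition holds for an indel allele pair
  expect_equal(classifySite(c("A", "GAP"), c("A", "GAP")), "INTER_HOMOEOLOGOUS")
  expect_equal(classifySite("A", "GAP"), "INTER")
  expect_equal(classifySite("GAP", c("A", "GAP")), "HEMI")
  expect_error(classifySite(character(0), "C"), "precondition")
})

test_that("figure-style clusters classify at site and cluster level", {
  # both species carry both base types (reads duplicated so alleles are
  # reliable): inter-homoeologous pseudo-SNP
  homoeo <- clusterFromColumns(list(c("C", "C", "T", "T", "C", "C", "T", "T")),
                               species = c(rep("Gh", 4), rep("Gb", 4)),
                               genotype = sprintf("g%d", 1:8))
  expect_equal(classifySites(homoeo)$site_class, "INTER_HOMOEOLOGOUS")

  inter <- twoSpeciesCluster("CAG", "TAG")
  expect_equal(classifySites(inter)$site_class, "INTER")

  hemi <- clusterFromColumns(list(c("C", "C", "C", "C", "T", "T")),
                             species = c("Gh", "Gh", "Gb", "Gb", "Gb", "Gb"),
                             genotype = sprintf("g%d", 1:6))
  expect_equal(classifySites(hemi)$site_class, "HEMI")
})

test_that("cluster rollup is deterministic and permutation-invariant", {
  expect_equal(classifyCluster(character(0)), "NO_SNP")
  expect_equal(classifyCluster(c("HEMI", "INTER_HOMOEOLOGOUS")), "HEMI_ONLY")
  expect_equal(classifyCluster(c("HEMI", "INTER")), "INTER_HEMI")
  expect_equal(classifyCluster("INTER_HOMOEOLOGOUS"), "HOMOEO_ONLY")
  set.seed(5)
  for (i in 1:20) {
    cls <- sample(c("INTER", "HEMI", "INTER_HOMOEOLOGOUS", "UNCLASSIFIED"),
                  sample(1:6, 1), TRUE)
    expect_equal(classifyCluster(cls), classifyCluster(sample(cls)))
  }
})

test_that("cluster classes partition a collection", {
  set.seed(6)
  classes <- vapply(1:30, function(i) {
    p <- simParams(seed = 1000L + i, errorRate = 0, indelRate = 0,
                   nPerHaplotype = 1L, seqLength = 150L)
    res <- checkInterspecificEligibility(simulateCluster(p)$cluster)
    res$cluster_class
  }, "")
  summ <- clusterClassSummary(classes)
  expect_equal(sum(summ$count), 30L)
  expect_true(all(summ$class %in%
                    c("NO_SNP", "HOMOEO_ONLY", "INTER_HEMI", "HEMI_ONLY")))
})

test_that("interspecific eligibility applies the per-species floor and class rules", {
  cfg <- runConfig()
  # 3 Gh + 1 Gb with a reliable hemi site: fails only the per-species floor
  skew <- clusterFromColumns(list(c("C", "C", "T", "T"), c("A", "A", "A", "A")),
                             species = c("Gh", "Gh", "Gh", "Gb"),
                             genotype = sprintf("g%d", 1:4))
  r <- checkInterspecificEligibility(skew, cfg)
  expect_false(r$eligible)
  expect_equal(r$reasons, "MIN_SEQS_PER_SPECIES")

  # only inter-homoeologous sites: discarded
  homoeo <- clusterFromColumns(list(c("C", "C", "T", "T", "C", "C", "T", "T")),
                               species = c(rep("Gh", 4), rep("Gb", 4)),
                               genotype = sprintf("g%d", 1:8))
  r <- checkInterspecificEligibility(homoeo, cfg)
  expect_false(r$eligible)
  expect_equal(r$reasons, "HOMOEO_ONLY")
  expect_equal(r$cluster_class, "HOMOEO_ONLY")

  # one reliable hemi site: eligible
  hemi <- clusterFromColumns(list(c("C", "C", "C", "C", "T", "T")),
                             species = c("Gh", "Gh", "Gb", "Gb", "Gb", "Gb"),
                             genotype = sprintf("g%d", 1:6))
  r <- checkInterspecificEligibility(hemi, cfg)
  expect_true(r$eligible)
  expect_length(r$reasons, 0L)

  # no variation at all
  mono <- twoSpeciesCluster("ACGTACGT", "ACGTACGT")
  r <- checkInterspecificEligibility(mono, cfg)
  expect_equal(r$reasons, "NO_RELIABLE_SNP")
  expect_equal(r$cluster_class, "NO_SNP")

  oneSpecies <- makeCluster(c(a = "ACG", b = "ACG"), c("Gh", "Gh"),
                            c("g1", "g2"))
  expect_error(checkInterspecificEligibility(oneSpecies, cfg),
               "grouping error")
})

test_that("intraspecific eligibility enforces EST count, genotypes and reliable SNPs", {
  cfg <- runConfig()
  tiny <- makeCluster(c(a = "ACGT", b = "ACGT", c = "ACTT"),
                      species = rep("Gh", 3), genotype = c("g1", "g2", "g3"))
  r <- checkIntraspecificEligibility(tiny, cfg)
  expect_false(r$eligible)
  expect_true("MIN_ESTS" %in% r$reasons)

  sameGt <- clusterFromColumns(list(c("C", "C", "T", "T", "T")),
                               species = rep("Gh", 5),
                               genotype = rep("TM-1", 5))
  r <- checkIntraspecificEligibility(sameGt, cfg)
  expect_false(r$eligible)
  expect_true("SINGLE_GENOTYPE" %in% r$reasons)

  putative <- clusterFromColumns(list(c("C", "C", "C", "T")),
                                 species = rep("Gh", 4),
                                 genotype = c("g1", "g1", "g2", "g2"))
  r <- checkIntraspecificEligibility(putative, cfg)
  expect_false(r$eligible)
  expect_equal(r$reasons, "NO_RELIABLE_SNP")

  good <- clusterFromColumns(list(c("C", "C", "T", "T")),
                             species = rep("Gh", 4),
                             genotype = c("g1", "g1", "g2", "g2"))
  r <- checkIntraspecificEligibility(good, cfg)
  expect_true(r$eligible)
  expect_equal(r$sites$site_class, "INTRA")
})
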