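test_that("sequence evolution honours rate zero and the kappa limit", {
  set.seed(71)
  s <- randomDna(300)
  r <- evolveSequence(s, rate = 0)
  expect_identical(r$seq, s)
  expect_equal(nrow(r$events), 0L)

  # kappa -> infinity: substitutions are all transitions
  r <- evolveSequence(s, rate = 0.5, kappa = 1e9)
  subs <- r$events[r$events$type == "substitution", ]
  expect_gt(nrow(subs), 50)
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  expect_true(all(subs$to == ts[subs$from]))

  # deletions become gaps in place: alignment length is preserved
  r <- evolveSequence(s, rate = 0.1, indelRate = 0.1)
  expect_equal(nchar(r$seq), nchar(s))
  dels <- r$events[r$events$type == "deletion", ]
  expect_true(all(substring(r$seq, dels$position, dels$position) == "-"))
})

test_that("identical SimParams reproduce byte-identical clusters and truth", {
  p <- simParams(seed = 99L)
  a <- simulateCluster(p)
  b <- simulateCluster(p)
  expect_identical(as.character(clusterAlignment(a$cluster)),
                   as.character(clusterAlignment(b$cluster)))
  expect_identical(a$truth, b$truth)
  c3 <- simulateCluster(simParams(seed = 100L))
  expect_false(identical(as.character(clusterAlignment(a$cluster)),
                         as.character(clusterAlignment(c3$cluster))))
})

test_that("single-divergence regimes yield pure truth classes", {
  # species divergence only, one retained homoeolog: all INTER
  inter <- simulateCluster(simParams(
    seed = 72, dHomoeolog = 0, dSpecies = 0.03, dIntra = 0, errorRate = 0,
    homoeologs = list(Gh = "A", Gb = "A")))
  expect_gt(nrow(inter$truth), 0)
  expect_true(all(inter$truth$true_class == "INTER"))

  # homoeolog divergence only, both homoeologs in both species: all pseudo-SNPs
  homoeo <- simulateCluster(simParams(
    seed = 73, dHomoeolog = 0.03, dSpecies = 0, dIntra = 0, errorRate = 0))
  expect_gt(nrow(homoeo$truth), 0)
  expect_true(all(homoeo$truth$true_class == "INTER_HOMOEOLOGOUS"))

  # one species with both homoeologs, the other with one: hemi-SNPs
  hemi <- simulateCluster(simParams(
    seed = 74, dHomoeolog = 0.03, dSpecies = 0, dIntra = 0, errorRate = 0,
    homoeologs = list(Gh = c("A", "D"), Gb = "A")))
  expect_gt(nrow(hemi$truth), 0)
  expect_true(all(hemi$truth$true_class == "HEMI"))
})

test_that("error-free simulated clusters are classified exactly as the truth", {
  p <- simParams(seed = 75, errorRate = 0, nPerHaplotype = 2L)
  sim <- simulateCluster(p)
  sites <- classifySites(sim$cluster)
  truth <- sim$truth[sim$truth$true_class != "COMPLEX", ]
  merged <- merge(truth, sites[c("position", "site_class")], by = "position")
  expect_equal(nrow(merged), nrow(truth))
  expect_equal(merged$site_class, merged$true_class)
  # and no classified site lacks a truth event
  expect_true(all(sites$position %in% sim$truth$position))
})

test_that("misclassifications under sequencing error trace to error events", {
  p <- simParams(seed = 76, errorRate = 0.01, nPerHaplotype = 2L)
  sim <- simulateCluster(p)
  sites <- classifySites(sim$cluster)
  truth <- sim$truth[sim$truth$true_class %in%
                       c("INTER", "HEMI", "INTER_HOMOEOLOGOUS"), ]
  merged <- merge(truth, sites[c("position", "site_class")], by = "position")
  wrong <- merged$position[is.na(merged$site_class) |
                             merged$site_class != merged$true_class]
  errPos <- sim$truth$position[sim$truth$event == "error"]
  expect_true(all(wrong %in% errPos))
})

test_that("simulated unigenes carry INTRA truth and pass intraspecific mining", {
  p <- simParams(seed = 77, dIntra = 0.02, errorRate = 0, nPerHaplotype = 2L)
  sim <- simulateUnigene(p)
  expect_equal(length(unique(speciesLabels(sim$cluster))), 1L)
  expect_gt(nrow(sim$truth), 0)
  expect_true(all(sim$truth$true_class %in% c("INTRA", "COMPLEX")))
  r <- checkIntraspecificEligibility(sim$cluster)
  expect_true(r$eligible)
  expect_setequal(r$sites$position,
                  sim$truth$position[sim$truth$true_class == "INTRA"])
})

test_that("undersized species samples always fail the per-species floor", {
  for (seed in 78:82) {
    p <- simParams(seed = seed, genotypes = list(Gh = c("a", "b"), Gb = "c"),
                   homoeologs = list(Gh = c("A", "D"), Gb = "A"),
                   nPerHaplotype = 1L)
    sim <- simulateCluster(p)
    keep <- which(speciesLabels(sim$cluster) == "Gh" |
                    seq_len(nSeq(sim$cluster)) ==
                      which(speciesLabels(sim$cluster) == "Gb")[1])
    aln <- as.character(clusterAlignment(sim$cluster))[keep]
    cl <- ESTCluster("skew", aln, speciesLabels(sim$cluster)[keep],
                     genotypeLabels(sim$cluster)[keep])
    r <- checkInterspecificEligibility(cl)
    expect_true("MIN_SEQS_PER_SPECIES" %in% r$reasons)
    expect_false(r$eligible)
  }
})

test_that("simulated mRNA sets exercise the UTR threshold and redundancy removal", {
  sim <- simulateMrnaSet(10, utrLengths = 80:120, seed = 83)
  acc <- vapply(seq_len(nrow(sim$annotations)), function(i) {
    a <- sim$annotations[i, ]
    extractUtr3(sim$sequences[[a$seq_id]], a)$accepted
  }, TRUE)
  utrLen <- nchar(sim$sequences) - sim$annotations$cds_end
  expect_equal(sum(acc), sum(utrLen > 100))

  dup <- simulateMrnaSet(10, utrLengths = 150:200, dupFraction = 0.5, seed = 84)
  recs <- data.frame(seq_id = dup$annotations$seq_id,
                     utr_sequence = vapply(seq_len(10), function(i) {
                       a <- dup$annotations[i, ]
                       substring(dup$sequences[[a$seq_id]], a$cds_end + 1)
                     }, ""), stringsAsFactors = FALSE)
  kept <- removeRedundancy(recs)
  expect_lte(abs(nrow(kept) - 5L), 1L)

  one <- simulateMrnaSet(1, utrLengths = c(0L, 0L), seed = 85)
  r <- extractUtr3(one$sequences[[1]], one$annotations[1, ])
  expect_equal(r$reason, "NO_UTR")
})
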