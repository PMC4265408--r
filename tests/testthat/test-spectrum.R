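test_that("variation categories are symmetric and partition the base pairs", {
  expect_equal(categorizeVariation(c("C", "T"))$category, "CT")
  expect_equal(categorizeVariation(c("T", "C"))$category, "CT")
  expect_equal(categorizeVariation(c("C", "T"))$family, "transition")
  expect_equal(categorizeVariation(c("G", "T"))$category, "TG")
  expect_equal(categorizeVariation(c("G", "T"))$family, "transversion")
  expect_equal(categorizeVariation(c("A", "GAP"))$category, "A_GAP")
  expect_equal(categorizeVariation(c("A", "GAP"))$family, "indel")
  expect_error(categorizeVariation(c("A", "C", "G")), "categorization error")

  pairs <- combn(c("A", "C", "G", "T"), 2)
  cats <- apply(pairs, 2, function(p) categorizeVariation(p)$category)
  expect_setequal(cats, c("CT", "GA", "CG", "AT", "CA", "TG"))
  expect_equal(anyDuplicated(cats), 0L)
  fams <- apply(pairs, 2, function(p) categorizeVariation(p)$family)
  expect_equal(sum(fams == "transition"), 2L)
  expect_equal(sum(fams == "transversion"), 4L)
})

test_that("spectrum counts, percentages and aggregates are consistent", {
  one <- data.frame(cluster_id = "c", position = 1L, kind = "substitution",
                    alleles = "C,T", reliable_alleles = "C,T", reliable = TRUE,
                    stringsAsFactors = FALSE)
  s <- computeSpectrum(one)
  expect_equal(s$table$percent[s$table$category == "CT"], 100)
  expect_equal(s$aggregates$percent[s$aggregates$family == "transition"], 100)

  ten <- data.frame(
    cluster_id = "c", position = 1:10,
    kind = c(rep("substitution", 6), rep("indel", 4)),
    alleles = c("C,T", "A,G", "C,G", "A,T", "A,C", "G,T",
                "A,GAP", "C,GAP", "G,GAP", "GAP,T"),
    reliable_alleles = NA, reliable = TRUE, stringsAsFactors = FALSE)
  s <- computeSpectrum(ten)
  expect_true(all(s$table$count == 1))
  expect_true(all(s$table$percent == 10))
  expect_equal(s$aggregates$percent[s$aggregates$family == "transition"], 20)
  expect_equal(s$grand_total, 10)
  # aggregates always sum exactly to the grand total
  expect_equal(sum(s$aggregates$count[s$aggregates$family != "total"]),
               s$grand_total)
  expect_equal(sum(s$sixKinds$count), s$grand_total)

  empty <- computeSpectrum(ten[0, ])
  expect_true(empty$empty)
  expect_equal(empty$grand_total, 0)
  expect_true(all(empty$table$percent == 0))

  expect_error(computeSpectrum(data.frame(kind = "complex", alleles = "A,C,G")),
               "complex")
})

test_that("aggregate identity holds over random spectra", {
  set.seed(61)
  cats <- c("CT", "GA", "CG", "AT", "CA", "TG",
            "A_GAP", "C_GAP", "G_GAP", "T_GAP")
  for (i in 1:10) {
    counts <- stats::setNames(rpois(10, lambda = sample(1:50, 1)), cats)
    s <- spectrumFromCounts(counts)
    expect_equal(sum(s$aggregates$count[s$aggregates$family != "total"]),
                 s$grand_total)
    expect_equal(s$grand_total, sum(counts))
    if (s$grand_total > 0)
      expect_lt(abs(sum(s$table$percent) - 100), 0.05 * 10)
  }
})

test_that("SNPs per gene aggregates multi-category genes", {
  counts <- c(g1 = 300, g2 = 35, g3 = 12)
  cats <- data.frame(gene = c("g1", "g2", "g1", "g3"),
                     category = c("cellular component", "cellular component",
                                  "biological process", "biological process"),
                     stringsAsFactors = FALSE)
  out <- snpsPerGene(counts, cats)
  cc <- out[out$category == "cellular component", ]
  expect_equal(cc$n_genes, 2)
  expect_equal(cc$n_snps, 335)
  expect_equal(cc$snps_per_gene, 167.5)
  bp <- out[out$category == "biological process", ]
  expect_equal(bp$n_snps, 312)

  expect_equal(snpsPerGene(c(g = 0), data.frame(gene = "g", category = "x"))$
                 snps_per_gene, 0)
  expect_warning(out <- snpsPerGene(counts,
                                    rbind(cats, data.frame(gene = "ghost",
                                                           category = "x"))),
                 "ghost")
  expect_false("x" %in% out$category)
})

test_that("panel rates validate inputs and recompute rolled-up rates", {
  out <- panelRates(data.frame(class = "all", subclass = "all",
                               tested = 1349, polymorphic = 137, loci = 142))
  expect_equal(out$rate_pct[out$subclass == "all"], 10.16)
  zero <- panelRates(data.frame(class = "x", subclass = "x",
                                tested = 10, polymorphic = 0, loci = 0))
  expect_equal(zero$rate_pct[1], 0)
  expect_error(panelRates(data.frame(class = "x", subclass = "x", tested = 5,
                                     polymorphic = 6, loci = 6)),
               "data error")
  expect_error(panelRates(data.frame(class = "x", subclass = "x", tested = 0,
                                     polymorphic = 0, loci = 0)),
               "data error")
})

test_that("map summary recomputes intervals from aggregated loci", {
  out <- mapSummary(data.frame(chromosome = "Chr01", genome = "A",
                               length_cM = 100, n_loci = 100))
  expect_equal(out$interval_cM[out$chromosome == "Chr01"], 1)
  two <- mapSummary(data.frame(chromosome = c("c1", "c2"), genome = "A",
                               length_cM = c(120, 80), n_loci = c(30, 20)))
  gen <- two[two$chromosome == "genome", ]
  expect_equal(gen$length_cM, 200)
  expect_equal(gen$n_loci, 50)
  expect_equal(gen$interval_cM, 4)
  expect_error(mapSummary(data.frame(chromosome = "c", genome = "A",
                                     length_cM = 10, n_loci = 0)),
               "data error")
})

test_that("half-up rounding differs from banker's rounding where it matters", {
  expect_equal(roundHalfUp(0.125, 2), 0.13)
  expect_equal(roundHalfUp(0.135, 2), 0.14)
  expect_equal(roundHalfUp(-0.125, 2), -0.13)
  expect_equal(roundHalfUp(2.675, 2), 2.68)
})
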