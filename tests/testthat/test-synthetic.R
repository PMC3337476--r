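test_that("random genomes hit the target base composition", {
  allGC <- makeGenome(200, 1, seed = 71)
  expect_equal(gcFraction(allGC), 1)
  g <- makeGenome(1e5, 0.508, seed = 72)
  expect_lt(abs(gcFraction(g) - 0.508),
            3 * sqrt(0.508 * 0.492 / 1e5))
  expect_identical(as.character(genomeSeq(makeGenome(500, 0.4, seed = 73))),
                   as.character(genomeSeq(makeGenome(500, 0.4, seed = 73))))
})

test_that("generated genes follow the usage table and translate cleanly", {
  # single-codon families are forced
  freq <- setNames(rep(1, 61), names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"])
  freq["AAA"] <- 3; freq["AAG"] <- 1
  tab <- codonUsageTable(freq)
  expect_equal(unname(usageFraction(tab, "ATG")), 1)   # Met family
  expect_equal(unname(usageFraction(tab, "TGG")), 1)   # Trp family

  # Lys codon draws follow the 0.75/0.25 family fractions (3 sigma)
  gen <- makeGenes(60, 102, tab, seed = 74)
  codons <- character(0)
  s <- as.character(genomeSeq(gen$genome))
  for (i in seq_len(nrow(gen$genes))) {
    gi <- gen$genes[i, ]
    cds <- substring(s, gi$start, gi$end)
    if (gi$strand == "-")
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    codons <- c(codons, substring(cds, seq(1, nchar(cds) - 2, 3),
                                  seq(3, nchar(cds), 3)))
  }
  expect_true(all(codons[seq(1, length(codons), 102)] == "ATG"))
  lys <- codons[codons %in% c("AAA", "AAG")]
  expect_gt(length(lys), 100)
  pHat <- mean(lys == "AAA")
  expect_lt(abs(pHat - 0.75), 3 * sqrt(0.75 * 0.25 / length(lys)))

  # a planted synonymous mutation is reported synonymous end to end
  gi <- gen$genes[1, ]
  # third position of the first internal codon (coding offset 5)
  pos <- if (gi$strand == "+") gi$start + 5L else gi$end - 5L
  ref <- baseAt(gen$genome, pos)
  cods <- substring(if (gi$strand == "+")
    substring(s, gi$start, gi$end) else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      substring(s, gi$start, gi$end)))), 4, 6)
  aa <- Biostrings::GENETIC_CODE[[cods]]
  fam <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
  syn <- setdiff(fam[substring(fam, 1, 2) == substring(cods, 1, 2)], cods)
  if (length(syn)) {
    altCoding <- substring(syn[1], 3, 3)
    alt <- if (gi$strand == "+") altCoding else
      chartr("ACGT", "TGCA", altCoding)
    cc <- codonChangeOf(list(position = pos, ref = ref, alt = alt),
                        gen$genome, gen$genes)
    expect_identical(changeStatus(cc), "synonymous")
  }
})

test_that("planted mutations validate and reproduce the planted spectrum", {
  g <- makeGenome(3e4, 0.508, seed = 75)
  probs <- c(`GC>AT` = 0.5, `GC>TA` = 0.2, `GC>CG` = 0.3,
             `AT>GC` = 0, `AT>CG` = 0, `AT>TA` = 0)
  probs <- probs / sum(probs)
  tab <- plantMutations(g, 400, spectrumProbs = probs, seed = 76)
  expect_equal(nrow(validateAgainstGenome(tab, g)), 400L)
  expect_true(all(tab$ref %in% c("G", "C")))   # AT classes carry no mass
  sp <- spectrumCounts(summarizeSpectrum(tab))
  for (cl in c("GC>AT", "GC>TA", "GC>CG")) {
    expect_lt(abs(sp[cl] - 400 * probs[cl]),
              3 * sqrt(400 * probs[cl] * (1 - probs[cl])))
  }

  # all-A/T genome with G/C classes zeroed still plants
  at <- genome(paste(rep("AT", 200), collapse = ""))
  atProbs <- c(`GC>AT` = 0, `GC>TA` = 0, `GC>CG` = 0,
               `AT>GC` = 0.5, `AT>CG` = 0.25, `AT>TA` = 0.25)
  tabAT <- plantMutations(at, 30, spectrumProbs = atProbs, seed = 77)
  expect_true(all(tabAT$ref %in% c("A", "T")))
})

test_that("beta = 0 places mutations uniformly over eligible sites", {
  g <- makeGenome(2e4, 0.5, seed = 78)
  tab <- plantMutations(g, 500, beta = 0, seed = 79)
  # chi-square over 10 equal-width positional bins, alpha = 0.01
  bins <- cut(tab$position, breaks = seq(0, 2e4, length.out = 11))
  pval <- suppressWarnings(chisq.test(table(bins))$p.value)
  expect_gt(pval, 0.01)
})

test_that("beta > 0 enriches G/C-rich contexts detectably", {
  g <- makeGenome(1e5, 0.5, seed = 80)
  alt <- contextGof(extractContext(
    g, plantMutations(g, 200, beta = 1, seed = 81), p = 0.5))
  nullGP <- vapply(1:11, function(i) {
    pooledG(contextGof(extractContext(
      g, plantMutations(g, 200, beta = 0, seed = 81 + i), p = 0.5)))
  }, numeric(1))
  expect_gt(pooledG(alt), median(nullGP))
  # and the planted effect is big enough to reject outright
  expect_lt(gofPValues(alt)$GP, 0.01)
})

test_that("Poisson MA counts have the planted mean and close the loop to rates", {
  expect_equal(simulateMACounts(0, 1e4, 20, seed = 82), rep(0L, 20))
  counts <- simulateMACounts(0.0025, 4e4, 1e4, seed = 83)
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 1e4))
  # end-to-end: pooled counts fed back through the rate calculus recover
  # the planted per-genome rate within 3 MC standard errors
  L <- 4629812
  nLines <- 200
  counts <- simulateMACounts(0.0025, 4e4, nLines, seed = 84)
  est <- perGenomeRate(pointRate(sum(counts), nLines * 4e4, L), L)
  se <- sqrt(sum(counts)) / (nLines * 4e4)
  expect_lt(abs(ratePerGenome(est) - 0.0025), 3 * se)
})
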