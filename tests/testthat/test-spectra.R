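test_that("substitution collapse is strand-symmetric over all 12 ordered pairs", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pairs <- expand.grid(ref = names(comp), alt = names(comp),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  expect_equal(nrow(pairs), 12L)
  for (i in seq_len(nrow(pairs))) {
    cls <- collapseSubstitution(pairs$ref[i], pairs$alt[i])
    expect_true(cls %in% SUBSTITUTION_CLASSES)
    expect_identical(
      cls, collapseSubstitution(comp[pairs$ref[i]], comp[pairs$alt[i]]))
  }
  expect_identical(collapseSubstitution("G", "A"), "GC>AT")
  expect_identical(collapseSubstitution("C", "T"), "GC>AT")
  expect_identical(collapseSubstitution("A", "T"), "AT>TA")
  expect_true(isTransition("GC>AT"))
  expect_true(isTransition("AT>GC"))
  expect_false(any(isTransition(c("GC>TA", "GC>CG", "AT>CG", "AT>TA"))))
  expect_error(collapseSubstitution("G", "G"), "differ")
})

test_that("spectrum summaries conserve counts and ignore input order", {
  empty <- summarizeSpectrum(toyMutation()[0, ])
  expect_equal(nTotal(empty), 0L)
  expect_true(all(spectrumCounts(empty) == 0))

  g <- makeGenome(50000, 0.5, seed = 31)
  probs <- c(`GC>AT` = 0.4, `GC>TA` = 0.1, `GC>CG` = 0.05,
             `AT>GC` = 0.25, `AT>CG` = 0.05, `AT>TA` = 0.15)
  tab <- plantMutations(g, 1000, spectrumProbs = probs, seed = 32)
  sp <- summarizeSpectrum(tab)
  expect_equal(nTotal(sp), 1000L)
  expect_equal(sum(spectrumCounts(sp)), nTotal(sp))
  expect_equal(gcToWeakCount(sp),
               sum(spectrumCounts(sp)[c("GC>AT", "GC>TA")]))

  shuffled <- tab[sample(nrow(tab)), ]
  expect_identical(spectrumCounts(summarizeSpectrum(shuffled)),
                   spectrumCounts(sp))

  # class draws are conditioned on the ref pair: within each pair group the
  # counts are multinomial with the renormalised probabilities (3 sigma)
  nGC <- gcToWeakCount(sp) + spectrumCounts(sp)["GC>CG"]
  pGC <- probs[c("GC>AT", "GC>TA", "GC>CG")] / sum(probs[1:3])
  for (cl in names(pGC)) {
    expect_lt(abs(spectrumCounts(sp)[cl] - nGC * pGC[cl]),
              3 * sqrt(nGC * pGC[cl] * (1 - pGC[cl])) + 1e-9)
  }
})

test_that("codon changes classify by the standard bacterial code", {
  expect_identical(changeStatus(codonChange("GAA", "GAG")), "synonymous")
  expect_identical(changeStatus(codonChange("TGG", "TGA")), "nonsense")
  expect_identical(changeStatus(codonChange("AAA", "GAA")), "missense")
  expect_error(codonChange("AAA", "GGA"), "exactly one site")
})

test_that("status partition over all 549 single-base codon changes matches seqinr", {
  senses <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  statuses <- character(0)
  oracle <- character(0)
  for (cod in senses) {
    for (i in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substring(cod, i, i))) {
        after <- cod
        substring(after, i, i) <- b
        statuses <- c(statuses, changeStatus(codonChange(cod, after)))
        aaB <- seqinr::translate(strsplit(cod, "")[[1]])
        aaA <- seqinr::translate(strsplit(after, "")[[1]])
        oracle <- c(oracle,
                    if (aaA == aaB && aaB != "*") "synonymous"
                    else if (aaA == "*") "nonsense" else "missense")
      }
    }
  }
  expect_length(statuses, 549L)
  expect_identical(statuses, oracle)
})

test_that("coding-strand codons are read correctly on both strands", {
  # + strand: gene ATG GAA TAA at 3..11 of a 13 bp genome
  g <- genome("TTATGGAATAATT")
  gene <- data.frame(gene = "g1", start = 3L, end = 11L, strand = "+")
  cc <- codonChangeOf(list(position = 8L, ref = "A", alt = "G"), g, gene)
  expect_identical(codonBefore(cc), "GAA")
  expect_identical(codonAfter(cc), "GAG")
  expect_identical(changeStatus(cc), "synonymous")

  # - strand: same CDS reverse-complemented; forward C>T at the position
  # pairing with the GAA third base reads as the same GAA>GAG change
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGGAATAA")))
  g2 <- genome(paste0("TT", rc, "TT"))
  gene2 <- data.frame(gene = "g1", start = 3L, end = 11L, strand = "-")
  # coding offset of the GAA third base is 5 -> forward position end - 5
  pos <- 11L - 5L
  expect_identical(baseAt(g2, pos), "T")
  cc2 <- codonChangeOf(list(position = pos, ref = "T", alt = "C"), g2, gene2)
  expect_identical(codonBefore(cc2), "GAA")
  expect_identical(codonAfter(cc2), "GAG")

  expect_error(codonChangeOf(list(position = 1L, ref = "T", alt = "C"),
                             g, gene), "outside|contained")
})

test_that("usage vectors follow the ratio band and are antisymmetric", {
  freq <- setNames(rep(1, 61), names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"])
  freq["AAA"] <- 3; freq["AAG"] <- 1      # Lys family fractions 0.75/0.25
  tab <- codonUsageTable(freq)
  down <- usageVector(codonChange("AAA", "AAG"), tab, rho = 1.5)
  up <- usageVector(codonChange("AAG", "AAA"), tab, rho = 1.5)
  expect_identical(down, "down")
  expect_identical(up, "up")
  # equal fractions are 'similar' for any rho > 1
  for (rho in c(1.01, 1.5, 5)) {
    expect_identical(usageVector(codonChange("GGT", "GGC"),
                                 uniformUsageTable(), rho = rho), "similar")
  }
  # non-synonymous input rejected
  expect_error(usageVector(codonChange("AAA", "GAA"), tab), "synonymous")

  # antisymmetry across random biased tables and synonymous pairs
  tab2 <- makeUsageTable(seed = 33)
  syn <- list(c("CTG", "CTA"), c("GCT", "GCC"), c("CGT", "CGC"),
              c("ACA", "ACG"), c("TCT", "TCC"))
  for (pr in syn) {
    fwd <- usageVector(codonChange(pr[1], pr[2]), tab2)
    rev <- usageVector(codonChange(pr[2], pr[1]), tab2)
    expect_identical(fwd == "down", rev == "up")
    expect_identical(fwd == "similar", rev == "similar")
  }
})

test_that("exact binomial composition test matches enumeration oracles", {
  # centred observation -> 1 under the doubling convention
  expect_equal(gcCompositionTest(5, 10, 0.5), 1)
  expect_equal(gcCompositionTest(0, 10, 0.5), 2 * 0.5^10)
  # regional G+C vs genomic expectation (lacI-sized problem)
  expect_equal(gcCompositionTest(610, 1083, 0.508),
               enumBinomTwoTail(610, 1083, 0.508), tolerance = 1e-12)
  expect_equal(gcCompositionTest(610, 1083, 0.508), 3.040333e-4,
               tolerance = 1e-6)
  expect_equal(gcCompositionTest(610, 1083, 0.508, method = "minlike"),
               enumBinomTwoTail(610, 1083, 0.508, "minlike"),
               tolerance = 1e-12)
  # a small case enumerable by hand-checked summation
  expect_equal(gcCompositionTest(18, 23, 0.508),
               enumBinomTwoTail(18, 23, 0.508), tolerance = 1e-12)
})
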