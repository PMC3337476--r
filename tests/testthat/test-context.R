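test_that("context windows enumerate G/C occupancy around the mutated site", {
  g <- toyGenome()
  prof <- extractContext(g, toyMutation(position = 6L), flank = 5, p = 0.508)
  # hand enumeration of ACGTAGATCGA around position 6
  expect_equal(unname(contextCounts(prof)),
               c(0, 1, 1, 0, 0, 1, 0, 0, 1, 1, 0))
  expect_equal(contextN(prof), 1L)
  expect_equal(expectedGC(prof), 0.508)

  # offset 0 uses the pre-mutation reference base, not the genome's
  # post-mutation state: a G>A mutation still counts G at the centre
  expect_equal(contextCounts(prof)[["0"]], 1)
})

test_that("boundary windows are skipped on linear genomes and wrap on circular", {
  rec <- toyMutation(position = 3L, ref = "G", alt = "A")
  expect_error(extractContext(toyGenome(), rec, flank = 5),
               "all records skipped")

  two <- rbind(rec, toyMutation(position = 6L, ref = "G", alt = "T", id = "m2"))
  prof <- extractContext(toyGenome(), two, flank = 5, p = 0.5)
  expect_equal(contextN(prof), 1L)
  expect_identical(skippedRecords(prof), "m1")

  # circular topology wraps: window of position 3 spans 9,10,11,1,2,...,8
  profC <- extractContext(toyGenome("circular"), rec, flank = 5, p = 0.5)
  expect_equal(contextN(profC), 1L)
  expect_equal(unname(contextCounts(profC)),
               c(1, 1, 0, 0, 1, 1, 0, 0, 1, 0, 0))

  # all-G/C genome saturates every offset
  gc <- genome(strrep("GC", 20))
  recs <- data.frame(id = c("a", "b"), position = c(10L, 21L),
                     ref = c("C", "G"), alt = c("T", "A"))
  profS <- extractContext(gc, recs, flank = 5, p = 0.9)
  expect_true(all(contextCounts(profS) == 2))
})

test_that("masked bases exclude the whole window", {
  g <- genome("ACGRTAGATCGAACGT", mask = TRUE)   # R -> N at position 4
  hit <- data.frame(id = c("x", "y"), position = c(8L, 11L),
                    ref = c("A", "G"), alt = c("G", "A"))
  prof <- extractContext(g, hit, flank = 5, p = 0.5)
  expect_identical(skippedRecords(prof), "x")    # window 3..13 holds the N
  expect_equal(contextN(prof), 1L)
})

test_that("two-class G matches an independent multinomial oracle", {
  expect_equal(gGof(23 * 0.5, 23, 0.5), 0)      # analytic zero at O = np
  for (case in list(c(18, 23, 0.508), c(61, 80, 0.563), c(3, 10, 0.2),
                    c(0, 12, 0.4), c(12, 12, 0.4))) {
    expect_equal(gGof(case[1], case[2], case[3]),
                 oracleG(case[1], case[2], case[3]), tolerance = 1e-12)
  }
  expect_equal(gGof(18, 23, 0.508), 7.390, tolerance = 1e-3)
  expect_equal(gGof(61, 80, 0.563), 13.83, tolerance = 1e-3)
})

test_that("replicated decomposition reproduces the printed flank statistics", {
  dec23 <- replicatedGof(FLANK_COUNTS_23, 23, 0.508)
  expect_equal(signif(heterogeneityG(dec23), 3), 14.7)
  expect_equal(unname(gofDf(dec23)), c(1, 9, 10))
  expect_equal(round(gofPValues(dec23)$GH, 4), 0.1004, tolerance = 1e-4)

  decL <- replicatedGof(FLANK_COUNTS_LACI, 80, 0.563)
  expect_equal(signif(totalG(decL), 3), 39.2)
  expect_lt(gofPValues(decL)$GT, 1e-4)
  expect_lt(gofPValues(decL)$GH, 1e-4)

  # counts exactly at n*p give identically zero statistics
  z <- replicatedGof(rep(50, 10), 100, 0.5)
  expect_equal(c(pooledG(z), heterogeneityG(z), totalG(z)), c(0, 0, 0))
})

test_that("G_T = G_P + G_H to 1e-10 and components are well-behaved", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(10:200, 1)
    p <- runif(1, 0.1, 0.9)
    k <- sample(2:12, 1)
    counts <- rbinom(k, n, runif(1, 0.1, 0.9))
    dec <- replicatedGof(counts, n, p)
    expect_lt(abs(totalG(dec) - (pooledG(dec) + heterogeneityG(dec))), 1e-10)
    # naive second route: per-position G summed independently
    expect_lt(abs(totalG(dec) -
                    sum(vapply(counts, oracleG, numeric(1), n = n, p = p))),
              1e-10)
    expect_true(all(perPositionG(dec) >= 0))
    expect_lte(pooledG(dec), totalG(dec) + 1e-12)
  }
})

test_that("chi-square tail is a survival function with the 1-df normal identity", {
  expect_equal(chiSqTail(0, 5), 1)
  expect_equal(chiSqTail(14.7, 9), 0.0995, tolerance = 5e-4)
  expect_equal(round(chiSqTail(3.84, 1), 3), 0.050)
  xs <- seq(0.2, 25, by = 0.7)
  expect_true(all(diff(chiSqTail(xs, 3)) < 0))   # strictly decreasing
  # chi2_sf(x, 1) equals the two-sided normal tail of sqrt(x)
  expect_equal(chiSqTail(xs, 1), 2 * pnorm(sqrt(xs), lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("Williams correction shrinks G by q and vanishes asymptotically", {
  q <- 1 + (2^2 - 1) / (6 * 80 * 1)
  expect_equal(q, 1.00625)
  expect_equal(williamsCorrect(7.586, 80), 7.586 / q)
  expect_equal(williamsCorrect(7.586, 80), 7.539, tolerance = 1e-3)
  expect_equal(williamsCorrect(0, 80), 0)
  expect_equal(williamsCorrect(5, 1e12), 5, tolerance = 1e-9)
})

test_that("context G analysis excludes the centre by default, optionally not", {
  g <- makeGenome(20000, 0.508, seed = 43)
  tab <- plantMutations(g, 23, seed = 44)
  prof <- extractContext(g, tab, flank = 5, p = 0.508)
  dec <- contextGof(prof)
  expect_length(perPositionG(dec), 10L)
  expect_false("0" %in% names(perPositionG(dec)))
  expect_equal(unname(gofDf(dec)), c(1, 9, 10))
  decC <- contextGof(prof, includeCenter = TRUE)
  expect_length(perPositionG(decC), 11L)
  expect_equal(unname(gofDf(decC)), c(1, 10, 11))

  # binomial per-position alternative agrees with the enumeration oracle
  decB <- contextGof(prof, perPositionTest = "binomial")
  counts <- contextCounts(prof)[names(perPositionG(decB))]
  expect_equal(unname(gofPValues(decB)$perPosition),
               unname(vapply(counts, enumBinomTwoTail, numeric(1),
                             n = 23, p = 0.508)),
               tolerance = 1e-12)
})
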