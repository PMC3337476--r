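#' Generate an i.i.d. random genome
#'
#' Bases are drawn independently with `P(G) = P(C) = p/2` and
#' `P(A) = P(T) = (1 - p)/2`, giving a genome whose expected G+C fraction
#' is exactly `p`.
#'
#' @param length genome length in bp (>= 1).
#' @param p target G+C fraction in (0, 1\], or exactly 1 for an all-G/C
#'   genome.
#' @param seed RNG seed.
#' @param topology passed to [genome()].
#' @return a [Genome-class].
#' @export
makeGenome <- function(length, p = 0.508, seed = NULL,
                       topology = c("linear", "circular")) {
  stopifnot(length >= 1, p >= 0, p <= 1)
  topology <- match.arg(topology)
  probs <- c((1 - p) / 2, p / 2, p / 2, (1 - p) / 2)
  seqc <- withSeed(seed,
    paste(sample(BASES, length, replace = TRUE, prob = probs),
          collapse = ""))
  genome(seqc, id = sprintf("synthetic_gc%.3f", p), topology = topology)
}

#' Generate a random codon usage table
#'
#' Within each synonymous family, usage fractions are drawn from a
#' symmetric Dirichlet; small `concentration` gives strongly biased
#' families (one codon dominating, emulating a translationally selected
#' usage pattern), large values approach uniform usage.
#'
#' @param seed RNG seed.
#' @param concentration Dirichlet concentration per codon (default 0.5,
#'   strongly biased).
#' @return a [CodonUsageTable-class].
#' @export
makeUsageTable <- function(seed = NULL, concentration = 0.5) {
  stopifnot(concentration > 0)
  senses <- senseCodons()
  freq <- withSeed(seed, {
    x <- rgamma(length(senses), shape = concentration, rate = 1)
    x + 1e-6          # keep every codon representable
  })
  codonUsageTable(setNames(freq, senses))
}

#' Generate usage-biased coding genes on a synthetic genome
#'
#' Each gene is `ATG`, then `lengthCodons - 2` internal codons (amino acid
#' uniform over the 20, codon within the family proportional to its usage
#' fraction), then `TAA`. Genes are placed on alternating random strands
#' separated by i.i.d. spacers, and the assembled sequence is returned as
#' a genome together with a coordinate/strand annotation table.
#'
#' @param nGenes number of genes.
#' @param lengthCodons codons per gene including start and stop (>= 3).
#' @param usageTable a [CodonUsageTable-class].
#' @param seed RNG seed.
#' @param spacer intergenic spacer length in bp.
#' @param spacerGC G+C fraction of spacers.
#' @return list with `genome` ([Genome-class]) and `genes` (data.frame
#'   `gene`, `start`, `end`, `strand`).
#' @export
makeGenes <- function(nGenes, lengthCodons, usageTable, seed = NULL,
                      spacer = 20L, spacerGC = 0.5) {
  stopifnot(nGenes >= 1, lengthCodons >= 3, is(usageTable, "CodonUsageTable"))
  aaOf <- usageTable@aminoAcid
  fams <- split(names(aaOf), aaOf)
  withSeed(seed, {
    spacerSeq <- function()
      paste(sample(BASES, spacer, replace = TRUE,
                   prob = c((1 - spacerGC) / 2, spacerGC / 2,
                            spacerGC / 2, (1 - spacerGC) / 2)),
            collapse = "")
    pieces <- character()
    genes <- vector("list", nGenes)
    at <- 0L
    for (i in seq_len(nGenes)) {
      sp <- spacerSeq()
      pieces <- c(pieces, sp)
      at <- at + nchar(sp)
      aas <- sample(names(fams), lengthCodons - 2L, replace = TRUE)
      internal <- vapply(aas, function(a) {
        cods <- fams[[a]]
        if (length(cods) == 1L) cods
        else sample(cods, 1L, prob = usageTable@familyFraction[cods])
      }, character(1))
      cds <- paste(c("ATG", internal, "TAA"), collapse = "")
      strand <- sample(c("+", "-"), 1L)
      placed <- if (strand == "+") cds
                else as.character(reverseComplement(DNAString(cds)))
      pieces <- c(pieces, placed)
      genes[[i]] <- data.frame(gene = sprintf("gene%03d", i),
                               start = at + 1L,
                               end = at + nchar(cds),
                               strand = strand)
      at <- at + nchar(cds)
    }
    pieces <- c(pieces, spacerSeq())
    list(genome = genome(paste(pieces, collapse = ""), id = "synthetic_genes"),
         genes = do.call(rbind, genes))
  })
}

## alt base for a given ref base under a strand-collapsed class
altForClass <- function(ref, class) {
  pur <- if (ref %in% c("G", "C")) "G" else "A"      # purine representative
  target <- switch(paste(pur, class),
    "G GC>AT" = "A", "G GC>TA" = "T", "G GC>CG" = "C",
    "A AT>GC" = "G", "A AT>CG" = "C", "A AT>TA" = "T",
    stop("class ", class, " incompatible with ref ", ref))
  if (ref == pur) target else complementBase(target)
}

#' Plant mutations with a controllable spectrum and flanking-G/C effect
#'
#' Samples `n` distinct sites with probability proportional to
#' `exp(beta * c(site))`, where `c` is the number of G/C bases in the
#' `+/-flank` window around the site (centre excluded), then draws each
#' alternate base from `spectrumProbs` conditioned on the reference base
#' pair at the site. `beta = 0` gives uniformly distributed sites (the
#' null of the context G test); `beta > 0` plants the G/C-rich-context
#' hypermutability alternative. Only sites with a complete window are
#' eligible on a linear genome; on a circular genome the window wraps.
#'
#' @param genome a [Genome-class].
#' @param n number of mutations (>= 1, at most the number of eligible
#'   sites).
#' @param spectrumProbs named probabilities over [SUBSTITUTION_CLASSES]
#'   summing to 1; default uniform.
#' @param beta flanking-G/C enrichment strength (default 0).
#' @param flank window half-width used for `c(site)` (default 5).
#' @param seed RNG seed.
#' @return mutation table (data.frame `id`, `position`, `ref`, `alt`)
#'   that validates against `genome` by construction.
#' @export
plantMutations <- function(genome, n, spectrumProbs = NULL, beta = 0,
                           flank = 5L, seed = NULL) {
  stopifnot(is(genome, "Genome"), n >= 1)
  if (is.null(spectrumProbs))
    spectrumProbs <- setNames(rep(1 / 6, 6), SUBSTITUTION_CLASSES)
  if (!setequal(names(spectrumProbs), SUBSTITUTION_CLASSES))
    stop("spectrumProbs must be named by the six substitution classes")
  spectrumProbs <- spectrumProbs[SUBSTITUTION_CLASSES]
  if (abs(sum(spectrumProbs) - 1) > 1e-9)
    stop("spectrumProbs must sum to 1")
  L <- length(genome)
  s <- as.character(genomeSeq(genome))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  isGC <- as.numeric(chars %in% c("G", "C"))
  w <- 2L * as.integer(flank) + 1L
  circular <- genomeTopology(genome) == "circular"
  if (circular) {
    ext <- c(utils::tail(isGC, flank), isGC, utils::head(isGC, flank))
    winsum <- as.numeric(stats::filter(ext, rep(1, w), sides = 2))
    winsum <- winsum[(flank + 1):(flank + L)]
    eligible <- seq_len(L)
  } else {
    winsum <- as.numeric(stats::filter(isGC, rep(1, w), sides = 2))
    eligible <- which(!is.na(winsum))
  }
  cOf <- winsum[eligible] - isGC[eligible]   # centre excluded
  ## drop sites whose ref pair has zero class mass
  gcMass <- sum(spectrumProbs[c("GC>AT", "GC>TA", "GC>CG")])
  atMass <- sum(spectrumProbs[c("AT>GC", "AT>CG", "AT>TA")])
  refGC <- isGC[eligible] == 1
  keep <- (refGC & gcMass > 0) | (!refGC & atMass > 0)
  eligible <- eligible[keep]; cOf <- cOf[keep]
  if (length(eligible) < n) stop("not enough eligible sites")
  withSeed(seed, {
    sites <- sort(sample(eligible, n, prob = exp(beta * cOf)))
    ref <- chars[sites]
    alt <- vapply(ref, function(r) {
      cls <- if (r %in% c("G", "C")) c("GC>AT", "GC>TA", "GC>CG")
             else c("AT>GC", "AT>CG", "AT>TA")
      pr <- spectrumProbs[cls]
      drawn <- sample(cls, 1L, prob = pr)
      altForClass(r, drawn)
    }, character(1))
    data.frame(id = sprintf("mut%04d", seq_len(n)),
               position = sites, ref = ref, alt = unname(alt))
  })
}

#' Simulate per-line mutation-accumulation counts
#'
#' Independent Poisson draws with mean `ratePerGenome * generations` per
#' line: the number of substitutions a line accumulates when mutations
#' arrive as a Poisson process along its pedigree.
#'
#' @param ratePerGenome per genome per generation.
#' @param generations generations per line.
#' @param nLines number of parallel lines.
#' @param seed RNG seed.
#' @return integer vector of per-line counts.
#' @export
simulateMACounts <- function(ratePerGenome, generations, nLines,
                             seed = NULL) {
  stopifnot(ratePerGenome >= 0, generations >= 0, nLines >= 1)
  withSeed(seed, rpois(nLines, ratePerGenome * generations))
}
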