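#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Genome: a validated nucleotide sequence with topology
#'
#' Thin S4 wrapper around a [Biostrings::DNAString] carrying an identifier
#' and a topology flag. On construction the sequence is upper-cased and
#' checked to contain only A/C/G/T (ambiguity codes are rejected, or masked
#' to `N` when `mask = TRUE`; masked positions are excluded from downstream
#' context windows).
#'
#' @slot id character(1) sequence label.
#' @slot sequence a `DNAString`.
#' @slot topology `"linear"` or `"circular"`; governs whether flanking
#'   windows near the ends wrap around.
#' @aliases Genome
#' @exportClass Genome
setClass("Genome",
  representation(id = "character", sequence = "DNAString",
                 topology = "character"))

setValidity("Genome", function(object) {
  msg <- character()
  if (length(object@id) != 1L) msg <- c(msg, "'id' must be length 1")
  if (!object@topology %in% c("linear", "circular"))
    msg <- c(msg, "'topology' must be 'linear' or 'circular'")
  freq <- Biostrings::alphabetFrequency(object@sequence)
  bad <- sum(freq) - sum(freq[c(BASES, "N")])
  if (bad > 0) msg <- c(msg, "sequence contains letters outside A/C/G/T/N")
  if (length(msg)) msg else TRUE
})

#' CodonUsageTable: codon frequencies and within-family fractions
#'
#' Holds one non-negative usage frequency per sense codon (per-thousand or
#' relative; the scale is immaterial) together with the derived
#' within-synonymous-family fractions, which sum to one inside each family
#' of the standard bacterial genetic code.
#'
#' @slot frequency named numeric(61), one entry per sense codon.
#' @slot familyFraction named numeric(61), usage fraction within each
#'   synonymous family; sums to 1 per family.
#' @slot aminoAcid named character(61), one-letter amino acid per codon.
#' @aliases CodonUsageTable
#' @exportClass CodonUsageTable
setClass("CodonUsageTable",
  representation(frequency = "numeric", familyFraction = "numeric",
                 aminoAcid = "character"))

setValidity("CodonUsageTable", function(object) {
  msg <- character()
  senses <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  if (!setequal(names(object@frequency), senses))
    msg <- c(msg, "all 61 sense codons must be present exactly once")
  if (any(object@frequency < 0)) msg <- c(msg, "frequencies must be >= 0")
  fam <- split(object@familyFraction, object@aminoAcid[names(object@familyFraction)])
  bad <- vapply(fam, function(x) abs(sum(x) - 1) > 1e-9, logical(1))
  if (any(bad))
    msg <- c(msg, paste("family fractions do not sum to 1 for:",
                        paste(names(fam)[bad], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' RateEstimate: a point mutation-rate estimate
#'
#' @slot numMutations non-negative mutation count m.
#' @slot generations cumulative generations G (> 0).
#' @slot sites number of target sites L in bp (> 0).
#' @slot rate m / (G * L), per bp per generation, kept at full precision.
#' @aliases RateEstimate
#' @exportClass RateEstimate
setClass("RateEstimate",
  representation(numMutations = "numeric", generations = "numeric",
                 sites = "numeric", rate = "numeric"))

setValidity("RateEstimate", function(object) {
  if (!isTRUE(all.equal(object@rate,
                        object@numMutations / (object@generations * object@sites))))
    "rate must equal m / (generations * sites)" else TRUE
})

#' GenomeRate: a per-bp rate scaled to a whole genome
#'
#' @slot ratePerBp per bp per generation.
#' @slot genomeSize genome length in bp.
#' @slot ratePerGenome ratePerBp * genomeSize, per genome per generation.
#' @aliases GenomeRate
#' @exportClass GenomeRate
setClass("GenomeRate",
  representation(ratePerBp = "numeric", genomeSize = "numeric",
                 ratePerGenome = "numeric"))

#' ExpectedCounts: expected substitution-class counts over an experiment
#'
#' @slot generations duration T of the experiment.
#' @slot genomeRate per genome per generation.
#' @slot codingFraction fraction of substitutions hitting coding sequence.
#' @slot synonymousFraction fraction of coding substitutions that are
#'   synonymous.
#' @slot total,coding,synonymous the chained expected counts.
#' @aliases ExpectedCounts
#' @exportClass ExpectedCounts
setClass("ExpectedCounts",
  representation(generations = "numeric", genomeRate = "numeric",
                 codingFraction = "numeric", synonymousFraction = "numeric",
                 total = "numeric", coding = "numeric", synonymous = "numeric"))

#' SpectrumSummary: counts per strand-collapsed substitution class
#'
#' @slot counts named integer(6) over the classes
#'   `GC>AT, GC>TA, GC>CG, AT>GC, AT>CG, AT>TA`.
#' @aliases SpectrumSummary
#' @exportClass SpectrumSummary
setClass("SpectrumSummary", representation(counts = "integer"))

setValidity("SpectrumSummary", function(object) {
  if (!identical(names(object@counts), SUBSTITUTION_CLASSES))
    "counts must be named by the six substitution classes"
  else if (any(object@counts < 0)) "counts must be non-negative" else TRUE
})

#' CodonChange: a single-base codon change and its coding consequence
#'
#' @slot codonBefore,codonAfter trinucleotides on the coding strand,
#'   differing at exactly one site.
#' @slot aaBefore,aaAfter one-letter amino acids (`*` = stop).
#' @slot status `"synonymous"`, `"missense"` or `"nonsense"`.
#' @aliases CodonChange
#' @exportClass CodonChange
setClass("CodonChange",
  representation(codonBefore = "character", codonAfter = "character",
                 aaBefore = "character", aaAfter = "character",
                 status = "character"))

#' ContextProfile: per-offset G/C counts around mutated sites
#'
#' For each offset -flank..+flank the number of contributing mutations whose
#' genome base at that offset is G or C. Offset 0 uses the pre-mutation
#' (reference) base. On a linear genome, records whose window would run off
#' an end are skipped (kept in `skipped`) so that n is constant across
#' offsets; on a circular genome the window wraps.
#'
#' @slot offsets integer vector -flank..+flank.
#' @slot counts named numeric, per-offset G/C counts, each in `[0, n]`.
#' @slot n number of mutations contributing.
#' @slot p expected G/C proportion for the region the mutations come from.
#' @slot flank window half-width in bp.
#' @slot skipped ids of records excluded for boundary or masked-base reasons.
#' @aliases ContextProfile
#' @exportClass ContextProfile
setClass("ContextProfile",
  representation(offsets = "integer", counts = "numeric", n = "integer",
                 p = "numeric", flank = "integer", skipped = "character"))

setValidity("ContextProfile", function(object) {
  msg <- character()
  if (length(object@counts) != length(object@offsets))
    msg <- c(msg, "one count per offset required")
  if (any(object@counts < 0) || any(object@counts > object@n))
    msg <- c(msg, "counts must lie in [0, n]")
  if (object@p <= 0 || object@p >= 1)
    msg <- c(msg, "p must lie strictly inside (0, 1)")
  if (length(msg)) msg else TRUE
})

#' GofDecomposition: replicated goodness-of-fit G partition
#'
#' Partition of the total G across k replicate positions into a pooled
#' component `G_P` (overall deviation from the expected proportion, 1 df)
#' and a heterogeneity component `G_H` (differences among positions, k-1
#' df), with `G_T = G_P + G_H` (k df) holding exactly by construction.
#'
#' @slot perPositionG named numeric(k), the two-class G at each position.
#' @slot GP,GH,GT the pooled, heterogeneity and total statistics.
#' @slot df named numeric, degrees of freedom for GP/GH/GT.
#' @slot pValues list with elements `perPosition`, `GP`, `GH`, `GT`
#'   (chi-square upper tails, or the chosen per-position test).
#' @slot williamsApplied logical flag.
#' @aliases GofDecomposition
#' @exportClass GofDecomposition
setClass("GofDecomposition",
  representation(perPositionG = "numeric", GP = "numeric", GH = "numeric",
                 GT = "numeric", df = "numeric", pValues = "list",
                 williamsApplied = "logical"))

setValidity("GofDecomposition", function(object) {
  k <- length(object@perPositionG)
  msg <- character()
  if (abs(object@GT - (object@GP + object@GH)) > 1e-8)
    msg <- c(msg, "GT must equal GP + GH")
  if (!identical(unname(object@df), c(1, k - 1, k)))
    msg <- c(msg, "df must be 1, k-1, k for GP, GH, GT")
  if (length(msg)) msg else TRUE
})

#' RegimeSpec: serial-transfer mutation-accumulation regime constants
#'
#' Describes a daily-passage regime: overnight growth by `growthFactor`
#' (so `log2(growthFactor)` generations per cycle) followed by a transfer
#' bottleneck of `bottleneckCells` cells.
#'
#' @slot bottleneckCells cells transferred at each bottleneck (default 5e6).
#' @slot growthFactor within-cycle fold growth (default 100, i.e. ~6.64
#'   generations per cycle).
#' @slot totalGenerations nominal experiment duration (default 40000).
#' @aliases RegimeSpec
#' @exportClass RegimeSpec
setClass("RegimeSpec",
  representation(bottleneckCells = "numeric", growthFactor = "numeric",
                 totalGenerations = "numeric"))

setValidity("RegimeSpec", function(object) {
  if (object@bottleneckCells < 1 || object@growthFactor <= 1 ||
      object@totalGenerations <= 0)
    "bottleneckCells >= 1, growthFactor > 1, totalGenerations > 0 required"
  else TRUE
})

#' SelectionEstimate: a fitted selection coefficient with its uncertainty
#'
#' @slot sHat point estimate of the per-generation selection coefficient.
#' @slot se Monte-Carlo (or regression) standard error; may be `NA`.
#' @slot replicates simulation replicates used (`NA` for regression fits).
#' @slot seed RNG seed used (`NA` when none).
#' @aliases SelectionEstimate
#' @exportClass SelectionEstimate
setClass("SelectionEstimate",
  representation(sHat = "numeric", se = "numeric", replicates = "numeric",
                 seed = "numeric"))
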