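translateCodon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[toupper(codon)]
  if (any(is.na(aa))) stop("not a codon: ", paste(codon[is.na(aa)], collapse = ", "))
  unname(aa)
}

#' Construct a codon change
#'
#' Classifies a single-base codon change under the standard bacterial
#' genetic code: synonymous iff the amino acid is unchanged and neither
#' codon is a stop; nonsense iff the change creates a stop; missense
#' otherwise.
#'
#' @param codonBefore,codonAfter trinucleotides (coding strand) differing
#'   at exactly one position.
#' @return a [CodonChange-class].
#' @examples
#' changeStatus(codonChange("GAA", "GAG"))  # synonymous
#' changeStatus(codonChange("TGG", "TGA"))  # nonsense
#' @export
codonChange <- function(codonBefore, codonAfter) {
  codonBefore <- toupper(codonBefore); codonAfter <- toupper(codonAfter)
  stopifnot(nchar(codonBefore) == 3L, nchar(codonAfter) == 3L)
  ndiff <- sum(strsplit(codonBefore, "")[[1L]] != strsplit(codonAfter, "")[[1L]])
  if (ndiff != 1L)
    stop("codons must differ at exactly one site (got ", ndiff, ")")
  aaB <- translateCodon(codonBefore)
  aaA <- translateCodon(codonAfter)
  status <- if (aaB == aaA && aaB != "*") "synonymous"
            else if (aaA == "*" && aaB != "*") "nonsense"
            else "missense"
  new("CodonChange", codonBefore = codonBefore, codonAfter = codonAfter,
      aaBefore = aaB, aaAfter = aaA, status = status)
}

#' CodonChange accessors
#'
#' @param x a [CodonChange-class].
#' @return character(1).
#' @export
changeStatus <- function(x) { stopifnot(is(x, "CodonChange")); x@status }

#' @rdname changeStatus
#' @export
codonBefore <- function(x) { stopifnot(is(x, "CodonChange")); x@codonBefore }

#' @rdname changeStatus
#' @export
codonAfter <- function(x) { stopifnot(is(x, "CodonChange")); x@codonAfter }

setMethod("show", "CodonChange", function(object) {
  cat(sprintf("CodonChange %s(%s) -> %s(%s): %s\n",
              object@codonBefore, object@aaBefore,
              object@codonAfter, object@aaAfter, object@status))
})

#' Codon change implied by a genomic substitution
#'
#' Locates the codon containing a mutated position inside an annotated
#' gene, reads both codons in coding orientation (reverse-complemented for
#' minus-strand genes) and classifies the change. The gene annotation is a
#' one-row data.frame (or list) with `start`, `end` (1-based inclusive
#' forward-strand coordinates of the coding span, whose length must be a
#' multiple of 3) and `strand` (`"+"` or `"-"`).
#'
#' @param record one mutation record (one-row data.frame or list with
#'   `position`, `ref`, `alt`).
#' @param genome a [Genome-class].
#' @param gene gene annotation as above; when a multi-row `genes` table is
#'   given, the row whose span contains the position is used.
#' @return a [CodonChange-class].
#' @export
codonChangeOf <- function(record, genome, gene) {
  stopifnot(is(genome, "Genome"))
  pos <- as.integer(record$position)
  ref <- toupper(record$ref); alt <- toupper(record$alt)
  if (is.data.frame(gene) && nrow(gene) > 1L) {
    hit <- which(gene$start <= pos & gene$end >= pos)
    if (length(hit) != 1L)
      stop("position ", pos, " contained in ", length(hit), " gene spans")
    gene <- gene[hit, ]
  }
  start <- as.integer(gene$start); end <- as.integer(gene$end)
  strand <- as.character(gene$strand)
  if (pos < start || pos > end)
    stop("position ", pos, " outside gene span ", start, "-", end)
  if ((end - start + 1L) %% 3L != 0L)
    stop("coding span length is not a multiple of 3")
  if (baseAt(genome, pos) != ref)
    stop("genome base at ", pos, " is not the stated ref base")
  s <- as.character(genomeSeq(genome))
  if (strand == "+") {
    off <- pos - start
    cstart <- start + 3L * (off %/% 3L)
    fwd <- substring(s, cstart, cstart + 2L)
    within <- off %% 3L + 1L
    before <- fwd
    refCoding <- ref; altCoding <- alt
  } else if (strand == "-") {
    off <- end - pos
    cend <- end - 3L * (off %/% 3L)
    fwd <- substring(s, cend - 2L, cend)
    before <- as.character(reverseComplement(DNAString(fwd)))
    within <- off %% 3L + 1L
    refCoding <- complementBase(ref); altCoding <- complementBase(alt)
  } else stop("strand must be '+' or '-'")
  if (grepl("N", before, fixed = TRUE))
    stop("codon contains a masked base")
  if (substring(before, within, within) != refCoding)
    stop("internal frame inconsistency at position ", pos)
  after <- before
  substring(after, within, within) <- altCoding
  codonChange(before, after)
}

#' Codon-usage vector of a synonymous change
#'
#' Direction of a synonymous codon switch relative to usage frequencies:
#' `"down"` when the source codon is used more than `rho` times as often as
#' the target (within the synonymous family), `"up"` for the reverse, and
#' `"similar"` inside the band. The band factor `rho` (> 1) operationalises
#' "similarly often used"; the default 1.5 treats up to 1.5-fold usage
#' differences as similar.
#'
#' @param change a [CodonChange-class] with synonymous status.
#' @param table a [CodonUsageTable-class].
#' @param rho band factor > 1.
#' @return `"down"`, `"similar"` or `"up"`.
#' @examples
#' usageVector(codonChange("GGT", "GGC"), uniformUsageTable())  # "similar"
#' @export
usageVector <- function(change, table, rho = 1.5) {
  stopifnot(is(change, "CodonChange"), is(table, "CodonUsageTable"), rho > 1)
  if (change@status != "synonymous")
    stop("usage vector is defined only for synonymous changes (got ",
         change@status, ")")
  uB <- usageFraction(table, change@codonBefore)
  uA <- usageFraction(table, change@codonAfter)
  if (uB > rho * uA) "down" else if (uA > rho * uB) "up" else "similar"
}

#' Exact two-tailed binomial composition test
#'
#' Tests an observed G/C count against an expected proportion with the
#' exact binomial distribution. The default `"doubling"` convention doubles
#' the smaller one-sided tail and caps at 1; `"minlike"` sums all outcomes
#' no more likely than the observed one (the [stats::binom.test()]
#' convention).
#'
#' @param observed observed count (e.g. G+C bases) in `[0, n]`.
#' @param n number of trials (e.g. bp examined).
#' @param p null proportion, strictly inside (0, 1).
#' @param method `"doubling"` (default) or `"minlike"`.
#' @return two-tailed P value.
#' @examples
#' gcCompositionTest(610, 1083, 0.508)  # ~3e-4
#' @export
gcCompositionTest <- function(observed, n, p,
                              method = c("doubling", "minlike")) {
  method <- match.arg(method)
  stopifnot(observed >= 0, observed <= n, p > 0, p < 1)
  if (method == "minlike")
    return(binom.test(observed, n, p)$p.value)
  lower <- pbinom(observed, n, p)
  upper <- pbinom(observed - 1, n, p, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}
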