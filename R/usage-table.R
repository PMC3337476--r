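senseCodons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

#' Construct a codon usage table
#'
#' @param frequency named non-negative numeric with one entry per sense
#'   codon (61 codons, DNA alphabet). Values may be per-thousand counts or
#'   any relative scale; they are normalised internally to
#'   within-synonymous-family fractions.
#' @return a [CodonUsageTable-class].
#' @examples
#' tab <- uniformUsageTable()
#' usageFraction(tab, "AAA")  # 0.5 (Lys family has two codons)
#' @export
codonUsageTable <- function(frequency) {
  senses <- senseCodons()
  names(frequency) <- toupper(names(frequency))
  missing <- setdiff(senses, names(frequency))
  if (length(missing))
    stop("missing codon(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(frequency), senses)
  if (length(extra))
    stop("unknown or stop codon(s): ", paste(extra, collapse = ", "))
  frequency <- frequency[senses]
  aa <- Biostrings::GENETIC_CODE[senses]
  fam <- split(seq_along(senses), aa)
  frac <- frequency
  for (idx in fam) {
    tot <- sum(frequency[idx])
    if (tot <= 0)
      stop("synonymous family '", aa[idx[1L]], "' has zero total usage")
    frac[idx] <- frequency[idx] / tot
  }
  new("CodonUsageTable", frequency = frequency, familyFraction = frac,
      aminoAcid = aa)
}

#' Uniform codon usage (no bias)
#'
#' Every codon gets equal weight, so within-family fractions are 1/(family
#' size). Useful as a null table in tests.
#'
#' @return a [CodonUsageTable-class].
#' @export
uniformUsageTable <- function() {
  senses <- senseCodons()
  codonUsageTable(setNames(rep(1, length(senses)), senses))
}

#' Read a codon usage table from TSV
#'
#' Expected columns: `codon`, `aa`, `freq` (tab-separated, header line).
#' The `aa` column is checked against the standard bacterial genetic code
#' when present.
#'
#' @param path TSV file.
#' @return a [CodonUsageTable-class].
#' @export
readCodonUsageTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("codon", "freq") %in% names(tab)))
    stop("usage table needs columns 'codon' and 'freq'")
  codon <- toupper(gsub("U", "T", toupper(tab$codon)))
  if ("aa" %in% names(tab)) {
    expect <- Biostrings::GENETIC_CODE[codon]
    bad <- which(!is.na(expect) & toupper(tab$aa) != expect)
    if (length(bad))
      stop("aa column disagrees with the genetic code at row(s): ",
           paste(bad, collapse = ", "))
  }
  codonUsageTable(setNames(as.numeric(tab$freq), codon))
}

#' Usage-table accessors
#'
#' `usageFraction` returns the within-synonymous-family usage fraction of
#' one or more codons; `usageFrequency` the raw frequency as supplied.
#'
#' @param table a [CodonUsageTable-class].
#' @param codon character vector of sense codons.
#' @return numeric vector.
#' @export
usageFraction <- function(table, codon) {
  stopifnot(is(table, "CodonUsageTable"))
  codon <- toupper(codon)
  miss <- setdiff(codon, names(table@familyFraction))
  if (length(miss)) stop("codon(s) not in table: ", paste(miss, collapse = ", "))
  table@familyFraction[codon]
}

#' @rdname usageFraction
#' @export
usageFrequency <- function(table, codon) {
  stopifnot(is(table, "CodonUsageTable"))
  codon <- toupper(codon)
  miss <- setdiff(codon, names(table@frequency))
  if (length(miss)) stop("codon(s) not in table: ", paste(miss, collapse = ", "))
  table@frequency[codon]
}

setMethod("show", "CodonUsageTable", function(object) {
  cat("CodonUsageTable: 61 sense codons,",
      length(unique(object@aminoAcid)), "amino acids\n")
})
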