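## Shared small fixtures, all built in code.

toyGenome <- function(topology = "linear") {
  genome("ACGTAGATCGA", id = "toy", topology = topology)
}

toyMutation <- function(position = 6L, ref = "G", alt = "A", id = "m1") {
  data.frame(id = id, position = as.integer(position), ref = ref, alt = alt)
}

## Counts printed for the 23-mutation genome-wide set (flanks only, -5..+5
## with the centre removed) and the 80-mutation lacI set.
FLANK_COUNTS_23 <- c(`-5` = 16, `-4` = 10, `-3` = 16, `-2` = 18, `-1` = 15,
                     `1` = 15, `2` = 10, `3` = 13, `4` = 10, `5` = 11)
FLANK_COUNTS_LACI <- c(`-5` = 40, `-4` = 50, `-3` = 40, `-2` = 42, `-1` = 61,
                       `1` = 39, `2` = 51, `3` = 38, `4` = 33, `5` = 57)

## Independent two-class G oracle written as the plain multinomial
## 2*sum(O*log(O/E)) over both classes (different algebraic route from
## the package's xlogxe form).
oracleG <- function(O, n, p) {
  obs <- c(O, n - O); exp <- c(n * p, n * (1 - p))
  keep <- obs > 0
  2 * sum(obs[keep] * log(obs[keep] / exp[keep]))
}

## Exact two-tailed binomial by full enumeration over 0..n.
enumBinomTwoTail <- function(O, n, p, convention = c("doubling", "minlike")) {
  convention <- match.arg(convention)
  probs <- dbinom(0:n, n, p)
  if (convention == "minlike") {
    sum(probs[probs <= probs[O + 1] * (1 + 1e-7)])
  } else {
    lower <- sum(probs[0:n <= O]); upper <- sum(probs[0:n >= O])
    min(1, 2 * min(lower, upper))
  }
}
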