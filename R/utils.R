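#' @importFrom methods new validObject is setValidity show slot
#' @importFrom stats pchisq pbinom dbinom qbinom rbinom rpois runif rgamma
#'   binom.test lm coef qlogis rmultinom setNames
#' @importFrom utils read.delim write.table
NULL

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state; seed = NULL leaves the global stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

## x * log(x / e) with the 0 * log(0) = 0 convention, vectorised.
xlogxe <- function(x, e) {
  out <- numeric(length(x))
  nz <- x > 0
  out[nz] <- x[nz] * log(x[nz] / e[nz])
  out
}

complementBase <- function(x) {
  unname(COMPLEMENT[toupper(x)])
}
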