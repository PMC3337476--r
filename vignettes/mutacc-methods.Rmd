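---
title: "Methods: rate contrasts, context G-tests and selection through bottlenecks"
author: "mutacc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rate contrasts, context G-tests and selection through bottlenecks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutacc)
```

`mutacc` quantifies the gap between mutation-rate estimates from
specific-locus assays and from long-term mutation-accumulation (MA)
sequencing, and provides the statistical and simulation machinery to ask
whether purifying selection on synonymous codon usage can explain it.
This vignette records the models, their assumptions, the tunable
parameters, and the design choices made where more than one reasonable
construction existed.

## Rate calculus

A point rate is the exact quotient `m / (G · L)`: `m` observed mutations,
`G` cumulative generations (summed over parallel lines), `L` surveyed
sites in bp. Scaling by genome size gives a per-genome rate, and expected
class counts over an experiment of `T` generations are chained products
`total = rate · T`, `coding = total · f_c`, `synonymous = coding · f_s`.
All quantities are kept at full double precision; the 2-significant-figure
rounding conventional in this literature is applied only by `show()`
methods and `writeReport()`. The defaults `f_c = 0.86` (fraction of the
genome that is protein-coding) and `f_s = 0.25` (fraction of coding
substitutions that are synonymous, appropriate for a genome with roughly
equal base frequencies) are overridable arguments, not constants.

```{r rates}
r <- pointRate(25, 3e5, 941000)
perGenomeRate(r, 4629812)
expectedClassCounts(0.0025, 40000)
```

## Spectrum classes and codon-usage vectors

Because mutation and repair act on base *pairs*, single-strand changes are
collapsed into six strand-symmetric classes (`collapseSubstitution`);
`G>A` and `C>T` are the same event, `GC>AT`. The two transitions are
`GC>AT` and `AT>GC`. `summarizeSpectrum` tallies a mutation table into
these classes; counts are order-invariant and always sum to the number of
records.

Synonymous status is decided by the standard genetic code (shared by
*E. coli*; `codonChangeOf` reads codons in coding orientation, reverse-
complementing minus-strand genes). A synonymous switch gets a
**usage vector** relative to a codon-usage table: *down* when the source
codon's within-family usage fraction exceeds ρ times the target's, *up*
for the reverse, *similar* inside the band. "Similarly often used" has no
canonical definition, so it is an explicit parameter: ρ = 1.5 by default
(usage differences under 1.5-fold are treated as ties). Conclusions about
down:up ratios should be checked for stability across ρ. The usage table
itself is user-supplied — organism- and dataset-specific — and is
validated to contain all 61 sense codons with family fractions summing
to 1.

Regional composition is compared with the genome by an exact binomial
test. Two two-tailed conventions are offered: doubling the smaller tail
(capped at 1; the default, symmetric and conservative) and the "minlike"
summation of all outcomes no likelier than observed (delegated to
`binom.test`). For a lacI-sized region (609–610 G/C in 1083 bp against
p = 0.508) both conventions give P ≈ 3×10⁻⁴.

## Flanking-base context and the replicated G decomposition

`extractContext` scores the ±`flank` window (default 5) around each
mutated site for G/C occupancy per offset. Conventions, each chosen to
keep the downstream test exact:

* Offset 0 always uses the *reference* base, so the profile describes the
  pre-mutation sequence.
* On a linear genome, a record whose window would cross an end is
  **skipped entirely** (and reported), not truncated: the decomposition
  assumes the same n at every offset. On a circular genome windows wrap.
* Windows containing masked (`N`) bases are skipped for the same reason.

The test (`replicatedGof` / `contextGof`) treats the k flanking offsets
as replicates of a two-class goodness-of-fit problem against the expected
G/C proportion p: per-offset
`G = 2[O ln(O/np) + (n−O) ln((n−O)/n(1−p))]` (0·ln 0 ≡ 0),
`G_T = Σ G_i` with k df, pooled `G_P = G(ΣO, kn, p)` with 1 df, and
heterogeneity `G_H = G_T − G_P` with k−1 df, so the additive identity
holds to machine precision by construction. `G_P` answers "is the average
flanking composition biased?", `G_H` "do the offsets disagree?". Tail
probabilities use `pchisq(..., lower.tail = FALSE)`.

Choices that matter:

* **Centre exclusion.** The mutated site is not a flank; by default the
  test uses the 10 flanking offsets of a ±5 profile (9 heterogeneity df),
  with `includeCenter = TRUE` available. The profile itself always
  reports all 11 offsets.
* **p is user-supplied and region-specific** (e.g. a genome-wide 0.508
  vs a lacI-regional 0.563); using the genome-wide value for a
  compositionally distinct locus would confound regional composition
  with context effects.
* **No small-sample correction by default.** At n = 23 the plain G is
  mildly anticonservative; the Williams correction
  (`G / (1 + (a²−1)/(6nν))`) is an opt-in flag, as is an exact binomial
  per-position test. The package's null simulations (2000 replicates,
  k = 10, n = 23, p = 0.508) put the pooled test's type-I error at
  0.05 ± 0.015, which is why the uncorrected statistic is an acceptable
  default at these sizes.
* **Reporting precision**: statistics at 3 significant figures, P values
  at 4 decimals, matching field convention.

```{r gof}
replicatedGof(c(16, 10, 16, 18, 15, 15, 10, 13, 10, 11), 23, 0.508)
```

## Selection through serial bottlenecks

The MA regime modelled by `regimeSpec()` is a daily cycle: growth by a
factor of 100 (log₂100 ≈ 6.644 binary-fission generations) to ~5×10⁸
cells, then transfer of N_b = 5×10⁶ cells. The simulator's model
decisions, all of which were genuinely open:

* **Growth is deterministic**, a relative-fitness update
  `f' = f(1+s)^g / (f(1+s)^g + 1 − f)`; drift acts only at the transfer,
  as a binomial sample of N_b cells. Justification: census size during
  growth never falls below N_b = 5×10⁶, so within-day drift is negligible
  next to transfer sampling. There is no explicit resource model; s is
  the net per-generation fitness difference under the experiment's
  conditions, constant in time, without epistasis or clonal interference.
* **New mutants enter as one cell among the founders of a cycle**
  (f₀ = 1/N_b). The alternative — arising mid-growth, entering the first
  transfer at 1/(N_b·growthFactor) — is the `origin = "growth"` option.
* **Retention** means ≥1 copy in the final bottleneck sample; a
  frequency-threshold criterion emulating sequencing detectability is the
  `threshold` option.
* **Common random numbers.** All stochastic draws go through
  `qbinom(runif(...))` on a seed-fixed stream, so runs at different s
  consume identical uniforms. The depression ratio
  `retention(0)/retention(s)` is then exactly 1 at s = 0, its Monte-Carlo
  noise largely cancels, and the ratio curve is smooth enough to invert
  by bisection (tolerance |Δs| < 10⁻⁴, fixed replicate budget per
  evaluation, seeds recorded in the returned estimate). The Monte-Carlo
  standard error of the inverted coefficient is propagated through the
  local slope of the ratio curve.
* **Horizon.** The depression experienced by a mutation depends on how
  long it is exposed to selection before sampling; there is no single
  correct value, so the horizon is an argument (default 200 generations,
  ~30 cycles — long enough for neutral lineage loss to approach its
  slow asymptote while keeping a run at 10⁴–2×10⁴ replicates
  subsecond). Inversions of an observed ratio should be reported together
  with the horizon used.

Reconstruction controls are handled by `simulateMixtureTrajectory` /
`fitSelectionFromMixture`: under the deterministic update, logit f is
linear in elapsed generations with slope ln(1+s), so a least-squares fit
of the logit trajectory recovers s (exactly, in the noiseless limit; the
regression slope's standard error is back-transformed for the noisy
case).

```{r sim}
obs <- rateDepressionRatio(-0.01, horizon = 200, replicates = 5000, seed = 7)
obs$ratio
```

## The synthetic-data generator

Every pipeline stage is testable without external data:

* `makeGenome(length, p, seed)` — i.i.d. bases with
  P(G) = P(C) = p/2; default p = 0.508, a typical enteric-bacterial
  G+C content.
* `makeUsageTable` — within-family fractions from a symmetric Dirichlet
  (concentration 0.5 by default, i.e. strongly biased families, the
  regime where usage vectors are informative).
* `makeGenes` — start codon, internal codons drawn per amino acid
  (uniform) and codon (per usage fraction), stop codon; genes placed on
  random strands with i.i.d. spacers, annotations carrying strand and
  frame.
* `plantMutations` — sites drawn with weight `exp(β · c)`, c = G/C count
  in the ±flank window excluding the centre; the alternate base drawn
  from the six-class spectrum probabilities conditioned on the reference
  pair. `exp(β·c)` was chosen because it is a monotone single-parameter
  alternative whose β = 0 case reduces *exactly* to the uniform null the
  G test assumes, and the centre exclusion in c matches the test's
  centre-exclusion convention, so planted effects target precisely what
  the test measures.
* `simulateMACounts` — Poisson counts with mean rate·T per line.

All generators take explicit seeds and restore the caller's RNG state.
What the generator does **not** emulate: real gene content and operon
structure, replication-origin distance effects, transcription-coupled
repair, strand asymmetries, mutator heterogeneity among lines, and any
higher-order (di/trinucleotide) context structure. Tests passing on this
synthetic universe therefore validate the *statistical machinery* —
calibration, identities, parameter recovery — not the biological claim
that any particular real dataset satisfies the i.i.d. null.

## Numerical conventions and degenerate inputs

* `0 · ln(0)` terms in G are 0 by continuity; counts at exactly n·p give
  identically zero statistics.
* The doubling binomial P at the distribution centre is capped at 1.
* `ref == alt` records, duplicate ids, unparsable positions and
  reference-base mismatches are hard errors that name the offending
  rows/ids; validation never silently drops rows.
* Ambiguity codes are rejected by default (`mask = TRUE` converts to `N`
  and excludes affected windows).
* An all-skipped context extraction errors rather than returning an
  empty profile; lethal selection (1+s ≤ 0) errors in the growth update.
* Bisection brackets that cannot reach the observed ratio raise a
  bracket-failure error instead of extrapolating.

## Problem sizes used by the test suite

Null calibration uses 2000 replicate count vectors; parameter-recovery
runs use 2×10⁴ lineages over 30 cycles for the selection coefficient,
1000 planted mutations for spectrum recovery, and 10⁵ bp genomes for
context power checks. These sizes give 3σ Monte-Carlo bounds that are
tight relative to the planted effects while keeping the whole suite in
the tens of seconds.

## Known limitations

* The similarity band ρ and the usage table jointly determine usage-vector
  tallies; down/similar/up counts are not comparable across choices.
* The pooled G at n = 23 is slightly anticonservative without the
  Williams correction; borderline pooled P values near 0.05 should be
  read accordingly.
* The simulator's s is an *average effective* coefficient under the
  regime; it does not separate fixation dynamics from detection, and
  clonal interference among co-segregating mutations is ignored.
* The inversion of a rate-depression ratio into s is conditional on the
  chosen horizon; report both.
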