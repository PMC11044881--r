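---
title: "Estimating allele frequency by KDE on sequence space"
author: "alleleKDE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating allele frequency by KDE on sequence space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alleleKDE)
```

## The estimation problem

A locus of length $l$ defines a discrete space of $4^l$ possible
sequences; the allele frequencies of a population are a probability
mass function on that space. A sample of $n$ sequences observes only
some alleles, and the plain counting estimator puts zero mass on every
sequence not observed. Because alleles arise by substitution,
sequences close (in Hamming distance) to an observed allele are more
plausible carriers of hidden frequency than distant ones. `alleleKDE`
formalizes this with kernel density estimation: every sampled sequence
spreads its $1/n$ weight over its mutational neighbourhood,

$$\hat f(a) \;=\; \frac{1}{n}\sum_{i=1}^{n} Q_P\!\bigl(d(a, a_i)\bigr),
\qquad Q_P(x) = (1-3P)^{\,l-x}\,P^{\,x},$$

where $d$ is the Hamming distance and $x$ counts substituted
positions. $Q_P(x)$ is the probability, under the Jukes–Cantor model,
that a sequence turns into one *specific* sequence $x$ substitutions
away: each of the $x$ changed bases with probability $P$, each of the
$l-x$ retained bases with probability $1-3P$. Summed over all $4^l$
sequences this kernel is exactly 1 (binomial identity over the
distance shells of size $\binom{l}{x}3^x$), so $\hat f$ is a proper
mass function.

### The bandwidth

$P$ is the finite-time Jukes–Cantor transition probability
$P(g,\mu) = \tfrac14 - \tfrac14 (1-\tfrac{4}{3}\mu)^{g}$, the chance
that one base has become one specific other base after $g$ generations
at mutation rate $\mu$ per base per generation. Neither $g$ nor $\mu$
needs to be known: their whole effect on the kernel passes through the
single number $P \in [0, 1/4)$, which is selected from the data.
$P = 0$ reduces the estimate to counting; as $P \to 1/4$ the kernel
flattens toward the uniform distribution over all sequences. The
closed form is monotone in $g$ and saturates at $1/4$; it is exact for
real $g \ge 0$ (with $P(0,\mu)=0$), which the coalescent simulator
exploits for continuous branch lengths.

Bandwidth selection uses leave-one-out cross-validation, the only
family of selectors that survives on a space where differentiation is
unavailable:

* **LSCV** minimizes
  $\sum_c \mathrm{mult}(c)\,\hat f_{\mathrm{seq}}(c)^2 -
  \tfrac{2}{n}\sum_i \hat f_{-i}(a_i)$, a discrete integrated-squared-
  error estimate. Weighting the squared per-sequence mass by the
  coordinate multiplicity makes the criterion computed on the
  compressed space *identical* to the same criterion on the full
  sequence space (verified against enumeration in the tests).
* **LCV** maximizes $\sum_i \log \hat f_{-i}(a_i)$ and is $-\infty$
  whenever some held-out allele gets zero leave-one-out mass — e.g. a
  singleton farther than the truncation radius from every other
  sampled sequence. If that happens for every candidate bandwidth the
  selection falls back to $P=0$ (counting) and flags it.

Leave-one-out removes one *individual* (one sequence record), not one
allele type, so the denominator is $n-1$ and duplicated alleles retain
mass. The search grid is $\{0\} \cup$ 64 log-spaced points in
$[10^{-8}, 0.2499]$, refined by golden-section search around the grid
optimum; ties break toward smaller $P$ (less smoothing) so the
selection is deterministic.

## Compressing the space

The sequence space is materializable only for toy lengths
(`buildSequenceSpace()` refuses above $4^{10}$ coordinates by
default). Real estimation runs on the **distance space**: each
sequence is represented by its vector of Hamming distances to the $k$
detected alleles. The kernel depends on a sequence only through these
distances, so all sequences sharing a distance vector share one
coordinate, whose **multiplicity** (the number of such sequences) is
computed exactly.

Truncation makes this finite: with mutation number $m$, the kernel is
cut at distance $m$, sequences farther than $m$ from every detected
allele carry no mass and are dropped, and distance entries above $m$
are censored to `Inf`. Detected alleles keep their exact mutual
distances. $m=0$ is exactly counting; $m$ of 1 or 2 is enough in
practice because the kernel decays geometrically in $x$.
Realizable coordinates are found constructively — enumerating
substitution patterns of up to $m$ positions around each detected
allele and reading distances off an incremental position-class rule —
never by materializing $4^l$; a guard refuses enumerations beyond
`maxCandidates` sequences.

Because the paper-trail question "is the truncated kernel
renormalized?" has no single right answer, both behaviours are
exposed. The default `renormalize = TRUE` divides the truncated kernel
by its total so each sample still contributes mass exactly $1/n$ and
$\hat f$ remains a proper mass function; with `renormalize = FALSE`
the truncated kernel keeps its raw values and total mass falls below
one. We keep renormalization on by default because a mass deficit
breaks the premise that frequencies sum to one, and in our experiments
the deficit at cross-validated bandwidths is small either way.

## Approximate nucleotide diversity

Nucleotide diversity is the frequency-weighted mean substitution rate
over ordered allele pairs, $\pi = \sum_i \sum_j p_i p_j d_{ij}/l$. On
the distance space the pairwise distances between two *undetected*
coordinates are unknown, so the estimator keeps the
(detected, detected) and (detected, undetected) terms and drops the
(undetected, undetected) ones; the dropped terms are non-negative, so
the approximation can only undershoot the full-space value of the same
estimate. When a coordinate's distance to allele $i$ is censored, the
coordinate's mass is distributed over the true distances it may hide:
for sequences at distance $x$ from an anchor allele $A$ (the
coordinate's nearest finite-distance allele; ties broken toward the
lexicographically smallest sequence, for determinism), the count at
each distance to another allele $B$ at $d(A,B)=d$ follows a
convolution over position classes — a substitution at one of the $l-d$
agreeing positions moves the distance to $B$ by $+1$ (3 variants), one
at a differing position by $-1$ (1 variant) or $0$ (2 variants) —
restricted to distances beyond $m$ (the censoring condition). With two
detected alleles this reconstruction is exact; with more it conditions
on one allele at a time and is an approximation. A debug flag
(`allTerms = TRUE`) expands the retained member sequences of a small
space and evaluates *all* pair terms, which the tests use to verify
the machinery against exhaustive enumeration.

Expected heterozygosity and Watterson's $\theta$ are deliberately
absent: they need per-site or segregating-site information that the
distance space does not retain.

## The synthetic populations

`simulatePopulation()` draws a standard single-deme $n$-coalescent
genealogy (exponential waiting times with rate $\binom{k}{2}$ while
$k$ lineages remain, uniformly chosen pairs merging) and evolves a
uniform random root sequence down it under finite-sites Jukes–Cantor
substitution, using the same $P(g,\mu)$ transition engine as the
kernel — one exact finite-time step per branch, so multiple hits
collapse automatically and no per-generation looping occurs.

Two timescales are supported. `simulateGenealogy()` defaults to
branch lengths in generations (scaled by $2N$, so a random pair of
lineages coalesces after $2N$ generations in expectation — the
calibration the tests check). The population generator and experiment
harness default to `timescale = "coalescent"`: branch lengths stay in
coalescent units and $\mu$ acts per unit, so per-site population
diversity lands near $2\mu$ (with Jukes–Cantor saturation pulling it
below that as $\mu$ grows). This mirrors classic
coalescent-plus-sequence-simulator pipelines, in which a rapidly
coalescing single deme yields order-one tree depths and mutation rates
of 0.01–0.1 per base are needed to place appreciable polymorphism in
the population; at $\mu = 0.01$ and $\mu = 0.1$ the simulated
diversities fall in the same range as the populations such pipelines
produce. The generation timescale is kept for users who want literal
demographic units and for calibration checks.

What the generator does **not** emulate: recombination, migration,
selection, population-size change, indels, rate heterogeneity across
sites, and non-JC substitution biases. Tests passing on these
populations therefore say nothing about loci where those forces
matter; they validate the estimator's internal consistency and its
behaviour on neutral, panmictic, substitution-only variation.

All randomness flows from one user seed through a documented split
(`sample.int` sub-seeds drawn under the master seed), so every
artifact is bit-reproducible.

## The evaluation harness

`runExperimentGrid()` simulates one population per
(mutation rate, replicate), shares it across sample sizes, mutation
numbers and CV methods (so within-replicate comparisons are paired),
and records for every cell the selected bandwidth, the approximate
diversity, each replicate's true population diversity, and the
concordance rate $1 - \sum_c |f(c) - \hat f(c)|$ between the
population frequencies (mapped onto the estimate's coordinates;
population alleles outside the truncated space count their full
frequency as discrepancy) and the estimate.
`summarizeExperiment()` aggregates relative bias
$\mathrm{mean}((x_i - X)/X)$, accuracy $\mathrm{mean}(|x_i - X|/X)$
and squared accuracy per cell; `compareCells()` returns paired
per-replicate differences.

The default problem size — populations of 100 sequences of 200 bp,
mutation rate 0.01 per base per coalescent unit, samples of 20 and
100, mutation numbers 0–1, 20 replicates — was chosen so a full grid
runs in seconds while keeping ~10–20 allele types per population;
the full experiment at 1,000 bp and mutation number 2 is supported but
slow, and mutation number 2 at high mutation rates enumerates large
neighbourhoods (the candidate guard will object before memory does).

Two regimes are worth distinguishing when reading harness output. At
low per-sequence mutation load (short sequences, $\mu$ = 0.01) samples
share many alleles, cross-validation selects very small bandwidths,
and the smoothed diversity sits close to — often slightly above — the
counting value: the undetected neighbours of a detected allele lie on
average slightly farther from the *other* detected alleles than the
allele itself, and this inflation can outweigh the omitted
undetected–undetected terms. At high load (long sequences or $\mu$ =
0.1), samples are dominated by singleton alleles, the selectors are
forced toward larger bandwidths (or LCV collapses to counting), a
substantial share of mass moves onto undetected coordinates, and the
omitted terms dominate: the diversity estimate is then biased strongly
downward and its accuracy is clearly worse than counting. The
acceptance script reports both the per-cell accuracies and the sign
pattern so either regime is visible in the numbers it writes.

## Numerical choices

* All kernel mass arithmetic is done in log space; shells,
  truncation totals and per-coordinate accumulations use
  log-sum-exp (a single max-shift suffices because renormalized
  kernel values are bounded by 1), and exponentiation happens once at
  the reporting boundary. The counting limits ($P=0$ or $m=0$) are
  computed exactly as `count/n`, not round-tripped through logs.
* `Inf` is the censoring sentinel, ordered above every finite
  distance; coordinates are canonically ordered (detected alleles
  first in input order, undetected rows lexicographically with `Inf`
  last) so outputs and TSV dumps are deterministic.
* Degenerate inputs are rejected with specific errors: gaps (indels
  cannot be co-used with substitutions), ambiguity codes, `U`, unequal
  lengths, empty files, zero-length sequences, `n < 2` for any
  cross-validation, sample sizes beyond the population.
* Capacity guards protect both the sequence space ($4^l$ cap) and the
  distance-space enumeration (candidate cap); both name the guard in
  their error message rather than attempting allocation.

## Known limitations

* The kernel is isotropic: it assumes every base mutates to every
  other at one rate. General time-reversible substitution would make
  the kernel sequence-dependent, and the distance space — which
  assumes all sequences at equal distances are exchangeable — would no
  longer compress it losslessly.
* The approximate diversity conditions censored-distance recovery on
  one allele at a time; with three or more detected alleles the
  reconstruction is approximate even before terms are dropped.
* Pre-aligned, gap-free, equal-length input is required; indels are
  out of scope by construction.
* Estimation quality degrades with the dimensionality of the distance
  space (one dimension per detected allele): high-diversity samples
  are exactly where the smoothing has the most room to misplace mass.
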