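#' Per-base substitution probability under the Jukes-Cantor chain
#'
#' Probability that one specific base has become one specific other base
#' after `g` generations, when each base mutates at total rate `mu` per
#' generation (to each of the three other bases with probability `mu/3`).
#' Closed form of the one-generation recurrence
#' `p_g = p_{g-1} (1 - mu) + (1 - p_{g-1}) mu/3`:
#' `P(g, mu) = 1/4 - (1/4) (1 - 4 mu / 3)^g`,
#' equivalently `1/4 + (mu/3 - 1/4) (1 - 4 mu/3)^(g-1)`.
#' The form is exact for real `g >= 0` (with `P(0, mu) = 0`), which
#' permits continuous branch lengths in the coalescent simulator. The
#' probability increases monotonically in `g` and saturates at 1/4.
#'
#' @param g number of generations (real, `>= 0`); vectorized.
#' @param mu mutation rate per generation per base, in `[0, 3/4]`.
#' @return probability in `[0, 1/4]`.
#' @examples
#' substitutionProbability(1, 0.03)  # mu/3 = 0.01
#' @export
substitutionProbability <- function(g, mu) {
  if (any(g < 0)) stop("domain error: g must be >= 0")
  if (any(mu < 0 | mu > 0.75)) stop("domain error: mu must lie in [0, 3/4]")
  0.25 - 0.25 * (1 - 4 * mu / 3)^g
}

# Log kernel internals shared by the estimator and the CV criteria.
#
# Returns, for x = 0..m:
#   logQ      log mass the kernel puts on ONE sequence at distance x
#   logShell  log total mass on the distance-x shell: C(l,x) 3^x Q(x)
#   logTotal  log of the truncated kernel total (sum of shells 0..m)
#   logQtilde logQ, renormalized by logTotal when spec@renormalize
# All arithmetic stays on the log scale so that l up to the thousands
# cannot underflow before renormalization.
kernelLogTables <- function(spec) {
  P <- spec@P; l <- spec@l; m <- spec@m
  x <- 0:m
  if (P == 0) {
    logQ <- c(0, rep(-Inf, m))
  } else {
    logQ <- (l - x) * log1p(-3 * P) + x * log(P)
  }
  logShell <- lchoose(l, x) + x * log(3) + logQ
  logTotal <- logSumExp(logShell)
  logQtilde <- if (spec@renormalize) logQ - logTotal else logQ
  list(logQ = logQ, logShell = logShell, logTotal = logTotal,
       logQtilde = logQtilde)
}

#' Kernel mass assigned to one sequence at a given distance
#'
#' Mass the kernel centered on a sampled allele assigns to one specific
#' sequence at Hamming distance `x`: `(1 - 3P)^(l - x) P^x`, truncated
#' to zero beyond the mutation number `m` and, when
#' `spec@renormalize`, divided by the truncated kernel total so the
#' kernel still sums to one over all sequences within distance `m`.
#'
#' @param spec a [KernelSpec-class].
#' @param x integer Hamming distance(s), `0 <= x <= l`.
#' @return numeric mass per sequence (0 for `x > m`).
#' @examples
#' kernelMassPerSequence(KernelSpec(0.1, l = 2, renormalize = FALSE), 0)
#' @export
kernelMassPerSequence <- function(spec, x) {
  stopifnot(is(spec, "KernelSpec"))
  if (any(x < 0 | x > spec@l))
    stop("domain error: x must satisfy 0 <= x <= l")
  tab <- kernelLogTables(spec)
  out <- numeric(length(x))
  inside <- x <= spec@m
  out[inside] <- exp(tab$logQtilde[x[inside] + 1L])
  out
}

#' Total kernel mass per distance shell
#'
#' Aggregate mass the kernel assigns at each Hamming distance
#' `x = 0..m`: `C(l, x) 3^x` sequences per shell times the per-sequence
#' mass. Sums to 1 when `m = l` or when the truncated kernel is
#' renormalized; otherwise sums to the (sub-unit) truncated total.
#'
#' @param spec a [KernelSpec-class].
#' @return numeric vector indexed by distance `0..m`.
#' @examples
#' kernelMassByDistance(KernelSpec(0.1, l = 2, renormalize = FALSE))
#' @export
kernelMassByDistance <- function(spec) {
  stopifnot(is(spec, "KernelSpec"))
  tab <- kernelLogTables(spec)
  off <- if (spec@renormalize) tab$logTotal else 0
  exp(tab$logShell - off)
}
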