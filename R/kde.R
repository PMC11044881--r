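# KDE of allele frequency: each sampled sequence spreads its 1/n weight
# over its mutational neighbourhood through the kernel, so the estimate
# at a coordinate is
#   f(c) = multiplicity(c) * (1/n) * sum_i count_i * q(d(c, a_i))
# where q is the (renormalized) per-sequence kernel mass and d(c, a_i)
# the coordinate's distance to detected allele i (zero contribution when
# censored to Inf or beyond the mutation number).

# Align an AlleleTable's counts with a DistanceSpace's detected alleles.
.alignCounts <- function(table, space) {
  pos <- match(space@detected, table@alleles)
  if (anyNA(pos) || length(space@detected) != length(table@alleles))
    stop("configuration error: space was not built from this allele table")
  as.numeric(table@counts[pos])
}

# Shared accumulation: given a C x 2 index of (row, allele) pairs with
# their distances, counts per allele and the log kernel table, return
# the log per-sequence mass per row. A single global max-shift keeps the
# linear accumulation stable (kernel values are <= exp(shift)).
.accumulateLogMass <- function(nrowC, rowIdx, alleleIdx, dvals, counts, lq, n) {
  shift <- max(lq)
  if (!is.finite(shift)) shift <- 0
  w <- counts[alleleIdx] * exp(lq[dvals + 1L] - shift)
  sv <- numeric(nrowC)
  if (length(w) > 0L) {
    agg <- rowsum(w, group = rowIdx)
    sv[as.integer(rownames(agg))] <- agg
  }
  log(sv) + shift - log(n)
}

#' Estimate allele frequency by KDE on a sequence or distance space
#'
#' @param table an [AlleleTable-class] of the sample.
#' @param spec a [KernelSpec-class]; `spec@l` must equal the allele
#'   length and, on a distance space, `spec@m` the space truncation.
#' @param space a [DistanceSpace-class] built from the table's alleles,
#'   or a [SequenceSpace-class] of matching length. Default: build the
#'   distance space at `spec@m`.
#' @return a [FrequencyEstimate-class]. With `renormalize = TRUE` (or
#'   `m = l`) the total mass is 1; with `P = 0` or `m = 0` the masses
#'   are exactly the counting frequencies.
#' @examples
#' tab <- tallyAlleles(AlleleAlignment(rep(c("AA", "AT"), each = 3)))
#' est <- estimateFrequencies(tab, KernelSpec(0.1, l = 2))
#' freqMass(est)
#' @export
estimateFrequencies <- function(table, spec, space = NULL) {
  stopifnot(is(table, "AlleleTable"), is(spec, "KernelSpec"))
  if (spec@l != table@l)
    stop("configuration error: spec length does not match allele length")
  if (is.null(space)) space <- buildDistanceSpace(table@alleles, spec@m)
  lq <- kernelLogTables(spec)$logQtilde
  n <- table@n

  if (is(space, "DistanceSpace")) {
    if (space@m != spec@m)
      stop("configuration error: space truncation (m = ", space@m,
           ") does not match the kernel spec (m = ", spec@m, ")")
    counts <- .alignCounts(table, space)
    cm <- space@coords
    ok <- which(is.finite(cm) & cm <= spec@m)
    ri <- ((ok - 1L) %% nrow(cm)) + 1L
    ci <- ((ok - 1L) %/% nrow(cm)) + 1L
    logPerSeq <- .accumulateLogMass(nrow(cm), ri, ci, cm[ok], counts, lq, n)
  } else if (is(space, "SequenceSpace")) {
    if (space@l != spec@l)
      stop("configuration error: sequence space length mismatch")
    S <- seqToIntMatrix(space@sequences)
    A <- seqToIntMatrix(table@alleles)
    k <- nrow(A)
    dmat <- matrix(0L, nrow(S), k)
    for (j in seq_len(k))
      dmat[, j] <- rowSums(S != matrix(A[j, ], nrow(S), ncol(S), byrow = TRUE))
    ok <- which(dmat <= spec@m)
    ri <- ((ok - 1L) %% nrow(dmat)) + 1L
    ci <- ((ok - 1L) %/% nrow(dmat)) + 1L
    logPerSeq <- .accumulateLogMass(nrow(dmat), ri, ci, dmat[ok],
                                    as.numeric(table@counts), lq, n)
  } else stop("space must be a DistanceSpace or SequenceSpace")

  mult <- if (is(space, "DistanceSpace")) space@multiplicity
          else rep(1, length(logPerSeq))
  perSeq <- exp(logPerSeq)
  if (spec@P == 0 || spec@m == 0L) {
    # counting limit: masses are exactly count/n on the detected
    # coordinates, zero elsewhere (no log round-trip)
    perSeq <- numeric(length(logPerSeq))
    if (is(space, "DistanceSpace")) {
      counts <- .alignCounts(table, space)
      det <- seq_along(counts)
      perSeq[det] <- counts / n
    } else {
      pos <- match(table@alleles, space@sequences)
      perSeq[pos] <- table@counts / n
    }
    logPerSeq <- log(perSeq)
  }
  new("FrequencyEstimate", space = space, logMass = logPerSeq + log(mult),
      logPerSeq = logPerSeq, mass = perSeq * mult, perSeq = perSeq,
      spec = spec)
}

# Leave-one-out per-sequence mass at every allele type:
#   v_j = (sum_j' count'_j' qtilde(D_jj')) / (n - 1)
# with one copy of allele j removed, i.e. (Q %*% counts - qtilde(0)) / (n-1).
.looPerAllele <- function(table, spec, D = NULL) {
  if (table@n < 2L) stop("cross-validation undefined for n < 2")
  if (is.null(D)) D <- hammingMatrix(table@alleles)
  lq <- kernelLogTables(spec)$logQtilde
  qv <- exp(lq)
  Q <- matrix(0, nrow(D), ncol(D))
  inside <- D <= spec@m
  Q[inside] <- qv[D[inside] + 1L]
  as.numeric(Q %*% table@counts - qv[1L]) / (table@n - 1)
}

#' Leave-one-out density at one sampled individual
#'
#' The estimated per-sequence mass at individual `i`'s allele when that
#' individual is removed from the sample (denominator `n - 1`).
#' Individuals are indexed in allele-table order: all copies of the
#' first allele, then the second, and so on (the value depends only on
#' the individual's allele).
#'
#' @param table an [AlleleTable-class] with `n >= 2`.
#' @param spec a [KernelSpec-class].
#' @param i individual index in `1..n`.
#' @return the leave-one-out per-sequence mass (possibly 0).
#' @export
looDensity <- function(table, spec, i) {
  stopifnot(is(table, "AlleleTable"), is(spec, "KernelSpec"))
  i <- as.integer(i)
  if (i < 1L || i > table@n) stop("individual index out of range")
  j <- rep(seq_along(table@counts), table@counts)[i]
  .looPerAllele(table, spec)[j]
}

#' Least-squares cross-validation criterion
#'
#' Discrete integrated-squared-error criterion
#' `sum_c multiplicity(c) fhat_seq(c)^2 - (2/n) sum_i fhat_{-i}(a_i)`,
#' where `fhat_seq` is the per-sequence mass of the full-sample estimate
#' and the second sum runs over the leave-one-out density at each
#' sampled individual. Lower is better. Weighting the squared mass by
#' coordinate multiplicity makes the criterion on a distance space equal
#' to the same criterion evaluated on the full sequence space.
#'
#' @param table an [AlleleTable-class] with `n >= 2`.
#' @param spec a [KernelSpec-class].
#' @param space optional pre-built [DistanceSpace-class] (or
#'   [SequenceSpace-class]).
#' @return the criterion value (finite for every `P` in `[0, 1/4)`).
#' @export
lscvScore <- function(table, spec, space = NULL) {
  if (table@n < 2L) stop("cross-validation undefined for n < 2")
  est <- estimateFrequencies(table, spec, space)
  mult <- if (is(est@space, "DistanceSpace")) est@space@multiplicity
          else rep(1, length(est@logPerSeq))
  term1 <- exp(logSumExp(log(mult) + 2 * est@logPerSeq))
  v <- .looPerAllele(table, spec)
  term1 - (2 / table@n) * sum(table@counts * v)
}

#' Likelihood cross-validation criterion
#'
#' `sum_i log fhat_{-i}(a_i)` over sampled individuals; higher is
#' better; `-Inf` as soon as any held-out allele receives zero
#' leave-one-out mass (e.g. a singleton farther than the mutation number
#' from every other sampled allele).
#'
#' @inheritParams lscvScore
#' @return the summed log leave-one-out density (may be `-Inf`).
#' @export
lcvScore <- function(table, spec) {
  if (table@n < 2L) stop("cross-validation undefined for n < 2")
  v <- .looPerAllele(table, spec)
  if (any(v <= 0)) return(-Inf)
  sum(table@counts * log(v))
}

#' Default bandwidth search grid
#'
#' Zero plus 64 log-spaced points from `1e-8` to `0.2499`.
#'
#' @return numeric vector of candidate bandwidths.
#' @export
bandwidthGrid <- function() {
  c(0, exp(seq(log(1e-8), log(0.2499), length.out = 64)))
}

#' Select the kernel bandwidth by cross-validation
#'
#' Evaluates the LSCV (minimized) or LCV (maximized) criterion over a
#' deterministic bandwidth grid, optionally refines around the grid
#' optimum by golden-section search, and returns all scores together
#' with the selected bandwidth. Ties break toward the smaller `P` (less
#' smoothing). When every LCV score is `-Inf` the selection falls back
#' to `P = 0` with a warning and the `fallback` flag set.
#'
#' @param table an [AlleleTable-class] with `n >= 2`.
#' @param m mutation number.
#' @param method `"LSCV"` or `"LCV"`.
#' @param grid candidate bandwidths (default [bandwidthGrid()]).
#' @param renormalize renormalize the truncated kernel (default `TRUE`).
#' @param refine golden-section refinement around the grid optimum.
#' @param space optional pre-built [DistanceSpace-class] (used by LSCV;
#'   built on demand when absent).
#' @return a [CVResult-class].
#' @export
selectBandwidth <- function(table, m, method = c("LSCV", "LCV"),
                            grid = bandwidthGrid(), renormalize = TRUE,
                            refine = TRUE, space = NULL) {
  stopifnot(is(table, "AlleleTable"))
  method <- match.arg(method)
  if (table@n < 2L) stop("cross-validation undefined for n < 2")
  m <- as.integer(m)
  grid <- sort(unique(grid))
  if (method == "LSCV" && is.null(space))
    space <- buildDistanceSpace(table@alleles, m, keepSequences = FALSE)
  D <- hammingMatrix(table@alleles)

  scoreAt <- function(P) {
    spec <- KernelSpec(P, table@l, m, renormalize)
    if (method == "LSCV") lscvScore(table, spec, space)
    else {
      v <- .looPerAllele(table, spec, D)
      if (any(v <= 0)) -Inf else sum(table@counts * log(v))
    }
  }
  scores <- vapply(grid, scoreAt, numeric(1))

  fallback <- FALSE
  if (method == "LCV" && all(!is.finite(scores))) {
    warning("all LCV scores are -Inf; falling back to P = 0")
    return(new("CVResult", method = method, grid = grid, scores = scores,
               selectedP = 0, selectedScore = -Inf, fallback = TRUE))
  }
  better <- if (method == "LSCV") function(a, b) a < b else function(a, b) a > b
  opt <- if (method == "LSCV") min(scores) else max(scores[is.finite(scores)])
  bestIdx <- which(scores == opt)[1L]   # grid ascending: first = smallest P
  bestP <- grid[bestIdx]
  bestScore <- scores[bestIdx]

  if (refine && length(grid) > 2L) {
    lo <- if (bestIdx > 1L) grid[bestIdx - 1L] else grid[1L]
    hi <- if (bestIdx < length(grid)) grid[bestIdx + 1L] else grid[length(grid)]
    if (hi > lo) {
      o <- stats::optimize(scoreAt, interval = c(lo, hi),
                           maximum = (method == "LCV"), tol = 1e-6)
      oP <- if (method == "LCV") o$maximum else o$minimum
      oScore <- if (method == "LCV") o$objective else o$objective
      if (is.finite(oScore) &&
          (better(oScore, bestScore) ||
           (oScore == bestScore && oP < bestP))) {
        bestP <- oP
        bestScore <- oScore
      }
    }
  }
  new("CVResult", method = method, grid = grid, scores = scores,
      selectedP = bestP, selectedScore = bestScore, fallback = fallback)
}
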