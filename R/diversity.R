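# Nucleotide diversity: pi = sum_i sum_j p_i p_j d_ij / l over ordered
# allele pairs, the expected per-site difference proportion between two
# draws from the frequency distribution.

.piFromFreqs <- function(freqs, l, check = TRUE) {
  p <- as.numeric(freqs)
  al <- names(freqs)
  if (is.null(al)) stop("freqs must be named by allele sequence")
  if (check && abs(sum(p) - 1) > 1e-6)
    stop("frequency sum violation: frequencies must sum to 1")
  D <- hammingMatrix(al)
  as.numeric(p %*% D %*% p) / l
}

#' Exact nucleotide diversity from an allele frequency distribution
#'
#' `pi = sum_i sum_j p_i p_j d_ij / l`: the double sum over all ordered
#' allele pairs of the frequency product times the substitution rate
#' (Hamming distance divided by sequence length). Identical alleles
#' contribute zero; each unordered pair enters twice.
#'
#' @param freqs numeric vector of allele frequencies named by sequence,
#'   summing to 1 (tolerance `1e-6`), or an [AlleleTable-class] (counting
#'   frequencies are used).
#' @param l sequence length; inferred from the allele names by default.
#' @return a [DiversityResult-class].
#' @examples
#' piValue(nucleotideDiversityExact(c(AA = 0.5, AT = 0.5)))  # 0.25
#' @export
nucleotideDiversityExact <- function(freqs, l = NULL) {
  if (is(freqs, "AlleleTable"))
    freqs <- stats::setNames(freqs@counts / freqs@n, freqs@alleles)
  if (is.null(l)) l <- nchar(names(freqs)[1L])
  new("DiversityResult", pi = .piFromFreqs(freqs, l), terms = "all",
      l = as.integer(l))
}

# Memoized mean distance from allele i for a censored coordinate, given
# an anchor allele at finite distance x and anchor-to-i distance dAB:
# distribute the shell A_x over true distances to i combinatorially and
# keep only distances beyond the truncation m (the censoring condition).
.censoredMeanDistance <- function(dAB, l, x, m, cache) {
  key <- paste(dAB, x, sep = ":")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  cnt <- jointDistanceCounts(dAB, l, x)
  y <- as.numeric(names(cnt))
  keep <- y > m
  val <- if (any(keep)) sum(y[keep] * cnt[keep]) / sum(cnt[keep]) else m + 1
  cache[[key]] <- val
  val
}

#' Approximate nucleotide diversity from a distance-space estimate
#'
#' Computes nucleotide diversity from a KDE frequency estimate living on
#' a distance space, where pairwise distances between undetected alleles
#' are unavailable. The sum keeps the (detected, detected) terms, using
#' the exact distance matrix, and the (detected, undetected) terms,
#' using each coordinate's recorded distance to the detected allele.
#' When that distance is censored to `Inf`, the coordinate's mass is
#' distributed over the true distances it can hide via the
#' [jointDistanceCounts()] combinatorics, anchored at the coordinate's
#' nearest finite-distance detected allele (ties broken toward the
#' lexicographically smallest allele sequence), restricted to distances
#' beyond the truncation radius. Terms between two undetected alleles
#' are omitted; since those terms are non-negative, the approximation
#' never exceeds the full-space value on the same estimate.
#'
#' @param est a [FrequencyEstimate-class] on a [DistanceSpace-class].
#' @param allTerms debug flag: also include undetected-undetected terms
#'   by expanding the retained member sequences of every coordinate
#'   (requires a space built with `keepSequences = TRUE`); used to
#'   verify the estimator against the exact computation on small spaces.
#' @return a [DiversityResult-class].
#' @export
nucleotideDiversityApprox <- function(est, allTerms = FALSE) {
  stopifnot(is(est, "FrequencyEstimate"))
  space <- est@space
  if (!is(space, "DistanceSpace"))
    stop("approximate diversity is defined on a DistanceSpace estimate")
  l <- space@l
  k <- length(space@detected)
  w <- est@mass

  if (allTerms) {
    if (length(space@members) == 0L)
      stop("allTerms requires a space built with keepSequences = TRUE")
    seqs <- unlist(space@members, use.names = FALSE)
    p <- rep(est@perSeq, times = lengths(space@members))
    pi <- .piFromFreqs(stats::setNames(p, seqs), l, check = FALSE)
    return(new("DiversityResult", pi = pi, terms = "all", l = l))
  }

  pDet <- w[seq_len(k)]
  piDet <- as.numeric(pDet %*% space@D %*% pDet) / l

  piCross <- 0
  nc <- nrow(space@coords)
  if (nc > k) {
    cache <- new.env(parent = emptyenv())
    lexOrd <- order(space@detected)
    for (r in (k + 1L):nc) {
      row <- space@coords[r, ]
      if (w[r] == 0) next
      finite <- which(is.finite(row))
      dmin <- min(row[finite])
      nearest <- finite[row[finite] == dmin]
      anchor <- nearest[order(match(nearest, lexOrd))][1L]
      for (i in seq_len(k)) {
        di <- if (is.finite(row[i])) row[i]
              else .censoredMeanDistance(space@D[anchor, i], l,
                                         row[anchor], space@m, cache)
        piCross <- piCross + 2 * pDet[i] * w[r] * di / l
      }
    }
  }
  new("DiversityResult", pi = piDet + piCross,
      terms = "detected_pairs_and_detected_undetected", l = l)
}

#' Concordance rate between true and estimated allele frequencies
#'
#' `1 - sum_c |f(c) - fhat(c)|` over the union of coordinates of the
#' true and estimated mass functions. Equals 1 iff the distributions are
#' identical; can go down to -1 for disjoint supports. On a distance
#' space, population alleles are mapped onto the estimate's coordinates
#' (detected alleles by identity, others by their censored distance
#' vector); population alleles outside the truncated space contribute
#' their full frequency as discrepancy.
#'
#' @param trueFreqs numeric vector of population frequencies named by
#'   allele sequence (or an [AlleleTable-class]).
#' @param est a [FrequencyEstimate-class].
#' @return the concordance rate (`<= 1`).
#' @examples
#' tab <- tallyAlleles(AlleleAlignment(rep(c("AA", "AT"), each = 3)))
#' est <- estimateFrequencies(tab, KernelSpec(0, l = 2, m = 0))
#' concordanceRate(c(AA = 0.6, AT = 0.4), est)  # 0.8
#' @export
concordanceRate <- function(trueFreqs, est) {
  if (is(trueFreqs, "AlleleTable"))
    trueFreqs <- stats::setNames(trueFreqs@counts / trueFreqs@n,
                                 trueFreqs@alleles)
  stopifnot(is(est, "FrequencyEstimate"))
  space <- est@space
  fhat <- est@mass

  if (is(space, "SequenceSpace")) {
    f <- numeric(length(space@sequences))
    pos <- match(names(trueFreqs), space@sequences)
    if (anyNA(pos)) stop("population alleles do not match the space length")
    f[pos] <- trueFreqs
    return(1 - sum(abs(f - fhat)))
  }

  k <- length(space@detected)
  f <- numeric(nrow(space@coords))
  outside <- 0
  gkey <- do.call(paste, c(as.data.frame(space@coords), sep = ","))
  for (a in names(trueFreqs)) {
    idx <- match(a, space@detected)
    if (is.na(idx)) {
      dv <- vapply(space@detected, hammingDistance, numeric(1), a = a)
      dv[dv > space@m] <- Inf
      if (all(is.infinite(dv))) {
        outside <- outside + trueFreqs[[a]]
        next
      }
      idx <- match(paste(dv, collapse = ","), gkey)
      if (is.na(idx)) {  # cannot happen for a coordinate inside the space
        outside <- outside + trueFreqs[[a]]
        next
      }
    }
    f[idx] <- f[idx] + trueFreqs[[a]]
  }
  1 - (sum(abs(f - fhat)) + outside)
}

#' Bias, accuracy and squared accuracy over replicate estimates
#'
#' Relative bias `mean((x_i - X)/X)`, accuracy `mean(|x_i - X|/X)` and
#' squared accuracy `mean(((x_i - X)/X)^2)` of replicate estimates
#' against the known parameter, with the standard deviation of each
#' per-replicate quantity. Accuracy is always at least `|bias|`.
#'
#' @param estimates numeric vector of per-replicate estimates.
#' @param truth the known parameter value (scalar, or one value per
#'   replicate when each replicate has its own truth); must be nonzero.
#' @return one-row `data.frame` with columns `relativeBias`, `accuracy`,
#'   `squaredAccuracy`, their standard deviations, and `n`.
#' @export
evaluationStats <- function(estimates, truth) {
  if (length(estimates) < 1L) stop("at least one replicate is required")
  if (any(truth == 0)) stop("truth must be nonzero")
  rel <- (estimates - truth) / truth
  data.frame(
    relativeBias = mean(rel),
    accuracy = mean(abs(rel)),
    squaredAccuracy = mean(rel^2),
    sdRelativeBias = stats::sd(rel),
    sdAccuracy = stats::sd(abs(rel)),
    sdSquaredAccuracy = stats::sd(rel^2),
    n = length(rel))
}
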