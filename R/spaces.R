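#' Materialize the full nucleotide sequence space
#'
#' Enumerates all `4^l` sequences of length `l` in lexicographic order
#' (A < C < G < T). Intended for very short sequences only: the space
#' grows as `4^l`, so materialization is refused when `4^l` exceeds
#' `maxSize` (default `4^10`; even a 10-mer space holds over a million
#' coordinates, and real loci are far beyond any memory).
#'
#' @param l sequence length.
#' @param maxSize guard on the space size; refuse to allocate above it.
#' @return a [SequenceSpace-class].
#' @examples
#' sequences(buildSequenceSpace(1))
#' @export
buildSequenceSpace <- function(l, maxSize = 4^10) {
  l <- as.integer(l)
  if (l < 1L) stop("l must be a positive integer")
  if (4^l > maxSize)
    stop(sprintf(
      "capacity error: sequence space size 4^%d = %g exceeds the guard of %g coordinates",
      l, 4^l, maxSize))
  g <- do.call(expand.grid,
               c(rep(list(.BASES), l),
                 KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  seqs <- do.call(paste0, rev(as.list(g)))
  new("SequenceSpace", l = l, sequences = seqs)
}

# The v-th (v = 1..3) base different from base b (1..4), as integer codes.
.OTHER <- t(vapply(1:4, function(b) setdiff(1:4, b), integer(3)))

# Enumerate, for source allele index i, every sequence obtained by
# substituting exactly `s` positions, together with its exact Hamming
# distance to every detected allele. Distances are computed
# incrementally from the detected-allele distance matrix: substituting
# position p of allele i to base b shifts the distance to allele j by
#   +1 if allele_j[p] == allele_i[p]           (new mismatch)
#   -1 if b == allele_j[p]                     (mismatch repaired)
#    0 otherwise                               (mismatch stays)
# so no pairwise sequence comparison is ever needed.
.enumerateShell <- function(i, s, alleleMat, alleleStr, D) {
  l <- ncol(alleleMat)
  k <- nrow(alleleMat)
  ai <- alleleMat[i, ]
  posSets <- utils::combn(l, s)          # s x Np
  Np <- ncol(posSets)
  vGrid <- as.matrix(do.call(expand.grid, rep(list(1:3), s)))  # 3^s x s
  Nv <- nrow(vGrid)
  # candidate t-th changed position / base-choice, candidates = Np * Nv
  posIdx <- matrix(posSets[, rep(seq_len(Np), each = Nv)],
                   nrow = s)                       # s x Ncand
  vIdx <- t(vGrid[rep(seq_len(Nv), times = Np), , drop = FALSE]) # s x Ncand
  ncand <- Np * Nv
  newBase <- matrix(.OTHER[cbind(as.vector(ai[posIdx]), as.vector(vIdx))],
                    nrow = s)
  # exact distances to every detected allele
  dist <- matrix(0, ncand, k)
  for (j in seq_len(k)) {
    aj <- alleleMat[j, ]
    delta <- integer(ncand)
    for (t in seq_len(s)) {
      p <- posIdx[t, ]; b <- newBase[t, ]
      agree <- aj[p] == ai[p]
      delta <- delta + ifelse(agree, 1L, ifelse(b == aj[p], -1L, 0L))
    }
    dist[, j] <- D[i, j] + delta
  }
  # candidate sequence strings
  a <- alleleStr[i]
  keys <- if (s == 1L) {
    p <- posIdx[1L, ]
    paste0(substring(a, 1L, p - 1L), .BASES[newBase[1L, ]],
           substring(a, p + 1L, l))
  } else if (s == 2L) {
    p1 <- posIdx[1L, ]; p2 <- posIdx[2L, ]
    paste0(substring(a, 1L, p1 - 1L), .BASES[newBase[1L, ]],
           substring(a, p1 + 1L, p2 - 1L), .BASES[newBase[2L, ]],
           substring(a, p2 + 1L, l))
  } else {
    chars <- strsplit(a, "", fixed = TRUE)[[1L]]
    vapply(seq_len(ncand), function(cc) {
      x <- chars
      x[posIdx[, cc]] <- .BASES[newBase[, cc]]
      paste(x, collapse = "")
    }, character(1L))
  }
  list(keys = keys, dist = dist)
}

#' Build the compressed distance space around detected alleles
#'
#' Constructs every realizable coordinate of the distance space: one
#' coordinate per detected allele (carrying its exact distance vector to
#' all detected alleles) plus one coordinate for every distinct censored
#' distance vector realized by an undetected sequence within mutation
#' number `m` of at least one detected allele. Undetected entries larger
#' than `m` are censored to `Inf`; sequences farther than `m` from every
#' detected allele are outside the space entirely. Realizability is
#' decided constructively, by enumerating substitution patterns of up to
#' `m` positions around each detected allele, never by materializing the
#' `4^l` sequence space.
#'
#' @param detected character vector of distinct, equal-length detected
#'   alleles (or an [AlleleTable-class]).
#' @param m mutation number (truncation radius), `>= 0`.
#' @param keepSequences retain the member sequences of each coordinate
#'   (needed for sequence-level lookups and the all-terms diversity
#'   debug mode). Default `NULL`: retain when the enumeration holds at
#'   most `1e5` candidate sequences.
#' @param maxCandidates guard on the number of enumerated candidate
#'   sequences.
#' @return a [DistanceSpace-class]; detected alleles first (input
#'   order), undetected coordinates in lexicographic order with `Inf`
#'   sorting last.
#' @examples
#' coordinates(buildDistanceSpace(c("AA", "AT"), m = 2))
#' @export
buildDistanceSpace <- function(detected, m, keepSequences = NULL,
                               maxCandidates = 5e6) {
  if (is(detected, "AlleleTable")) detected <- detected@alleles
  detected <- as.character(detected)
  k <- length(detected)
  if (k < 1L) stop("at least one detected allele is required")
  if (anyDuplicated(detected)) stop("detected alleles must be distinct")
  l <- nchar(detected[1L])
  if (any(nchar(detected) != l)) stop("detected alleles must share one length")
  m <- as.integer(m)
  if (m < 0L) stop("mutation number m must be >= 0")
  mEff <- min(m, l)
  D <- hammingMatrix(detected)
  storage.mode(D) <- "double"

  if (mEff == 0L) {
    return(new("DistanceSpace", detected = detected, D = D, m = m, l = l,
               coords = D, multiplicity = rep(1, k),
               members = as.list(detected)))
  }

  shellSizes <- choose(l, 1:mEff) * 3^(1:mEff)
  if (k * sum(shellSizes) > maxCandidates)
    stop(sprintf(
      "capacity error: distance-space enumeration needs %g candidate sequences, above the guard of %g",
      k * sum(shellSizes), maxCandidates))

  alleleMat <- seqToIntMatrix(detected)
  keys <- vector("list", k * mEff)
  dists <- vector("list", k * mEff)
  idx <- 0L
  for (i in seq_len(k)) {
    for (s in seq_len(mEff)) {
      sh <- .enumerateShell(i, s, alleleMat, detected, D)
      idx <- idx + 1L
      keys[[idx]] <- sh$keys
      dists[[idx]] <- sh$dist
    }
  }
  keys <- unlist(keys, use.names = FALSE)
  dist <- do.call(rbind, dists)
  if (is.null(keepSequences)) keepSequences <- length(keys) <= 1e5

  sel <- !duplicated(keys) & !(keys %in% detected)
  keys <- keys[sel]
  cd <- dist[sel, , drop = FALSE]
  cd[cd > m] <- Inf

  if (nrow(cd) > 0L) {
    gkey <- do.call(paste, c(as.data.frame(cd), sep = ","))
    first <- !duplicated(gkey)
    ucoords <- cd[first, , drop = FALSE]
    f <- factor(gkey, levels = gkey[first])
    umult <- as.numeric(tabulate(f, nbins = nlevels(f)))
    ord <- do.call(order, as.data.frame(ucoords))
    ucoords <- ucoords[ord, , drop = FALSE]
    umult <- umult[ord]
    umembers <- if (keepSequences) {
      mem <- split(keys, f)
      unname(mem[ord])
    } else list()
  } else {
    ucoords <- cd
    umult <- numeric(0)
    umembers <- if (keepSequences) list() else list()
  }

  members <- if (keepSequences) c(as.list(detected), umembers) else list()
  new("DistanceSpace", detected = detected, D = D, m = m, l = l,
      coords = unname(rbind(D, ucoords)),
      multiplicity = c(rep(1, k), umult),
      members = members)
}

#' Multiplicity of one distance-space coordinate
#'
#' The number of distinct sequences realizing the given distance vector
#' (with `Inf` meaning "farther than the mutation number from that
#' detected allele").
#'
#' @param space a [DistanceSpace-class].
#' @param coord numeric vector of length k (entries may be `Inf`).
#' @return positive integer count.
#' @examples
#' sp <- buildDistanceSpace(c("AA", "AT"), m = 2)
#' coordinateMultiplicity(sp, c(1, 1))  # "AG" and "AC"
#' @export
coordinateMultiplicity <- function(space, coord) {
  stopifnot(is(space, "DistanceSpace"))
  if (length(coord) != ncol(space@coords))
    stop("coordinate must have one entry per detected allele")
  hit <- which(apply(space@coords, 1L, function(r) all(r == coord)))
  if (length(hit) == 0L)
    stop("lookup error: coordinate (", paste(coord, collapse = ", "),
         ") is not in the space")
  space@multiplicity[hit[1L]]
}

#' Joint distance counts around two alleles
#'
#' For two alleles A and B at Hamming distance `d`, counts how the
#' `C(l, x) 3^x` sequences lying at distance exactly `x` from A
#' distribute over their distance to B. Computed combinatorially over
#' the position classes: a substitution at one of the `l - d` positions
#' where A and B agree moves the distance to B by +1 (3 base choices); a
#' substitution at one of the `d` differing positions moves it by -1
#' when it hits B's base (1 choice) and by 0 otherwise (2 choices).
#' This is the counting that recovers frequency and distance between a
#' detected allele and censored undetected coordinates in the
#' approximate nucleotide diversity.
#'
#' @param d Hamming distance between the two reference alleles.
#' @param l sequence length.
#' @param x distance from allele A.
#' @return named numeric vector: counts indexed by distance to B;
#'   sums to `C(l, x) 3^x`.
#' @examples
#' jointDistanceCounts(d = 1, l = 2, x = 1)  # counts c(`0` = 1, `1` = 2, `2` = 3)
#' @export
jointDistanceCounts <- function(d, l, x) {
  if (d < 0 || d > l) stop("domain error: need 0 <= d <= l")
  if (x < 0 || x > l) stop("domain error: need 0 <= x <= l")
  counts <- numeric(l + 1L)  # index y + 1
  jmin <- max(0L, x - (l - d))
  jmax <- min(d, x)
  for (j in jmin:jmax) {
    agreePart <- choose(l - d, x - j) * 3^(x - j)
    for (t in 0:j) {
      y <- d - t + (x - j)
      counts[y + 1L] <- counts[y + 1L] +
        choose(d, j) * choose(j, t) * 2^(j - t) * agreePart
    }
  }
  nz <- which(counts > 0)
  stats::setNames(counts[nz], nz - 1L)
}

#' Write a distance space (with optional frequencies) to TSV
#'
#' One row per coordinate: columns `d_1 .. d_k` (integers or `Inf`),
#' `multiplicity`, and when an estimate is supplied, `frequency` (total
#' coordinate mass) and `per_sequence_frequency`.
#'
#' @param space a [DistanceSpace-class].
#' @param path output path.
#' @param estimate optional [FrequencyEstimate-class] on this space.
#' @return `path`, invisibly.
#' @export
writeDistanceSpace <- function(space, path, estimate = NULL) {
  stopifnot(is(space, "DistanceSpace"))
  df <- as.data.frame(space@coords)
  names(df) <- paste0("d_", seq_len(ncol(space@coords)))
  df$multiplicity <- space@multiplicity
  if (!is.null(estimate)) {
    stopifnot(is(estimate, "FrequencyEstimate"))
    df$frequency <- estimate@mass
    df$per_sequence_frequency <- estimate@perSeq
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
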