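#' @import methods
NULL

#' Gap-free equal-length nucleotide alignment
#'
#' One sequence per sampled individual; alleles are identified by their
#' exact sequence. Sequences must be equal length, strictly over
#' \{A, C, G, T\}: indels are completely different from substitutions and
#' cannot be used, and mixed (ambiguity) bases are not considered.
#'
#' @slot seqs character vector of uppercase sequences.
#' @slot ids character vector of record identifiers (duplicates allowed;
#'   identifiers play no role in any computation).
#' @exportClass AlleleAlignment
setClass("AlleleAlignment",
  representation(seqs = "character", ids = "character"))

setValidity("AlleleAlignment", function(object) {
  if (length(object@seqs) < 1L)
    return("alignment is empty: at least one sequence is required")
  if (length(object@ids) != length(object@seqs))
    return("ids and seqs must have the same length")
  ln <- nchar(object@seqs)
  if (any(ln == 0L))
    return("zero-length sequences are not allowed")
  if (length(unique(ln)) != 1L)
    return(sprintf(
      "alignment-length error: sequences have unequal lengths (%s)",
      paste(unique(ln), collapse = ", ")))
  if (any(grepl("[-.+]", object@seqs)))
    return(paste("gap error: gap characters present; indels cannot be",
                 "co-used with substitutions and must be excluded"))
  if (any(grepl("[^ACGT]", object@seqs)))
    return(paste("alphabet error: only A, C, G and T are allowed;",
                 "mixed/ambiguous bases are not considered"))
  TRUE
})

#' Construct an AlleleAlignment from character vectors
#'
#' @param seqs character vector of nucleotide sequences (lowercase is
#'   uppercased; `U` is rejected, not converted).
#' @param ids optional identifiers; defaults to `seq1`, `seq2`, ...
#' @return an [AlleleAlignment-class] object.
#' @examples
#' AlleleAlignment(c("AA", "AA", "AT"))
#' @export
AlleleAlignment <- function(seqs, ids = NULL) {
  seqs <- toupper(as.character(seqs))
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  new("AlleleAlignment", seqs = seqs, ids = as.character(ids))
}

setMethod("show", "AlleleAlignment", function(object) {
  cat("AlleleAlignment:", length(object@seqs), "sequences of length",
      nchar(object@seqs[1L]), "\n")
})

#' Table of distinct alleles with observed counts
#'
#' @slot alleles character vector of distinct sequences, in order of
#'   first appearance in the alignment.
#' @slot counts integer vector of observed copies per allele.
#' @slot n total sample size (`sum(counts)`).
#' @slot l sequence length.
#' @exportClass AlleleTable
setClass("AlleleTable",
  representation(alleles = "character", counts = "integer",
                 n = "integer", l = "integer"))

setValidity("AlleleTable", function(object) {
  if (length(object@alleles) == 0L) return("empty allele table")
  if (anyDuplicated(object@alleles)) return("alleles must be distinct")
  if (length(object@counts) != length(object@alleles))
    return("counts and alleles must align")
  if (any(object@counts < 1L)) return("counts must be positive")
  if (sum(object@counts) != object@n) return("counts must sum to n")
  if (any(nchar(object@alleles) != object@l))
    return("all alleles must have length l")
  TRUE
})

setMethod("show", "AlleleTable", function(object) {
  cat("AlleleTable:", length(object@alleles), "distinct alleles, n =",
      object@n, ", l =", object@l, "\n")
})

#' Kernel specification: bandwidth, length, truncation
#'
#' The bandwidth is the per-base substitution probability `P` in
#' `[0, 1/4)`: at `P = 0` the estimate degenerates to counting, and as
#' `P` approaches 1/4 the kernel approaches the uniform mass function
#' over all sequences. `m` is the mutation number, the truncation radius
#' of the kernel: sequences more than `m` substitutions from a sampled
#' allele receive zero mass from it. With `renormalize = TRUE` (the
#' default) a truncated kernel is rescaled so every sample still
#' contributes total mass 1/n, keeping the estimate a proper mass
#' function.
#'
#' @slot P numeric bandwidth in `[0, 1/4)`.
#' @slot l integer sequence length.
#' @slot m integer mutation number, `0 <= m <= l`.
#' @slot renormalize logical.
#' @exportClass KernelSpec
setClass("KernelSpec",
  representation(P = "numeric", l = "integer", m = "integer",
                 renormalize = "logical"))

setValidity("KernelSpec", function(object) {
  if (length(object@P) != 1L || is.na(object@P) ||
      object@P < 0 || object@P >= 0.25)
    return("bandwidth P must lie in [0, 1/4)")
  if (object@l < 1L) return("sequence length l must be positive")
  if (object@m < 0L || object@m > object@l)
    return("mutation number m must satisfy 0 <= m <= l")
  TRUE
})

#' @param P,l,m,renormalize see slot documentation.
#' @rdname KernelSpec-class
#' @export
KernelSpec <- function(P, l, m = l, renormalize = TRUE) {
  new("KernelSpec", P = as.numeric(P), l = as.integer(l),
      m = as.integer(m), renormalize = isTRUE(renormalize))
}

setMethod("show", "KernelSpec", function(object) {
  cat(sprintf("KernelSpec: P = %g, l = %d, m = %d, renormalize = %s\n",
              object@P, object@l, object@m, object@renormalize))
})

#' Fully materialized nucleotide sequence space
#'
#' All `4^l` sequences of length `l` in lexicographic order (A < C < G <
#' T). Materialization is refused above a guard size because the space
#' grows as `4^l` (a 1,000-bp locus has ~1e602 coordinates).
#'
#' @slot l sequence length.
#' @slot sequences character vector of all `4^l` sequences.
#' @exportClass SequenceSpace
setClass("SequenceSpace",
  representation(l = "integer", sequences = "character"))

setMethod("show", "SequenceSpace", function(object) {
  cat("SequenceSpace: l =", object@l, "(", length(object@sequences),
      "coordinates )\n")
})

#' Compressed distance space over detected alleles
#'
#' Each coordinate is a vector of Hamming distances to the k detected
#' alleles. Detected alleles occupy the first k coordinates and carry
#' their exact mutual distances; undetected coordinates censor any
#' distance exceeding the mutation number `m` to `Inf`, and sequences
#' farther than `m` from every detected allele are dropped from the
#' space entirely. `multiplicity` counts the distinct sequences realizing
#' each coordinate.
#'
#' @slot detected character vector of the k detected alleles (input order).
#' @slot D exact k x k Hamming distance matrix between detected alleles.
#' @slot m mutation number used for truncation.
#' @slot l sequence length.
#' @slot coords numeric matrix, one row per coordinate (entries may be Inf).
#' @slot multiplicity numeric vector of sequence counts per coordinate.
#' @slot members list of character vectors (the sequences realizing each
#'   coordinate) when retained, else an empty list.
#' @exportClass DistanceSpace
setClass("DistanceSpace",
  representation(detected = "character", D = "matrix", m = "integer",
                 l = "integer", coords = "matrix",
                 multiplicity = "numeric", members = "list"))

setValidity("DistanceSpace", function(object) {
  k <- length(object@detected)
  if (k < 1L) return("at least one detected allele is required")
  if (!all(dim(object@D) == c(k, k))) return("D must be k x k")
  if (ncol(object@coords) != k) return("coords must have k columns")
  if (nrow(object@coords) != length(object@multiplicity))
    return("multiplicity must align with coords")
  if (any(!is.finite(object@coords) & !is.infinite(object@coords)))
    return("coordinate entries must be integers or Inf")
  TRUE
})

setMethod("show", "DistanceSpace", function(object) {
  cat(sprintf(
    "DistanceSpace: %d detected alleles, m = %d, %d coordinates (%s sequences)\n",
    length(object@detected), object@m, nrow(object@coords),
    format(sum(object@multiplicity))))
})

#' Estimated allele-frequency mass function
#'
#' Masses are stored on the log scale; exponentiation happens at the
#' reporting accessors. `logPerSeq` is the mass of one individual
#' sequence at the coordinate; `logMass` multiplies in the coordinate's
#' multiplicity.
#'
#' @slot space a [SequenceSpace-class] or [DistanceSpace-class].
#' @slot logMass numeric log total mass per coordinate.
#' @slot logPerSeq numeric log per-sequence mass per coordinate.
#' @slot mass,perSeq the natural-scale masses (exact, not round-tripped
#'   through the log representation, so counting limits hold exactly).
#' @slot spec the [KernelSpec-class] used.
#' @exportClass FrequencyEstimate
setClass("FrequencyEstimate",
  representation(space = "ANY", logMass = "numeric",
                 logPerSeq = "numeric", mass = "numeric",
                 perSeq = "numeric", spec = "KernelSpec"))

setMethod("show", "FrequencyEstimate", function(object) {
  cat(sprintf(
    "FrequencyEstimate: %d coordinates, total mass %.6f (P = %g, m = %d)\n",
    length(object@mass), sum(object@mass),
    object@spec@P, object@spec@m))
})

#' Cross-validation bandwidth selection result
#'
#' @slot method "LSCV" or "LCV".
#' @slot grid candidate bandwidths evaluated.
#' @slot scores criterion value per candidate (LSCV: lower is better;
#'   LCV: higher is better; may be -Inf).
#' @slot selectedP the chosen bandwidth.
#' @slot selectedScore criterion at the chosen bandwidth.
#' @slot fallback TRUE when every LCV score was -Inf and the selection
#'   fell back to P = 0.
#' @exportClass CVResult
setClass("CVResult",
  representation(method = "character", grid = "numeric",
                 scores = "numeric", selectedP = "numeric",
                 selectedScore = "numeric", fallback = "logical"))

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult (%s): selected P = %g (score %g)%s\n",
              object@method, object@selectedP, object@selectedScore,
              if (object@fallback) " [fallback to P = 0]" else ""))
})

#' Nucleotide diversity value
#'
#' @slot pi the diversity estimate (expected pairwise difference
#'   proportion per site; bounded by the Jukes-Cantor ceiling 3/4).
#' @slot terms which pair terms entered the sum: `"all"` or
#'   `"detected_pairs_and_detected_undetected"`.
#' @slot l sequence length.
#' @exportClass DiversityResult
setClass("DiversityResult",
  representation(pi = "numeric", terms = "character", l = "integer"))

setValidity("DiversityResult", function(object) {
  if (object@pi < -1e-12 || object@pi > 0.75 + 1e-12)
    return("pi must lie in [0, 0.75]")
  TRUE
})

setMethod("show", "DiversityResult", function(object) {
  cat(sprintf("DiversityResult: pi = %.7f (terms: %s)\n",
              object@pi, object@terms))
})

#' Simulated population: sequences plus genealogy
#'
#' @slot alignment the [AlleleAlignment-class] of N population sequences.
#' @slot tree the coalescent genealogy (an [ape::rtree()]-style `phylo`).
#' @slot branchMutations number of substituted sites per edge of `tree`.
#' @slot mu mutation rate used.
#' @slot timescale "coalescent" or "generations".
#' @exportClass SimPopulation
setClass("SimPopulation",
  representation(alignment = "AlleleAlignment", tree = "ANY",
                 branchMutations = "numeric", mu = "numeric",
                 timescale = "character"))

setMethod("show", "SimPopulation", function(object) {
  cat(sprintf(
    "SimPopulation: N = %d, l = %d, mu = %g (%s timescale)\n",
    length(object@alignment@seqs), nchar(object@alignment@seqs[1L]),
    object@mu, object@timescale))
})
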