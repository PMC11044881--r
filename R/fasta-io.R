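#' Read a FASTA alignment of equal-length gap-free sequences
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines) and
#' validates the alignment constraints: all sequences equal length, no
#' gaps (indels are completely different from substitutions and cannot
#' be co-used with them) and no ambiguity codes (mixed bases are not
#' considered). Lowercase input is uppercased; `U` is rejected rather
#' than converted, as only DNA is supported.
#'
#' @param path path to a FASTA file.
#' @return an [AlleleAlignment-class] with record order preserved.
#' @seealso [writeAlignment()], [tallyAlleles()]
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">1", "AA", ">2", "AT"), fa)
#' readAlignment(fa)
#' @export
readAlignment <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("could not parse FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    stop("empty-input error: no FASTA records in '", path, "'")
  seqs <- toupper(as.character(set))
  if (any(grepl("U", seqs, fixed = TRUE)))
    stop("alphabet error: 'U' found; RNA is not supported and U is not ",
         "converted to T")
  aln <- tryCatch(
    new("AlleleAlignment", seqs = unname(seqs), ids = names(set)),
    error = function(e) stop(conditionMessage(e), call. = FALSE))
  aln
}

#' Write an alignment to FASTA
#'
#' @param aln an [AlleleAlignment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(aln, path) {
  stopifnot(is(aln, "AlleleAlignment"))
  set <- Biostrings::DNAStringSet(stats::setNames(aln@seqs, aln@ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Collapse an alignment into distinct alleles with counts
#'
#' Alleles are identified by exact sequence; the returned table lists
#' each distinct sequence with the number of sampled individuals
#' carrying it. These counts divided by `n` are the plain counting
#' allele frequencies (the estimate obtained with mutation number 0,
#' i.e. without any kernel smoothing).
#'
#' @param aln an [AlleleAlignment-class].
#' @return an [AlleleTable-class]; counts sum to the number of records,
#'   alleles ordered by first appearance.
#' @examples
#' tallyAlleles(AlleleAlignment(c("AA", "AA", "AA", "AT", "AT", "AT")))
#' @export
tallyAlleles <- function(aln) {
  stopifnot(is(aln, "AlleleAlignment"))
  if (length(aln@seqs) == 0L) stop("empty-input error: no sequences")
  al <- unique(aln@seqs)
  cnt <- as.integer(table(factor(aln@seqs, levels = al)))
  new("AlleleTable", alleles = al, counts = cnt,
      n = length(aln@seqs), l = nchar(al[1L]))
}

#' Hamming distance between two equal-length sequences
#'
#' The distance between alleles is the number of substitutions between
#' them: the count of mismatching positions.
#'
#' @param a,b character scalars of equal length.
#' @return non-negative integer; 0 iff identical.
#' @examples
#' hammingDistance("AAA", "ATT")  # 2
#' @export
hammingDistance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("length mismatch: sequences must have equal length")
  sum(charToRaw(a) != charToRaw(b))
}

# All pairwise Hamming distances among a character vector of sequences.
hammingMatrix <- function(seqs) {
  k <- length(seqs)
  M <- seqToIntMatrix(seqs)
  D <- matrix(0L, k, k)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      rest <- (i + 1L):k
      d <- rowSums(M[rest, , drop = FALSE] !=
                     matrix(M[i, ], length(rest), ncol(M), byrow = TRUE))
      D[i, rest] <- d
      D[rest, i] <- d
    }
  }
  D
}
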