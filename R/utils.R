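# Internal numerical helpers.

#' Numerically stable log(sum(exp(x)))
#'
#' @param x numeric vector of log-scale values (may contain -Inf).
#' @return log of the summed exponentials.
#' @keywords internal
#' @noRd
logSumExp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`
# (NULL = use the session RNG as-is). The caller's RNG state is restored.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Split a master seed into `n` independent sub-seeds (< 2^31), documented
# splitting scheme: one draw stream seeded by the master seed.
splitSeed <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.BASES <- c("A", "C", "G", "T")

# character vector of sequences -> integer matrix (rows = sequences)
seqToIntMatrix <- function(seqs) {
  l <- nchar(seqs[1L])
  m <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)), .BASES),
              nrow = length(seqs), ncol = l, byrow = TRUE)
  m
}

intRowToSeq <- function(row) paste(.BASES[row], collapse = "")
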