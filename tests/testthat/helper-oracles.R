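# Independent brute-force oracles. Everything here enumerates the full
# 4^l sequence space or iterates elementary definitions directly, and
# deliberately shares no code path with the package internals.

BASES <- c("A", "C", "G", "T")

enumSeqs <- function(l) {
  g <- do.call(expand.grid,
               c(rep(list(BASES), l),
                 KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  do.call(paste0, rev(as.list(g)))
}

hd <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# 4-state Jukes-Cantor transition matrix powered g times: the
# recurrence oracle for substitutionProbability.
transitionPower <- function(g, mu) {
  M <- matrix(mu / 3, 4, 4)
  diag(M) <- 1 - mu
  out <- diag(4)
  for (i in seq_len(g)) out <- out %*% M
  out
}

# Per-sequence kernel mass from the raw definition.
bruteKernel <- function(P, l, m, renorm = TRUE) {
  q <- function(x) if (x > m) 0 else (1 - 3 * P)^(l - x) * P^x
  tot <- sum(vapply(0:m, function(x) choose(l, x) * 3^x * q(x), 1))
  function(x) if (renorm) q(x) / tot else q(x)
}

# Full-enumeration KDE: named per-sequence mass over all 4^l sequences.
bruteKDE <- function(alleles, counts, P, l, m, renorm = TRUE) {
  seqs <- enumSeqs(l)
  n <- sum(counts)
  qq <- bruteKernel(P, l, m, renorm)
  mass <- vapply(seqs, function(s)
    sum(counts * vapply(alleles, function(a) qq(hd(s, a)), 1)) / n, 1)
  stats::setNames(mass, seqs)
}

# Full-enumeration distance space: censored coordinates, multiplicities
# and member sequences, keyed by the coordinate string. Detected
# alleles keep their exact (uncensored) distance vectors.
bruteDistanceSpace <- function(alleles, m) {
  l <- nchar(alleles[1])
  seqs <- enumSeqs(l)
  dv <- do.call(cbind, lapply(alleles, function(a)
    vapply(seqs, hd, 1, b = a)))
  detIdx <- match(alleles, seqs)
  cd <- dv
  cd[cd > m] <- Inf
  keep <- apply(cd, 1, function(r) any(is.finite(r)))
  keep[detIdx] <- FALSE
  ukeys <- apply(cd[keep, , drop = FALSE], 1, paste, collapse = ",")
  mult <- table(ukeys)
  members <- split(seqs[keep], ukeys)
  detKeys <- apply(dv[detIdx, , drop = FALSE], 1, paste, collapse = ",")
  list(detKeys = detKeys, undetMult = mult, members = members)
}

bruteLOO <- function(alleles, counts, P, l, m, i, renorm = TRUE) {
  n <- sum(counts)
  j <- rep(seq_along(counts), counts)[i]
  c2 <- counts
  c2[j] <- c2[j] - 1
  qq <- bruteKernel(P, l, m, renorm)
  sum(c2 * vapply(alleles, function(a) qq(hd(alleles[j], a)), 1)) / (n - 1)
}

bruteLSCV <- function(alleles, counts, P, l, m, renorm = TRUE) {
  n <- sum(counts)
  mass <- bruteKDE(alleles, counts, P, l, m, renorm)
  loo <- vapply(seq_len(n), function(i)
    bruteLOO(alleles, counts, P, l, m, i, renorm), 1)
  sum(mass^2) - (2 / n) * sum(loo)
}

bruteLCV <- function(alleles, counts, P, l, m, renorm = TRUE) {
  n <- sum(counts)
  loo <- vapply(seq_len(n), function(i)
    bruteLOO(alleles, counts, P, l, m, i, renorm), 1)
  if (any(loo <= 0)) return(-Inf)
  sum(log(loo))
}

brutePi <- function(freqs, l) {
  al <- names(freqs)
  tot <- 0
  for (i in seq_along(al)) for (j in seq_along(al))
    tot <- tot + freqs[[i]] * freqs[[j]] * hd(al[i], al[j]) / l
  tot
}

randomAlleles <- function(l, k) {
  out <- character(0)
  while (length(out) < k)
    out <- unique(c(out, paste(sample(BASES, l, TRUE), collapse = "")))
  out[seq_len(k)]
}

writeTempFasta <- function(lines) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(lines, fa)
  fa
}

# Compare a package DistanceSpace against the brute-force enumeration.
expectSpaceMatchesBrute <- function(alleles, m) {
  sp <- buildDistanceSpace(alleles, m)
  bf <- bruteDistanceSpace(alleles, m)
  k <- length(alleles)
  co <- coordinates(sp)
  keys <- apply(co, 1, paste, collapse = ",")
  expect_identical(unname(keys[seq_len(k)]), unname(bf$detKeys))
  ukeys <- keys[-seq_len(k)]
  expect_setequal(ukeys, names(bf$undetMult))
  expect_equal(unname(multiplicities(sp)[-seq_len(k)]),
               unname(as.numeric(bf$undetMult[ukeys])))
  if (length(sp@members) > 0) {
    for (r in seq_along(ukeys))
      expect_setequal(sp@members[[k + r]], bf$members[[ukeys[r]]])
  }
  invisible(sp)
}
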