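test_that("exact nucleotide diversity matches the pairwise double sum", {
  expect_equal(piValue(nucleotideDiversityExact(c(AA = 0.5, AT = 0.5))), 0.25)
  expect_equal(piValue(nucleotideDiversityExact(c(ACGT = 1))), 0)
  expect_error(nucleotideDiversityExact(c(AA = 0.5, AT = 0.4)),
               "frequency sum")
  set.seed(8)
  al <- randomAlleles(6, 4)
  p <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(piValue(nucleotideDiversityExact(stats::setNames(p, al))),
               brutePi(stats::setNames(p, al), 6), tolerance = 1e-12)
  # counting frequencies from an AlleleTable give the same double sum
  tab <- tallyAlleles(AlleleAlignment(rep(al, c(4, 3, 2, 1))))
  expect_equal(piValue(nucleotideDiversityExact(tab)),
               brutePi(stats::setNames(c(.4, .3, .2, .1), al), 6))
})

test_that("approximate diversity reduces to the exact value without smoothing", {
  tab <- tallyAlleles(AlleleAlignment(rep(c("ACG", "ATG", "CCC"), c(3, 2, 1))))
  est <- estimateFrequencies(tab, KernelSpec(0, 3, 0))
  expect_equal(piValue(nucleotideDiversityApprox(est)),
               piValue(nucleotideDiversityExact(tab)), tolerance = 1e-12)
})

test_that("all-terms diversity equals the exact sequence-space computation", {
  set.seed(19)
  for (cs in list(list(l = 3, k = 3, m = 3), list(l = 4, k = 3, m = 2),
                  list(l = 4, k = 2, m = 4))) {
    al <- randomAlleles(cs$l, cs$k)
    cnt <- sample(1:3, cs$k, TRUE)
    tab <- tallyAlleles(AlleleAlignment(rep(al, cnt)))
    sp <- buildDistanceSpace(al, cs$m)
    for (P in c(0.04, 0.2)) {
      est <- estimateFrequencies(tab, KernelSpec(P, cs$l, cs$m), sp)
      seqs <- unlist(sp@members)
      p <- rep(perSequenceMass(est), times = lengths(sp@members))
      exact <- brutePi(stats::setNames(p, seqs), cs$l)
      expect_equal(piValue(nucleotideDiversityApprox(est, allTerms = TRUE)),
                   exact, tolerance = 1e-10)
      # dropping undetected-undetected terms can only lower the value
      expect_lte(piValue(nucleotideDiversityApprox(est)), exact + 1e-12)
    }
  }
})

test_that("censored coordinates recover their mean distance combinatorially", {
  # With two detected alleles the coordinate censored w.r.t. the other
  # allele holds exactly the shell sequences beyond the truncation, so
  # the combinatoric recovery must reproduce the true member distances.
  al <- c("AAAAA", "GGGGG")
  tab <- tallyAlleles(AlleleAlignment(rep(al, c(3, 2))))
  sp <- buildDistanceSpace(al, 2)
  est <- estimateFrequencies(tab, KernelSpec(0.08, 5, 2), sp)
  w <- freqMass(est)
  k <- 2
  manual <- as.numeric(w[1:k] %*% sp@D %*% w[1:k]) / 5
  for (r in (k + 1):nrow(coordinates(sp))) {
    mem <- sp@members[[r]]
    pc <- perSequenceMass(est)[r]
    for (i in 1:k) for (s in mem)
      manual <- manual + 2 * w[i] * pc * hd(s, al[i]) / 5
  }
  expect_equal(piValue(nucleotideDiversityApprox(est)), manual,
               tolerance = 1e-10)
  # for k > 2 the recovery conditions on one allele at a time, so it is
  # an approximation; it must stay within the feasible distance range
  al3 <- c("AAAAA", "AATAA", "GGGGG")
  t3 <- tallyAlleles(AlleleAlignment(rep(al3, each = 2)))
  sp3 <- buildDistanceSpace(al3, 1)
  e3 <- estimateFrequencies(t3, KernelSpec(0.1, 5, 1), sp3)
  expect_gt(piValue(nucleotideDiversityApprox(e3)), 0)
  expect_lte(piValue(nucleotideDiversityApprox(e3)),
             piValue(nucleotideDiversityApprox(e3, allTerms = TRUE)) + 1e-12)
})

test_that("concordance rate behaves as one minus total variation", {
  tab <- tallyAlleles(AlleleAlignment(rep(c("AA", "AT"), each = 3)))
  est <- estimateFrequencies(tab, KernelSpec(0, 2, 0))
  # identical distributions
  expect_equal(concordanceRate(c(AA = 0.5, AT = 0.5), est), 1)
  # the published counting example
  expect_equal(concordanceRate(c(AA = 0.6, AT = 0.4), est), 0.8)
  # disjoint supports
  expect_equal(concordanceRate(c(GG = 0.7, CC = 0.3), est), -1)
  # population alleles inside the smoothed space are matched by coordinate
  sp <- buildDistanceSpace(alleles(tab), 1)
  est1 <- estimateFrequencies(tab, KernelSpec(0.05, 2, 1), sp)
  truth <- c(AA = 0.5, AT = 0.3, AG = 0.1, GG = 0.1)
  got <- concordanceRate(truth, est1)
  # manual: AG maps to coordinate (1,1); GG is outside the m=1 space
  w <- freqMass(est1)
  key <- apply(coordinates(sp), 1, paste, collapse = ",")
  f <- numeric(length(w))
  f[1] <- 0.5; f[2] <- 0.3; f[match("1,1", key)] <- 0.1
  expect_equal(got, 1 - (sum(abs(f - w)) + 0.1), tolerance = 1e-12)
  expect_lte(got, 1)
})

test_that("replicate evaluation statistics follow their definitions", {
  st <- evaluationStats(c(1, 1, 1), 1)
  expect_equal(st$relativeBias, 0)
  expect_equal(st$accuracy, 0)
  st2 <- evaluationStats(c(0.9, 1.1) * 3, 3)
  expect_equal(st2$relativeBias, 0)
  expect_equal(st2$accuracy, 0.1)
  expect_equal(st2$squaredAccuracy, 0.01)
  expect_error(evaluationStats(1:3, 0), "nonzero")
  set.seed(4)
  x <- rlnorm(20)
  st3 <- evaluationStats(x, 1.3)
  expect_gte(st3$accuracy, abs(st3$relativeBias))
})
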