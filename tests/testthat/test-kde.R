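fixtureTable <- function() tallyAlleles(AlleleAlignment(rep(c("AA", "AT"), each = 3)))

test_that("P = 0 and m = 0 both reduce the estimate to counting frequencies", {
  tab <- fixtureTable()
  for (spec in list(KernelSpec(0, 2), KernelSpec(0.2, 2, m = 0))) {
    est <- estimateFrequencies(tab, spec)
    mass <- freqMass(est)
    k <- length(alleles(tab))
    expect_equal(unname(mass[seq_len(k)]), c(0.5, 0.5))
    expect_equal(sum(mass[-seq_len(k)]), 0)
  }
  # sequence-space route agrees
  est <- estimateFrequencies(tab, KernelSpec(0, 2), buildSequenceSpace(2))
  m <- stats::setNames(freqMass(est), sequences(est@space))
  expect_equal(unname(m[c("AA", "AT")]), c(0.5, 0.5))
  expect_equal(sum(m), 1)
})

test_that("smoothing ranks undetected alleles by proximity to the sample", {
  # alleles one step from both detected alleles outrank the far corner
  tab <- fixtureTable()
  for (P in c(0.01, 0.1, 0.2)) {
    est <- estimateFrequencies(tab, KernelSpec(P, 2), buildSequenceSpace(2))
    m <- stats::setNames(freqMass(est), sequences(est@space))
    expect_equal(m[["AG"]], m[["AC"]])
    expect_gt(m[["AG"]], m[["GG"]])
  }
})

test_that("estimates are normalized and agree with brute-force enumeration", {
  set.seed(23)
  for (cs in list(list(l = 3, k = 3, m = 1), list(l = 4, k = 3, m = 2),
                  list(l = 5, k = 3, m = 5))) {
    al <- randomAlleles(cs$l, cs$k)
    cnt <- sample(1:4, cs$k, TRUE)
    tab <- tallyAlleles(AlleleAlignment(rep(al, cnt)))
    sp <- buildDistanceSpace(al, cs$m)
    for (P in c(0, 0.03, 0.22)) {
      spec <- KernelSpec(P, cs$l, cs$m)
      est <- estimateFrequencies(tab, spec, sp)
      expect_equal(sum(freqMass(est)), 1, tolerance = 1e-9)
      bf <- bruteKDE(al, cnt, P, cs$l, cs$m)
      ps <- perSequenceMass(est)
      for (r in seq_along(sp@members))
        expect_equal(unname(ps[r] + numeric(length(sp@members[[r]]))),
                     unname(bf[sp@members[[r]]]), tolerance = 1e-10)
    }
  }
})

test_that("detected-allele mass decreases as the bandwidth grows", {
  tab <- fixtureTable()
  sp <- buildDistanceSpace(alleles(tab), 2)
  detMass <- vapply(c(0, 0.01, 0.05, 0.1, 0.2, 0.24), function(P) {
    est <- estimateFrequencies(tab, KernelSpec(P, 2), sp)
    sum(freqMass(est)[1:2])
  }, 1)
  expect_true(all(diff(detMass) < 0))
})

test_that("leave-one-out density follows the counting closed forms", {
  tab <- fixtureTable()
  expect_equal(looDensity(tab, KernelSpec(0, 2), 1), 2 / 5)
  expect_equal(looDensity(tab, KernelSpec(0, 2), 6), 2 / 5)
  two <- tallyAlleles(AlleleAlignment(c("AA", "AT")))
  expect_equal(looDensity(two, KernelSpec(0, 2), 1), 0)
  expect_equal(looDensity(two, KernelSpec(0.1, 2), 1),
               kernelMassPerSequence(KernelSpec(0.1, 2), 1))
  expect_error(looDensity(tallyAlleles(AlleleAlignment("AA")),
                          KernelSpec(0, 2), 1), "n < 2")
  # brute-force agreement
  set.seed(3)
  al <- randomAlleles(3, 3)
  cnt <- c(2, 2, 1)
  t3 <- tallyAlleles(AlleleAlignment(rep(al, cnt)))
  for (i in c(1, 3, 5))
    expect_equal(looDensity(t3, KernelSpec(0.08, 3, 2), i),
                 bruteLOO(al, cnt, 0.08, 3, 2, i), tolerance = 1e-12)
})

test_that("cross-validation criteria match definitions and closed forms", {
  tab <- fixtureTable()
  # LSCV counting limit closed form
  n <- 6
  expected0 <- sum((c(3, 3) / n)^2) - (2 / n) * sum(c(3, 3) * (c(3, 3) - 1) / (n - 1)) / 1
  expect_equal(lscvScore(tab, KernelSpec(0, 2)), expected0)
  # LCV counting closed form
  expect_equal(lcvScore(tab, KernelSpec(0, 2)), 6 * log(2 / 5))
  # n = 2 distinct alleles: held-out mass vanishes at P = 0
  two <- tallyAlleles(AlleleAlignment(c("AA", "AT")))
  expect_identical(lcvScore(two, KernelSpec(0, 2)), -Inf)
  # finite iff every singleton is within m of another sampled allele
  near <- tallyAlleles(AlleleAlignment(c("AAA", "AAT", "ATT")))
  far <- tallyAlleles(AlleleAlignment(c("AAA", "TTT", "GGG")))
  expect_true(is.finite(lcvScore(near, KernelSpec(0.1, 3, 1))))
  expect_identical(lcvScore(far, KernelSpec(0.1, 3, 1)), -Inf)
  # LSCV finite across the bandwidth range
  for (P in c(0, 1e-6, 0.1, 0.2499 - 1e-9))
    expect_true(is.finite(lscvScore(tab, KernelSpec(P, 2))))
  # brute-force agreement on a mixed sample, distance and sequence space
  set.seed(41)
  al <- randomAlleles(4, 3)
  cnt <- c(3, 2, 1)
  t4 <- tallyAlleles(AlleleAlignment(rep(al, cnt)))
  for (m in c(1, 4)) for (P in c(0.02, 0.2)) {
    expect_equal(lscvScore(t4, KernelSpec(P, 4, m)),
                 bruteLSCV(al, cnt, P, 4, m), tolerance = 1e-10)
    expect_equal(lscvScore(t4, KernelSpec(P, 4, m), buildSequenceSpace(4)),
                 bruteLSCV(al, cnt, P, 4, m), tolerance = 1e-10)
    expect_equal(lcvScore(t4, KernelSpec(P, 4, m)),
                 bruteLCV(al, cnt, P, 4, m), tolerance = 1e-10)
  }
})

test_that("bandwidth selection finds the fine-grid optimum deterministically", {
  set.seed(12)
  al <- randomAlleles(4, 4)
  cnt <- c(4, 3, 2, 2)  # no singletons: LCV stays finite at every P
  tab <- tallyAlleles(AlleleAlignment(rep(al, cnt)))
  sp <- buildDistanceSpace(al, 2, keepSequences = FALSE)
  fine <- seq(0, 0.2499, by = 1e-4)
  lscvFine <- vapply(fine, function(P)
    lscvScore(tab, KernelSpec(P, 4, 2), sp), 1)
  cv <- selectBandwidth(tab, 2, "LSCV", space = sp)
  expect_lt(abs(selectedBandwidth(cv) - fine[which.min(lscvFine)]), 1e-3)
  lcvFine <- vapply(fine, function(P) lcvScore(tab, KernelSpec(P, 4, 2)), 1)
  cvL <- selectBandwidth(tab, 2, "LCV")
  expect_lt(abs(selectedBandwidth(cvL) - fine[which.max(lcvFine)]), 1e-3)
  # determinism
  expect_equal(selectBandwidth(tab, 2, "LSCV", space = sp), cv)
  # m = 0: criterion flat in P, ties resolve to the smallest candidate
  cv0 <- selectBandwidth(tab, 0, "LSCV")
  expect_equal(selectedBandwidth(cv0), 0)
})

test_that("LCV falls back to P = 0 when no bandwidth gives finite likelihood", {
  far <- tallyAlleles(AlleleAlignment(c("AAAA", "TTTT", "GGGG")))
  expect_warning(cv <- selectBandwidth(far, 1, "LCV"), "falling back")
  expect_true(cv@fallback)
  expect_equal(selectedBandwidth(cv), 0)
})
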