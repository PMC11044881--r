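test_that("sequence space enumerates lexicographically and guards capacity", {
  expect_identical(sequences(buildSequenceSpace(1)), c("A", "C", "G", "T"))
  s2 <- sequences(buildSequenceSpace(2))
  expect_length(s2, 16L)
  expect_identical(s2[1], "AA")
  expect_identical(s2[16], "TT")
  expect_identical(s2, sort(s2))
  expect_error(buildSequenceSpace(11), "guard")
  expect_error(buildSequenceSpace(3, maxSize = 10), "guard")
})

test_that("distance space reproduces the published worked examples", {
  sp <- buildDistanceSpace(c("AA", "AT"), 2)
  expect_equal(coordinates(sp),
               rbind(c(0, 1), c(1, 0), c(1, 1), c(1, 2), c(2, 1), c(2, 2)))
  expect_equal(multiplicities(sp), c(1, 1, 2, 3, 3, 6))

  sp1 <- buildDistanceSpace(c("AAA", "AAT", "GGG"), 1)
  expect_equal(coordinates(sp1),
               rbind(c(0, 1, 3), c(1, 0, 3), c(3, 3, 0), c(1, 1, Inf),
                     c(1, Inf, Inf), c(Inf, 1, Inf), c(Inf, Inf, 1)))
  expect_equal(multiplicities(sp1), c(1, 1, 1, 2, 6, 6, 9))
})

test_that("coordinate multiplicity counts the realizing sequences", {
  sp <- buildDistanceSpace(c("AA", "AT"), 2)
  expect_equal(coordinateMultiplicity(sp, c(1, 1)), 2)
  expect_setequal(sp@members[[3]], c("AG", "AC"))
  expect_equal(coordinateMultiplicity(sp, c(0, 1)), 1)
  expect_error(coordinateMultiplicity(sp, c(2, 0)), "lookup")

  sp1 <- buildDistanceSpace(c("AAA", "AAT", "GGG"), 1)
  brute <- bruteDistanceSpace(c("AAA", "AAT", "GGG"), 1)
  expect_equal(coordinateMultiplicity(sp1, c(1, 1, Inf)),
               as.numeric(brute$undetMult[["1,1,Inf"]]))
})

test_that("m = 0 collapses the space to the detected alleles", {
  al <- c("ACGT", "TTTT", "ACGA")
  sp <- buildDistanceSpace(al, 0)
  expect_identical(nrow(coordinates(sp)), 3L)
  expect_equal(multiplicities(sp), rep(1, 3))
  expect_equal(coordinates(sp)[1, ], c(0, 3, 1))
})

test_that("distance space equals brute-force enumeration across random cases", {
  set.seed(31)
  cases <- list(
    list(l = 2, k = 2, m = 1), list(l = 3, k = 3, m = 1),
    list(l = 3, k = 3, m = 3), list(l = 4, k = 3, m = 2),
    list(l = 4, k = 4, m = 4), list(l = 5, k = 3, m = 2),
    list(l = 5, k = 2, m = 5))
  for (cs in cases) {
    al <- randomAlleles(cs$l, cs$k)
    sp <- expectSpaceMatchesBrute(al, cs$m)
    if (cs$m >= cs$l)  # untruncated: whole space is covered
      expect_equal(sum(multiplicities(sp)), 4^cs$l)
  }
  # degenerate: every length-1 sequence detected
  sp <- buildDistanceSpace(c("A", "C", "G", "T"), 1)
  expect_identical(nrow(coordinates(sp)), 4L)
})

test_that("joint distance counts match exhaustive neighbourhood enumeration", {
  expect_equal(jointDistanceCounts(1, 2, 1), c(`0` = 1, `1` = 2, `2` = 3))
  # identical centers: all mass at distance x
  expect_equal(jointDistanceCounts(0, 5, 2), c(`2` = choose(5, 2) * 9))
  expect_error(jointDistanceCounts(3, 2, 1), "domain")

  set.seed(17)
  for (l in c(3, 4, 6)) {
    A <- paste(rep("A", l), collapse = "")
    for (d in 0:l) {
      B <- paste(c(rep("T", d), rep("A", l - d)), collapse = "")
      seqs <- enumSeqs(l)
      dA <- vapply(seqs, hd, 1, b = A)
      dB <- vapply(seqs, hd, 1, b = B)
      for (x in 0:l) {
        got <- jointDistanceCounts(d, l, x)
        want <- table(dB[dA == x])
        expect_equal(sum(got), choose(l, x) * 3^x)
        expect_equal(as.numeric(got), as.numeric(want[names(got)]))
      }
    }
  }
})

test_that("distance-space TSV dump writes Inf entries and frequencies", {
  sp <- buildDistanceSpace(c("AAA", "AAT", "GGG"), 1)
  tab <- tallyAlleles(AlleleAlignment(c("AAA", "AAA", "AAT", "GGG")))
  est <- estimateFrequencies(tab, KernelSpec(0.05, 3, 1), sp)
  out <- tempfile(fileext = ".tsv")
  writeDistanceSpace(sp, out, est)
  got <- utils::read.delim(out)
  expect_identical(names(got),
                   c("d_1", "d_2", "d_3", "multiplicity", "frequency",
                     "per_sequence_frequency"))
  expect_equal(got$d_3[4], Inf)
  expect_equal(sum(got$frequency), 1, tolerance = 1e-9)
})
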