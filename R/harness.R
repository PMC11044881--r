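# Experiment harness: simulate populations, resample, estimate, and
# score bias/accuracy/concordance of the KDE pipeline against the known
# population, over a grid of mutation rates, sample sizes, mutation
# numbers and CV methods. One population is simulated per
# (mutation rate, replicate) and shared across sample sizes, mutation
# numbers and CV methods, so comparisons within a replicate are paired.

#' Run the simulation experiment grid
#'
#' For every grid cell and replicate: simulate a population, subsample
#' it, select the bandwidth (skipped at mutation number 0, which is
#' plain counting), estimate the allele frequencies on the distance
#' space, and record the approximate nucleotide diversity and the
#' concordance rate against the true population frequencies. Fully
#' deterministic given `seed` (one documented seed split drives every
#' random step). Cells with a sample size above the population size are
#' skipped with a warning.
#'
#' @param populationSize number of sequences per simulated population.
#' @param seqLength sequence length in bp.
#' @param mu mutation rate(s) per base per time unit; one population set
#'   per rate.
#' @param sampleSizes sample sizes drawn without replacement.
#' @param mutationNumbers kernel truncation radii; 0 means no KDE.
#' @param cvMethods bandwidth selectors used for positive mutation
#'   numbers.
#' @param replicates populations (and samples) per rate.
#' @param seed master integer seed.
#' @param timescale passed to [simulatePopulation()].
#' @param renormalize renormalize truncated kernels (default `TRUE`).
#' @param verbose emit per-cell progress messages.
#' @return long-format `data.frame`, one row per
#'   (mu, replicate, sampleSize, mutationNumber, method): columns
#'   `selectedP`, `fallback`, `piHat`, `piPop`, `concordance`.
#' @seealso [summarizeExperiment()], [compareCells()]
#' @export
runExperimentGrid <- function(populationSize = 100, seqLength = 200,
                              mu = 0.01, sampleSizes = c(20, 100),
                              mutationNumbers = c(0, 1),
                              cvMethods = c("LSCV", "LCV"),
                              replicates = 20, seed = 1,
                              timescale = c("coalescent", "generations"),
                              renormalize = TRUE, verbose = FALSE) {
  timescale <- match.arg(timescale)
  nPop <- length(mu) * replicates
  seeds <- matrix(splitSeed(seed, nPop * (1 + length(sampleSizes))),
                  nrow = nPop)
  rows <- list()
  popIdx <- 0L
  for (rate in mu) {
    for (rep in seq_len(replicates)) {
      popIdx <- popIdx + 1L
      pop <- simulatePopulation(populationSize, seqLength, rate,
                                seed = seeds[popIdx, 1L],
                                timescale = timescale)
      popTab <- tallyAlleles(pop@alignment)
      popFreq <- stats::setNames(popTab@counts / popTab@n, popTab@alleles)
      piPop <- piValue(nucleotideDiversityExact(popFreq))
      for (si in seq_along(sampleSizes)) {
        k <- sampleSizes[si]
        if (k > populationSize) {
          warning("skipping infeasible cell: sample size ", k,
                  " exceeds population size ", populationSize)
          next
        }
        samp <- resampleAlignment(pop@alignment, k,
                                  seed = seeds[popIdx, 1L + si])
        sTab <- tallyAlleles(samp)
        for (m in sort(unique(as.integer(mutationNumbers)))) {
          space <- buildDistanceSpace(sTab@alleles, m,
                                      keepSequences = FALSE)
          if (m == 0L) {
            spec <- KernelSpec(0, seqLength, 0, renormalize)
            est <- estimateFrequencies(sTab, spec, space)
            rows[[length(rows) + 1L]] <- data.frame(
              mu = rate, replicate = rep, sampleSize = k,
              mutationNumber = m, method = "none", selectedP = 0,
              fallback = FALSE,
              piHat = piValue(nucleotideDiversityApprox(est)),
              piPop = piPop,
              concordance = concordanceRate(popFreq, est))
          } else {
            for (method in cvMethods) {
              cv <- selectBandwidth(sTab, m, method, space = space,
                                    renormalize = renormalize)
              spec <- KernelSpec(cv@selectedP, seqLength, m, renormalize)
              est <- estimateFrequencies(sTab, spec, space)
              rows[[length(rows) + 1L]] <- data.frame(
                mu = rate, replicate = rep, sampleSize = k,
                mutationNumber = m, method = method,
                selectedP = cv@selectedP, fallback = cv@fallback,
                piHat = piValue(nucleotideDiversityApprox(est)),
                piPop = piPop,
                concordance = concordanceRate(popFreq, est))
            }
          }
          if (verbose)
            message(sprintf("mu=%g rep=%d k=%d m=%d done", rate, rep, k, m))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize an experiment report per grid cell
#'
#' Aggregates the long-format report of [runExperimentGrid()] into one
#' row per (mu, sampleSize, mutationNumber, method) cell: relative bias,
#' accuracy and squared accuracy of the diversity estimate against each
#' replicate's own population value, their standard deviations, the
#' mean concordance rate and the mean selected bandwidth.
#'
#' @param report output of [runExperimentGrid()].
#' @return a `data.frame`, one row per cell.
#' @export
summarizeExperiment <- function(report) {
  key <- interaction(report$mu, report$sampleSize, report$mutationNumber,
                     report$method, drop = TRUE)
  out <- lapply(split(report, key), function(cell) {
    st <- evaluationStats(cell$piHat, cell$piPop)
    cbind(cell[1L, c("mu", "sampleSize", "mutationNumber", "method")],
          st,
          meanConcordance = mean(cell$concordance),
          sdConcordance = stats::sd(cell$concordance),
          meanSelectedP = mean(cell$selectedP),
          fallbackRate = mean(cell$fallback))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$mu, out$sampleSize, out$mutationNumber, out$method), ]
}

#' Paired comparison of two grid cells
#'
#' Pairs the replicates of two cells sharing (mu, sampleSize) and
#' returns the per-replicate differences of a statistic, e.g. the
#' absolute relative error of diversity at mutation number 1 minus that
#' at mutation number 0.
#'
#' @param report output of [runExperimentGrid()].
#' @param cellA,cellB named lists selecting cells, e.g.
#'   `list(mutationNumber = 1, method = "LSCV")`; unspecified fields are
#'   unrestricted but the two cells must pair one-to-one by
#'   (mu, sampleSize, replicate).
#' @param statistic `"pi_accuracy"` (per-replicate `|piHat - piPop| /
#'   piPop`), `"pi_bias"` (signed relative error) or `"concordance"`.
#' @return list with `differences` (per-pair `data.frame` with column
#'   `diff` = A - B), `mean` and `sd`.
#' @export
compareCells <- function(report, cellA, cellB,
                         statistic = c("pi_accuracy", "pi_bias",
                                       "concordance")) {
  statistic <- match.arg(statistic)
  pick <- function(cell) {
    sel <- rep(TRUE, nrow(report))
    for (f in names(cell)) sel <- sel & report[[f]] == cell[[f]]
    report[sel, , drop = FALSE]
  }
  a <- pick(cellA)
  b <- pick(cellB)
  keyOf <- function(d) paste(d$mu, d$sampleSize, d$replicate, sep = "|")
  ka <- keyOf(a); kb <- keyOf(b)
  if (anyDuplicated(ka) || anyDuplicated(kb) || !setequal(ka, kb))
    stop("mismatched pairing: cells must pair one-to-one by ",
         "(mu, sampleSize, replicate)")
  b <- b[match(ka, kb), , drop = FALSE]
  statOf <- function(d) switch(statistic,
    pi_accuracy = abs(d$piHat - d$piPop) / d$piPop,
    pi_bias = (d$piHat - d$piPop) / d$piPop,
    concordance = d$concordance)
  diff <- statOf(a) - statOf(b)
  list(differences = data.frame(mu = a$mu, sampleSize = a$sampleSize,
                                replicate = a$replicate, diff = diff),
       mean = mean(diff), sd = stats::sd(diff))
}
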