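# Single-deme coalescent population generator with finite-sites
# Jukes-Cantor mutation. Replaces external ms/Seq-Gen style pipelines
# with a built-in simulator sharing the substitution engine of the
# kernel: a branch of length b contributes substitution probability
# P(b, mu) per site toward each specific other base, the exact
# finite-time solution of the JC chain (no per-generation looping, and
# multiple hits collapse automatically).

#' Simulate a single-deme coalescent genealogy
#'
#' Standard n-coalescent: while k lineages remain, the waiting time to
#' the next coalescence is exponential with rate `choose(k, 2)` in
#' coalescent time units, and a uniformly chosen pair merges. With
#' `units = "generations"` (the default) times are scaled by `2 * N`, so
#' the expected coalescence time of any pair of lineages is `2N`
#' generations; with `units = "coalescent"` branch lengths stay in
#' coalescent units (pairwise expectation 1).
#'
#' @param n number of lineages (leaves), `>= 2`.
#' @param N population size used for the generation scaling; defaults
#'   to `n` (the sampled lineages are the population).
#' @param seed optional integer seed (the caller's RNG state is
#'   untouched).
#' @param units `"generations"` or `"coalescent"`.
#' @return an [ape] `phylo` tree with `n` leaves and positive branch
#'   lengths (export with [ape::write.tree()] for Newick).
#' @export
simulateGenealogy <- function(n, N = n,
                              seed = NULL,
                              units = c("generations", "coalescent")) {
  n <- as.integer(n)
  if (n < 2L) stop("at least two lineages are required")
  units <- match.arg(units)
  withSeed(seed, {
    nodes <- 2L * n - 1L
    height <- numeric(nodes)
    edge <- matrix(0L, 2L * (n - 1L), 2L)
    elen <- numeric(2L * (n - 1L))
    active <- seq_len(n)
    t <- 0
    for (e in seq_len(n - 1L)) {
      k <- length(active)
      t <- t + stats::rexp(1L, rate = choose(k, 2))
      pair <- sample(k, 2L)
      parent <- n + (n - e)         # last event becomes the root n + 1
      children <- active[pair]
      height[parent] <- t
      rows <- c(2L * e - 1L, 2L * e)
      edge[rows, 1L] <- parent
      edge[rows, 2L] <- children
      elen[rows] <- t - height[children]
      active <- c(active[-pair], parent)
    }
    scale <- if (units == "generations") 2 * N else 1
    phy <- structure(list(edge = edge, edge.length = elen * scale,
                          tip.label = paste0("t", seq_len(n)),
                          Nnode = n - 1L),
                     class = "phylo")
    ape::reorder.phylo(phy, "cladewise")
  })
}

#' Evolve sequences down a genealogy under Jukes-Cantor mutation
#'
#' The root sequence is uniform over `{A,C,G,T}^l`; along each branch of
#' length `b` (in the tree's time units) every site independently
#' becomes each specific other base with probability
#' [substitutionProbability]`(b, mu)`. Branch substitution counts record
#' end-point differences (multiple hits at a site collapse).
#'
#' @param tree a `phylo` genealogy (see [simulateGenealogy()]).
#' @param l sequence length.
#' @param mu mutation rate per base per unit of the tree's branch
#'   lengths, in `(0, 0.75]`; `mu = 0` yields identical sequences.
#' @param seed optional integer seed.
#' @param timescale label recorded on the result (`"coalescent"` or
#'   `"generations"`); purely descriptive.
#' @return a [SimPopulation-class].
#' @export
mutateSequences <- function(tree, l, mu, seed = NULL,
                            timescale = "generations") {
  stopifnot(inherits(tree, "phylo"))
  l <- as.integer(l)
  if (l < 1L) stop("sequence length must be positive")
  if (mu < 0 || mu > 0.75) stop("mu must lie in [0, 3/4]")
  ntip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  withSeed(seed, {
    seqs <- matrix(0L, 2L * ntip - 1L, l)
    root <- ntip + 1L
    seqs[root, ] <- sample.int(4L, l, replace = TRUE)
    nmut <- numeric(nrow(tree$edge))
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]
      chd <- tree$edge[e, 2L]
      b <- tree$edge.length[e]
      p <- substitutionProbability(b, mu)
      s <- seqs[par, ]
      hit <- stats::runif(l) < 3 * p
      nh <- sum(hit)
      if (nh > 0L)
        s[hit] <- .OTHER[cbind(s[hit], sample.int(3L, nh, replace = TRUE))]
      seqs[chd, ] <- s
      nmut[e] <- nh
    }
    aln <- AlleleAlignment(
      apply(seqs[seq_len(ntip), , drop = FALSE], 1L, intRowToSeq),
      ids = tree$tip.label)
    new("SimPopulation", alignment = aln, tree = tree,
        branchMutations = nmut, mu = mu, timescale = timescale)
  })
}

#' Simulate a finite sequence population
#'
#' Convenience wrapper: one coalescent genealogy for `N` lineages plus
#' finite-sites Jukes-Cantor mutation. The default
#' `timescale = "coalescent"` applies `mu` per coalescent time unit per
#' base, the regime in which a single rapidly coalescing deme carries
#' per-site diversity of roughly `2 * mu` (with the Jukes-Cantor
#' saturation correction); `timescale = "generations"` scales branches
#' by `2N` generations and applies `mu` per generation.
#'
#' @param N population size (number of sequences).
#' @param l sequence length in bp.
#' @param mu mutation rate per base per time unit of `timescale`.
#' @param seed optional integer seed; splits deterministically into a
#'   genealogy seed and a mutation seed.
#' @param timescale `"coalescent"` (default) or `"generations"`.
#' @return a [SimPopulation-class].
#' @examples
#' pop <- simulatePopulation(20, l = 50, mu = 0.01, seed = 1)
#' tallyAlleles(pop@alignment)
#' @export
simulatePopulation <- function(N, l, mu, seed = NULL,
                               timescale = c("coalescent", "generations")) {
  timescale <- match.arg(timescale)
  seeds <- if (is.null(seed)) list(NULL, NULL) else as.list(splitSeed(seed, 2))
  units <- if (timescale == "coalescent") "coalescent" else "generations"
  tree <- simulateGenealogy(N, N, seed = seeds[[1]], units = units)
  mutateSequences(tree, l, mu, seed = seeds[[2]], timescale = timescale)
}

#' Randomly subsample an alignment without replacement
#'
#' @param aln an [AlleleAlignment-class] (or [SimPopulation-class]).
#' @param k sample size, `1 <= k <= n`.
#' @param seed optional integer seed.
#' @return an [AlleleAlignment-class] of `k` records.
#' @export
resampleAlignment <- function(aln, k, seed = NULL) {
  if (is(aln, "SimPopulation")) aln <- aln@alignment
  stopifnot(is(aln, "AlleleAlignment"))
  n <- length(aln@seqs)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("sample size k must lie in [1, ", n, "]")
  idx <- withSeed(seed, sample.int(n, k))
  new("AlleleAlignment", seqs = aln@seqs[idx], ids = aln@ids[idx])
}
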