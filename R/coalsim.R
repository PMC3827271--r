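#' Demographic parameters of the two-population divergence model
#'
#' The model is a clean split: an ancestral population divides `T`
#' generations ago into two descendant populations of constant diploid
#' effective sizes `N_uar` (brown bears) and `N_uma` (polar bears), with no
#' migration afterwards. The ancestral size defaults to `N_uar`, reflecting
#' the view that the polar lineage arose from within brown-bear diversity;
#' it can be overridden.
#'
#' @param N_uar diploid effective size of population 1 (individuals).
#' @param N_uma diploid effective size of population 2 (individuals).
#' @param T divergence time in generations before present.
#' @param N_anc ancestral population size; defaults to `N_uar`.
#' @return an object of class `demographic_params`.
#' @export
demographic_params <- function(N_uar, N_uma, T, N_anc = N_uar) {
  stopifnot(N_uar > 0, N_uma > 0, T > 0, N_anc > 0)
  structure(list(N_uar = N_uar, N_uma = N_uma, T = T, N_anc = N_anc),
            class = "demographic_params")
}

#' @export
print.demographic_params <- function(x, ...) {
  cat(sprintf("Divergence model: N_uar = %g, N_uma = %g, T = %g generations (N_anc = %g)\n",
              x$N_uar, x$N_uma, x$T, x$N_anc))
  invisible(x)
}

#' Per-locus simulation configuration
#'
#' @param length locus length in bp.
#' @param mu_per_site mutation rate per site per generation.
#' @param recombination `"equal-to-mu"` (crossover rate per locus equals the
#'   locus mutation rate, the convention used for the autosomal loci) or
#'   `"zero"` (mtDNA).
#' @param ploidy `"diploid-aDNA"` (a population of N individuals holds
#'   K = 2N chromosomes) or `"haploid-mtDNA"` (K = N).
#' @param n_uar,n_uma sampled chromosomes per population.
#' @return an object of class `locus_config`.
#' @export
locus_config <- function(length = 500L, mu_per_site = 1.314e-8,
                         recombination = c("equal-to-mu", "zero"),
                         ploidy = c("diploid-aDNA", "haploid-mtDNA"),
                         n_uar = 36L, n_uma = 36L) {
  recombination <- match.arg(recombination)
  ploidy <- match.arg(ploidy)
  stopifnot(length >= 1, mu_per_site >= 0, n_uar >= 0, n_uma >= 0,
            n_uar + n_uma >= 1)
  structure(list(length = as.integer(length), mu_per_site = mu_per_site,
                 recombination = recombination, ploidy = ploidy,
                 n_uar = as.integer(n_uar), n_uma = as.integer(n_uma)),
            class = "locus_config")
}

# Effective chromosome counts for the simulator under each inheritance mode.
effective_chromosomes <- function(params, ploidy) {
  f <- if (ploidy == "diploid-aDNA") 2 else 1
  list(K1 = f * params$N_uar, K2 = f * params$N_uma, Kanc = f * params$N_anc)
}

#' ms-style scaling helpers
#'
#' Convert between the package's natural parametrization (effective
#' chromosome count `K`, time in generations, per-locus mutation rate) and
#' the scaled units of Hudson-style simulators, where theta = 4 N mu per
#' locus and time is counted in units of 4 N generations.
#'
#' @param N diploid effective size; `mu_locus` per-locus per-generation
#'   mutation rate; `t_gen` time in generations; `theta`, `t_scaled` the
#'   scaled equivalents.
#' @return the converted value.
#' @export
ms_theta <- function(N, mu_locus) 4 * N * mu_locus

#' @rdname ms_theta
#' @export
ms_time <- function(t_gen, N) t_gen / (4 * N)

#' @rdname ms_theta
#' @export
from_ms_theta <- function(theta, N) theta / (4 * N)

#' @rdname ms_theta
#' @export
from_ms_time <- function(t_scaled, N) t_scaled * 4 * N

#' Simulate one locus under the divergence model
#'
#' Draws a coalescent history for `n_uar + n_uma` chromosomes (continuous
#' time, pairwise coalescence rate 1/K per generation within a population of
#' K chromosomes; the populations merge into the ancestral population at
#' time `T`), then drops infinite-sites mutations at total rate
#' `mu_per_site * length` per lineage per generation. With
#' `recombination = "equal-to-mu"` crossovers occur at the same per-locus
#' rate and the locus is an ancestral recombination graph whose marginal
#' trees vary along the sequence.
#'
#' @param params a [demographic_params()] object.
#' @param locus a [locus_config()] object.
#' @param seed optional integer seed (the caller's RNG stream is preserved).
#' @return a list with elements `matrix` (a [haplotype_matrix()]: sites x
#'   chromosomes, 0 = ancestral, 1 = derived, ordered by position),
#'   `tmrca` (generations, the oldest marginal-tree root when recombining),
#'   and `genealogy` (a `genealogy` object, `NULL` when recombination is
#'   active since no single tree describes the locus).
#' @export
simulate_locus <- function(params, locus, seed = NULL) {
  stopifnot(inherits(params, "demographic_params"), inherits(locus, "locus_config"))
  K <- effective_chromosomes(params, locus$ploidy)
  mu_locus <- locus$mu_per_site * locus$length
  r_locus <- if (locus$recombination == "equal-to-mu") mu_locus else 0
  n1 <- locus$n_uar; n2 <- locus$n_uma
  with_seed(seed, {
    if (r_locus > 0) {
      res <- cpp_sim_locus_arg(n1, n2, K$K1, K$K2, K$Kanc, params$T,
                               mu_locus, r_locus)
      ord <- order(res$pos)
      hm <- haplotype_matrix(res$mat[ord, , drop = FALSE],
                             positions = res$pos[ord],
                             n_uar = n1, n_uma = n2)
      list(matrix = hm, tmrca = res$tmrca, genealogy = NULL)
    } else {
      tr <- cpp_sim_tree(n1, n2, K$K1, K$K2, K$Kanc, params$T)
      mut <- cpp_mutate_tree(tr$parent, tr$node_time, tr$n_tips, mu_locus, -1L)
      ord <- order(mut$pos)
      hm <- haplotype_matrix(mut$mat[ord, , drop = FALSE],
                             positions = mut$pos[ord],
                             n_uar = n1, n_uma = n2)
      gen <- genealogy(tr$parent, tr$node_time, tr$n_tips, n_uar = n1, n_uma = n2)
      list(matrix = hm, tmrca = tr$tmrca, genealogy = gen)
    }
  })
}

#' Coalescent genealogy
#'
#' A rooted ultrametric tree stored as parent pointers and node times in
#' generations; tips `1..n_uar` belong to population 1, the rest to
#' population 2.
#'
#' @param parent 0-based parent indices (-1 at the root), as returned by the
#'   simulator.
#' @param node_time node times in generations (tips at 0).
#' @param n_tips number of tips.
#' @param n_uar,n_uma tips per population.
#' @return an object of class `genealogy`.
#' @export
genealogy <- function(parent, node_time, n_tips, n_uar, n_uma) {
  stopifnot(length(parent) == length(node_time), n_uar + n_uma == n_tips)
  structure(list(parent = as.integer(parent), node_time = as.numeric(node_time),
                 n_tips = as.integer(n_tips), n_uar = as.integer(n_uar),
                 n_uma = as.integer(n_uma)),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("Coalescent genealogy: %d tips, TMRCA = %.1f generations\n",
              x$n_tips, tmrca(x)))
  invisible(x)
}

#' Tree heights and subset MRCA times
#'
#' `tmrca()` returns the root time of a genealogy; `subset_tmrca()` the time
#' of the most recent common ancestor of a subset of tips (used, e.g., for
#' the MRCA of one brown-bear lineage together with all polar-bear
#' lineages).
#'
#' @param gen a `genealogy`.
#' @param tips integer tip indices (1-based).
#' @return time in generations.
#' @export
tmrca <- function(gen) {
  stopifnot(inherits(gen, "genealogy"))
  if (gen$n_tips < 2) return(0)
  max(gen$node_time)
}

#' @rdname tmrca
#' @export
subset_tmrca <- function(gen, tips) {
  stopifnot(inherits(gen, "genealogy"), all(tips >= 1), all(tips <= gen$n_tips))
  tips <- unique(as.integer(tips))
  if (length(tips) < 2) return(0)
  cpp_subset_tmrca(gen$parent, gen$node_time, tips - 1L)
}

#' Convert a genealogy to an ape phylo object / Newick string
#'
#' A debugging aid: genealogies render via \pkg{ape} with branch lengths in
#' generations and tip labels `uar_i` / `uma_j`.
#'
#' @param gen a `genealogy`.
#' @return `as_phylo()` returns an [ape::as.phylo] tree;
#'   `genealogy_newick()` a Newick string.
#' @export
as_phylo <- function(gen) {
  stopifnot(inherits(gen, "genealogy"))
  n <- gen$n_tips
  stopifnot(n >= 2)
  n_nodes <- length(gen$parent)
  # ape numbering: tips 1..n, root n+1, then other internals. Our internal
  # nodes are n+1 .. 2n-1 in coalescence order with the root last (index
  # 2n-1, 1-based).
  map <- integer(n_nodes)
  map[seq_len(n)] <- seq_len(n)
  internal <- seq.int(n + 1L, n_nodes)
  map[n_nodes] <- n + 1L                       # root
  if (n_nodes > n + 1L)
    map[internal[-length(internal)]] <- seq.int(n + 2L, 2L * n - 1L)
  edge <- matrix(0L, n_nodes - 1L, 2L)
  elen <- numeric(n_nodes - 1L)
  k <- 0L
  for (v in seq_len(n_nodes)) {
    p <- gen$parent[v] + 1L   # to 1-based
    if (p > 0L) {
      k <- k + 1L
      edge[k, ] <- c(map[p], map[v])
      elen[k] <- gen$node_time[p] - gen$node_time[v]
    }
  }
  labs <- c(sprintf("uar_%d", seq_len(gen$n_uar)),
            if (gen$n_uma > 0) sprintf("uma_%d", seq_len(gen$n_uma)))
  tr <- list(edge = edge, edge.length = elen, tip.label = labs,
             Nnode = n - 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' @rdname as_phylo
#' @export
genealogy_newick <- function(gen) {
  ape::write.tree(as_phylo(gen))
}

#' Sample the time to the most recent common ancestor analytically
#'
#' For a constant-size population of `K` effective chromosomes, the TMRCA
#' of `n` lineages is the sum of independent inter-coalescent intervals
#' `T_i ~ Exponential(rate = i(i-1)/2)` in coalescent units of `K`
#' generations, i = n, n-1, ..., 2. Draws are returned in generations.
#'
#' @param n number of lineages (>= 2).
#' @param K effective chromosome count.
#' @param n_draws number of independent TMRCA draws.
#' @param seed optional seed.
#' @return numeric vector of length `n_draws` (generations).
#' @export
sample_tmrca <- function(n, K, n_draws = 1L, seed = NULL) {
  stopifnot(n >= 2, K > 0, n_draws >= 1)
  with_seed(seed, {
    draws <- vapply(seq_len(n_draws), function(j) {
      i <- seq.int(2L, n)
      sum(rexp(length(i), rate = i * (i - 1) / 2))
    }, numeric(1))
    draws * K
  })
}
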