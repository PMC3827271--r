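#' Configuration for synthetic multi-locus datasets
#'
#' Describes a dataset with the statistical structure the inference
#' assumes: independent loci simulated under the two-population divergence
#' model, rendered as nucleotide alignments with a distant "panda-like"
#' outgroup and a pair of closer "black-bear-like" outgroups for
#' polarization.
#'
#' @param n_loci number of loci.
#' @param locus_length locus length in bp.
#' @param samples_per_pop chromosomes per population, `c(uar, uma)`, both
#'   positive.
#' @param mode `"diploid-aDNA"` (recombination optional) or
#'   `"haploid-mtDNA"` (no recombination).
#' @param true_params a [demographic_params()].
#' @param mu_per_site mutation rate per site per generation.
#' @param recomb_equals_mu intra-locus crossovers at the locus mutation
#'   rate (ignored, forced off, for mtDNA).
#' @param n_recurrent recurrent mutations to inject per dataset (exercises
#'   four-gamete filtering).
#' @param outgroup_divergence generations to the panda-like outgroup split;
#'   the black-bear-like pair sits at one third of that distance.
#' @param seed master seed; per-locus seeds are derived from it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_loci = 14L, locus_length = 500L,
                             samples_per_pop = c(uar = 36L, uma = 36L),
                             mode = c("diploid-aDNA", "haploid-mtDNA"),
                             true_params = demographic_params(40000, 8000, 120000),
                             mu_per_site = 1.314e-8,
                             recomb_equals_mu = TRUE,
                             n_recurrent = 0L,
                             outgroup_divergence = 2.4e6,
                             seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_loci >= 1, locus_length >= 1, mu_per_site >= 0,
            n_recurrent >= 0, outgroup_divergence > 0,
            length(samples_per_pop) == 2)
  if (any(samples_per_pop <= 0))
    stop("zero samples in a population: both populations must be sampled")
  if (mode == "haploid-mtDNA") recomb_equals_mu <- FALSE
  structure(list(n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 samples_per_pop = as.integer(samples_per_pop),
                 mode = mode, true_params = true_params,
                 mu_per_site = mu_per_site,
                 recomb_equals_mu = isTRUE(recomb_equals_mu),
                 n_recurrent = as.integer(n_recurrent),
                 outgroup_divergence = outgroup_divergence,
                 seed = seed),
            class = "synthetic_config")
}

random_bases <- function(n) sample(VALID_BASES, n, replace = TRUE)

other_base <- function(base) {
  vapply(base, function(b) sample(setdiff(VALID_BASES, b), 1), character(1))
}

# Renders one simulated haplotype matrix as a nucleotide alignment with
# outgroups. Returns the alignment plus the per-site truth (bp position,
# ancestral and derived base).
render_locus <- function(hm, cfg, locus_id, tmrca) {
  L <- cfg$locus_length
  S <- nrow(hm$mat)
  if (S > L) stop("more segregating sites (", S, ") than base pairs (", L,
                  "); increase locus_length")
  og <- cfg$outgroup_divergence
  mu <- cfg$mu_per_site
  anc_seq <- random_bases(L)
  bp <- if (S) sort(sample.int(L, S)) else integer(0)
  anc_allele <- anc_seq[bp]
  der_allele <- if (S) other_base(anc_allele) else character(0)

  n1 <- hm$n_uar; n2 <- hm$n_uma
  ing <- matrix(rep(anc_seq, n1 + n2), nrow = n1 + n2, byrow = TRUE)
  for (s in seq_len(S)) {
    carriers <- which(hm$mat[s, ] == 1L)
    ing[carriers, bp[s]] <- der_allele[s]
  }

  # outgroups: private mutations at so-far-untouched positions (infinite
  # sites); branch lengths follow the extended genealogy, with the
  # black-bear-like pair at 1/3 of the panda distance and splitting
  # halfway down its own branch
  free <- setdiff(seq_len(L), bp)
  draw_private <- function(seqv, branch_gen) {
    k <- min(length(free), rpois(1, mu * L * branch_gen))
    if (k > 0) {
      posns <- sample(free, k)
      free <<- setdiff(free, posns)
      seqv[posns] <- other_base(seqv[posns])
    }
    seqv
  }
  panda <- draw_private(anc_seq, max(2 * og - tmrca, og))
  bb_div <- og / 3
  bb_stem <- draw_private(anc_seq, bb_div / 2)       # shared black-bear branch
  bb1 <- draw_private(bb_stem, bb_div / 2)
  bb2 <- draw_private(bb_stem, bb_div / 2)

  ids <- c(sprintf("uar_%d_%s", seq_len(n1), locus_id),
           sprintf("uma_%d_%s", seq_len(n2), locus_id),
           paste0("outg_panda_", locus_id),
           paste0("outg_blackbear1_", locus_id),
           paste0("outg_blackbear2_", locus_id))
  pops <- c(rep("uar", n1), rep("uma", n2), "outgroup-panda",
            rep("outgroup-blackbear", 2))
  align <- alignment(ids, pops, rbind(ing, panda, bb1, bb2))
  truth <- data.frame(locus = rep(locus_id, S),
                      position = bp,
                      ancestral = anc_allele,
                      derived = der_allele,
                      stringsAsFactors = FALSE)
  list(alignment = align, truth = truth)
}

#' Generate a synthetic multi-locus dataset
#'
#' Simulates every locus under the configured divergence model, renders
#' nucleotide alignments with outgroups, optionally injects recurrent
#' mutations, and records the ground truth (true parameters, per-locus
#' TMRCA, and the ancestral allele at every segregating site).
#'
#' @param config a [synthetic_config()].
#' @param out_dir if non-NULL, one FASTA per locus (plus a shared
#'   population map) and a tab-separated truth table are written there.
#' @return a list with `locus_set` (the simulated [locus_set()]),
#'   `alignments` (per-locus `alignment` objects), and `truth` (a list
#'   with `params`, `tmrca` per locus, and the `sites` data.frame).
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  lc <- locus_config(length = cfg$locus_length, mu_per_site = cfg$mu_per_site,
                     recombination = if (cfg$recomb_equals_mu) "equal-to-mu" else "zero",
                     ploidy = if (cfg$mode == "diploid-aDNA") "diploid-aDNA"
                              else "haploid-mtDNA",
                     n_uar = cfg$samples_per_pop[1], n_uma = cfg$samples_per_pop[2])
  seeds <- derive_seeds(cfg$seed, cfg$n_loci + 1L)
  loci <- vector("list", cfg$n_loci)
  aligns <- vector("list", cfg$n_loci)
  truths <- vector("list", cfg$n_loci)
  tmrcas <- numeric(cfg$n_loci)
  for (i in seq_len(cfg$n_loci)) {
    id <- sprintf("locus%02d", i)
    sim <- simulate_locus(cfg$true_params, lc, seed = seeds[[i]])
    hm <- sim$matrix
    hm$locus_id <- id
    loci[[i]] <- hm
    tmrcas[i] <- sim$tmrca
    rl <- with_seed(seeds[[i]] + 1L, render_locus(hm, cfg, id, sim$tmrca))
    aligns[[i]] <- rl$alignment
    truths[[i]] <- rl$truth
  }
  if (cfg$n_recurrent > 0) {
    inj_seeds <- with_seed(seeds[[cfg$n_loci + 1L]],
                           as.list(sample.int(.Machine$integer.max - 1L, cfg$n_loci)))
    # spread the injected recurrent mutations over loci with enough sites
    remaining <- cfg$n_recurrent
    for (i in seq_len(cfg$n_loci)) {
      if (remaining <= 0) break
      n_sites <- nrow(loci[[i]]$mat)
      if (n_sites < 2) next
      k <- min(remaining, max(1L, n_sites %/% 2L))
      aligns[[i]] <- inject_recurrent_mutations(aligns[[i]], k, seed = inj_seeds[[i]])
      remaining <- remaining - k
    }
    if (remaining > 0)
      warning(remaining, " recurrent mutation(s) could not be placed (too few sites)")
  }
  truth <- list(params = cfg$true_params, tmrca = tmrcas,
                sites = do.call(rbind, truths))
  ls <- locus_set(loci, mu_per_site = cfg$mu_per_site,
                  length = cfg$locus_length,
                  recombination = lc$recombination)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(cfg$n_loci)) {
      id <- sprintf("locus%02d", i)
      write_alignment(aligns[[i]], file.path(out_dir, paste0(id, ".fasta")),
                      popmap = file.path(out_dir, paste0(id, ".popmap.tsv")))
    }
    tr <- truth$sites
    tr$true_N_uar <- cfg$true_params$N_uar
    tr$true_N_uma <- cfg$true_params$N_uma
    tr$true_T <- cfg$true_params$T
    tr$tmrca <- truth$tmrca[match(tr$locus, sprintf("locus%02d", seq_len(cfg$n_loci)))]
    utils::write.table(tr, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(locus_set = ls, alignments = aligns, truth = truth)
}

#' Inject recurrent mutations into an alignment
#'
#' Adds `k` second, independent mutation events at existing segregating
#' sites of the ingroup: at each chosen site one chromosome's allele is
#' flipped to the other segregating state. The first injection searches for
#' a (site, partner-site) combination whose flip creates a four-gamete
#' incompatibility, so that `k >= 1` is guaranteed to leave a detectable
#' infinite-sites violation whenever a compatible partner site exists; the
#' altered sites are recorded in attribute `altered_sites`.
#'
#' @param align an `alignment` with at least 2 ingroup-segregating sites.
#' @param k number of recurrent mutations (0 = no-op).
#' @param seed optional seed (site and chromosome choices are
#'   reproducible).
#' @return the modified `alignment`.
#' @export
inject_recurrent_mutations <- function(align, k, seed = NULL) {
  stopifnot(inherits(align, "alignment"), k >= 0)
  if (k == 0) return(align)
  enc <- ingroup_binary(align)
  bi <- which(enc$class == "biallelic")
  if (length(bi) < 2) stop("alignment needs at least 2 segregating sites")
  if (k > length(bi)) stop("k = ", k, " exceeds the ", length(bi),
                           " available segregating sites")
  with_seed(seed, {
    altered <- integer(0)
    seqmat <- align$seq
    ing_rows <- enc$ingroup
    for (rep_i in seq_len(k)) {
      avail <- setdiff(bi, altered)
      flip <- NULL
      # search for a flip that creates a four-gamete incompatibility
      for (s in sample(avail)) {
        gs <- as.integer(seqmat[ing_rows, s] != seqmat[ing_rows, s][1])
        partners <- sample(setdiff(bi, s))
        for (t in partners) {
          gt <- as.integer(seqmat[ing_rows, t] != seqmat[ing_rows, t][1])
          present <- unique(paste0(gs, gt))
          if (length(present) >= 4) next        # already incompatible
          missing <- setdiff(c("00", "01", "10", "11"), present)
          for (m in missing) {
            g1 <- as.integer(substr(m, 1, 1)); g2 <- as.integer(substr(m, 2, 2))
            cand <- which(gs == 1 - g1 & gt == g2)
            # need >= 2 carriers so the donor gamete class survives the flip
            if (length(cand) >= 2) { flip <- list(site = s, chrom = sample(cand, 1)); break }
          }
          if (!is.null(flip)) break
        }
        if (!is.null(flip)) break
      }
      if (is.null(flip)) { # no compatible partner anywhere: flip at random
        s <- sample(avail, 1)
        col <- seqmat[ing_rows, s]
        flip <- list(site = s, chrom = sample(length(ing_rows), 1))
      }
      s <- flip$site
      col <- seqmat[ing_rows, s]
      alleles <- unique(col)
      cur <- col[flip$chrom]
      seqmat[ing_rows[flip$chrom], s] <- setdiff(alleles, cur)[1]
      altered <- c(altered, s)
    }
    out <- alignment(align$ids, align$populations, seqmat,
                     positions = align$positions)
    attr(out, "altered_sites") <- align$positions[altered]
    out
  })
}
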