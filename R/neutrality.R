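# Classical frequency-spectrum neutrality tests. All statistics are
# computed from the derived-allele count spectrum of a polarized
# haplotype matrix; fixed-derived rows are excluded.

harmonic <- function(n, power = 1) sum(1 / seq_len(n)^power)

site_counts <- function(hm) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  mat <- hm$mat[!hm$fixed, , drop = FALSE]
  rowSums(mat)
}

pi_from_counts <- function(d, n) sum(2 * d * (n - d)) / (n * (n - 1))

#' Tajima's D
#'
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the standard
#' constants (`a1 = sum 1/i`, etc.). The statistic uses only the folded
#' information (pairwise diversity and the number of segregating sites), so
#' it does not depend on which allele is called derived.
#'
#' @param hm a [haplotype_matrix()] with `n >= 2` chromosomes.
#' @return the statistic (NA with a warning when S = 0).
#' @export
tajimas_d <- function(hm) {
  n <- hm$n_uar + hm$n_uma
  stopifnot(n >= 2)
  d <- site_counts(hm)
  S <- length(d)
  if (S == 0L) { warning("S = 0: Tajima's D undefined"); return(NA_real_) }
  a1 <- harmonic(n - 1); a2 <- harmonic(n - 1, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_from_counts(d, n) - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fu and Li's D and F (outgroup versions)
#'
#' Contrast the number of external (singleton-derived) mutations `eta_e`
#' with the total `eta = S` (D) or with pairwise diversity (F), using the
#' published variance constants for the outgroup-polarized versions of the
#' tests.
#'
#' @param hm a polarized [haplotype_matrix()] with `n >= 3`.
#' @return named vector `c(D = , F = )` (NA with a warning when S = 0).
#' @export
fu_li_tests <- function(hm) {
  n <- hm$n_uar + hm$n_uma
  stopifnot(n >= 3)
  d <- site_counts(hm)
  S <- length(d)
  if (S == 0L) { warning("S = 0: Fu & Li tests undefined"); return(c(D = NA_real_, F = NA_real_)) }
  eta_e <- sum(d == 1L)
  an <- harmonic(n - 1); bn <- harmonic(n - 1, 2)
  an1 <- harmonic(n)
  cn <- if (n == 2) 1 else 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vD <- 1 + an^2 / (bn + an^2) * (cn - (n + 1) / (n - 1))
  uD <- an - 1 - vD
  Dstat <- (S - an * eta_e) / sqrt(uD * S + vD * S^2)
  vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) / (an^2 + bn)
  uF <- (1 + (n + 1) / (3 * (n - 1)) -
           4 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / an - vF
  Fstat <- (pi_from_counts(d, n) - eta_e) / sqrt(uF * S + vF * S^2)
  c(D = Dstat, F = Fstat)
}

#' Fay and Wu's H
#'
#' `H = pi - theta_H` with `theta_H = sum_i 2 xi_i i^2 / (n (n - 1))`, the
#' homozygosity-weighted estimator that loads on high-frequency derived
#' alleles; strongly negative H indicates an excess of nearly fixed derived
#' variants.
#'
#' @param hm a polarized [haplotype_matrix()].
#' @return the statistic (NA with a warning when S = 0).
#' @export
fay_wu_h <- function(hm) {
  n <- hm$n_uar + hm$n_uma
  stopifnot(n >= 2)
  d <- site_counts(hm)
  if (length(d) == 0L) { warning("S = 0: Fay & Wu's H undefined"); return(NA_real_) }
  theta_H <- sum(2 * d^2) / (n * (n - 1))
  pi_from_counts(d, n) - theta_H
}

# One fixed-S null replicate: a constant-size coalescent tree for n
# chromosomes with exactly S mutations placed multinomially by branch
# length. The time scale cancels, so K = 1 is used.
null_matrix_fixed_s <- function(n, S) {
  tr <- cpp_sim_tree(n, 0L, 1, 1, 1, Inf)
  mut <- cpp_mutate_tree(tr$parent, tr$node_time, tr$n_tips, 0, as.integer(S))
  haplotype_matrix(mut$mat, n_uar = n, n_uma = 0L,
                   fixed = rowSums(mut$mat) == n)
}

#' Empirical p-values under the fixed-S coalescent null
#'
#' Simulates `n_sims` constant-size coalescent samples conditioned on the
#' observed number of segregating sites (mutations placed multinomially on
#' branches), recomputes each statistic, and returns two-tailed empirical
#' p-values (doubled smaller tail, +1 correction, capped at 1).
#'
#' @param stats named vector with any of `D_tajima`, `D_fuli`, `F_fuli`,
#'   `H_faywu` (as produced by [neutrality_stats()]).
#' @param n sample size (chromosomes).
#' @param S observed number of segregating sites.
#' @param n_sims number of null replicates (>= 100).
#' @param seed optional seed.
#' @return named vector of p-values in `[1/(n_sims + 1), 1]`; attribute
#'   `null` holds the simulated null distributions.
#' @export
neutrality_pvalues <- function(stats, n, S, n_sims = 10000L, seed = NULL) {
  stopifnot(n_sims >= 100, n >= 3, S >= 1)
  null <- with_seed(seed, {
    out <- matrix(NA_real_, n_sims, 4,
                  dimnames = list(NULL, c("D_tajima", "D_fuli", "F_fuli", "H_faywu")))
    for (r in seq_len(n_sims)) {
      hm <- null_matrix_fixed_s(n, S)
      out[r, "D_tajima"] <- tajimas_d(hm)
      fl <- fu_li_tests(hm)
      out[r, "D_fuli"] <- fl[["D"]]
      out[r, "F_fuli"] <- fl[["F"]]
      out[r, "H_faywu"] <- fay_wu_h(hm)
    }
    out
  })
  keep <- intersect(names(stats), colnames(null))
  p <- vapply(keep, function(nm) {
    lo <- sum(null[, nm] <= stats[[nm]]) + 1
    hi <- sum(null[, nm] >= stats[[nm]]) + 1
    min(1, 2 * min(lo, hi) / (n_sims + 1))
  }, numeric(1))
  attr(p, "null") <- null[, keep, drop = FALSE]
  p
}

#' All neutrality statistics (with optional significance)
#'
#' @param hm a polarized [haplotype_matrix()].
#' @param n_sims if > 0, fixed-S null p-values are attached.
#' @param seed optional seed for the null simulations.
#' @return a list of class `neutrality_stats`: `n`, `S`, the four
#'   statistics, and `p` (or NULL).
#' @export
neutrality_stats <- function(hm, n_sims = 0L, seed = NULL) {
  n <- hm$n_uar + hm$n_uma
  d <- site_counts(hm)
  S <- length(d)
  stats <- c(D_tajima = if (S) tajimas_d(hm) else NA_real_,
             D_fuli = NA_real_, F_fuli = NA_real_,
             H_faywu = if (S) fay_wu_h(hm) else NA_real_)
  if (S) {
    fl <- fu_li_tests(hm)
    stats[["D_fuli"]] <- fl[["D"]]; stats[["F_fuli"]] <- fl[["F"]]
  }
  p <- if (n_sims > 0 && S > 0)
    neutrality_pvalues(stats, n, S, n_sims = n_sims, seed = seed) else NULL
  structure(list(n = n, S = S, stats = stats, p = p),
            class = "neutrality_stats")
}

#' @export
print.neutrality_stats <- function(x, ...) {
  cat(sprintf("Neutrality tests (n = %d, S = %d):\n", x$n, x$S))
  for (nm in names(x$stats)) {
    cat(sprintf("  %-9s %8.4f", nm, x$stats[[nm]]))
    if (!is.null(x$p) && nm %in% names(x$p)) cat(sprintf("  (p = %.4f)", x$p[[nm]]))
    cat("\n")
  }
  invisible(x)
}

#' Export neutrality results as a TSV table
#'
#' Writes a three-column table (statistic, value, p) in the layout of a
#' supplementary results table.
#'
#' @param x a `neutrality_stats` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_neutrality_table <- function(x, path) {
  stopifnot(inherits(x, "neutrality_stats"))
  df <- data.frame(statistic = names(x$stats),
                   value = as.numeric(x$stats),
                   p = if (!is.null(x$p)) as.numeric(x$p[names(x$stats)]) else NA_real_)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
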