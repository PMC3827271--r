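#' Constants of the analysis
#'
#' `generation_time_years()` is the generation time used for every
#' generations-to-years conversion (10 years). `default_mutation_rates()`
#' returns the calibrated per-site per-generation mutation rates shipped
#' with the package (derived from outgroup divergence at 12 MYA):
#' autosomal loci 1.314e-8, mtDNA 7.036e-8 (sequence-edited Set-I) and
#' 7.838e-8 (site-edited Set-II). `equilibrium_mtdna_ratio()` is the
#' expected mtDNA-to-autosome effective-size ratio under random mating, an
#' equal sex ratio and Poisson offspring: mtDNA is transmitted by the N/2
#' females as a haploid genome (effective count N/2) while autosomes are
#' carried on 2N chromosomes, so the ratio is (1/2) / 2 = 0.25.
#'
#' @return a scalar (or named vector of rates).
#' @export
generation_time_years <- function() 10

#' @rdname generation_time_years
#' @export
default_mutation_rates <- function()
  c(aDNA = 1.314e-8, mtDNA_set1 = 7.036e-8, mtDNA_set2 = 7.838e-8)

#' @rdname generation_time_years
#' @export
equilibrium_mtdna_ratio <- function() (1 / 2) / 2

#' Log-normal prior specification
#'
#' Each demographic parameter gets an independent log-normal prior whose
#' natural-scale mean is `mu` and whose natural-scale variance is `mu^2`.
#' That pins the log-scale parameters to `sdlog^2 = ln 2` (for every `mu`)
#' and `meanlog = ln(mu) - ln(2)/2`.
#'
#' @param N_uar,N_uma,T natural-scale prior means (> 0).
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(N_uar = 30000, N_uma = 10000, T = 100000) {
  mus <- c(N_uar = N_uar, N_uma = N_uma, T = T)
  stopifnot(all(mus > 0))
  structure(list(mu = mus), class = "prior_spec")
}

#' Default priors for each inference mode
#'
#' Autosomal: `N_uar ~ LN(30000, 30000^2)`, `N_uma ~ LN(10000, 10000^2)`,
#' `T ~ LN(100000, 100000^2)`. mtDNA: `N_uar ~ LN(200000, 200000^2)`,
#' `N_uma ~ LN(10000, 10000^2)`, `T ~ LN(30000, 30000^2)`.
#'
#' @return a [prior_spec()].
#' @export
adna_priors <- function() prior_spec(30000, 10000, 100000)

#' @rdname adna_priors
#' @export
mtdna_priors <- function() prior_spec(200000, 10000, 30000)

#' Sample demographic parameters from the priors
#'
#' @param spec a [prior_spec()].
#' @param n number of draws.
#' @param seed optional seed.
#' @return an `n x 3` matrix with columns `N_uar`, `N_uma`, `T`.
#' @export
sample_priors <- function(spec, n = 1L, seed = NULL) {
  stopifnot(inherits(spec, "prior_spec"), n >= 1)
  sdlog <- sqrt(log(2))
  with_seed(seed, {
    draws <- vapply(spec$mu, function(mu)
      rlnorm(n, meanlog = log(mu) - log(2) / 2, sdlog = sdlog), numeric(n))
    if (n == 1L) draws <- matrix(draws, nrow = 1, dimnames = list(NULL, names(spec$mu)))
    draws
  })
}

#' @rdname sample_priors
#' @return `prior_sampler()` returns a function `(n, seed) -> matrix`
#'   suitable as the `prior` argument of [run_abc()].
#' @export
prior_sampler <- function(spec) {
  force(spec)
  function(n, seed = NULL) sample_priors(spec, n, seed)
}

#' Tajima-Nei distance between two sequences
#'
#' The substitution-count correction for unequal base frequencies:
#' `d = -b log(1 - p / b)` where `p` is the raw mismatch proportion,
#' `b = (1 - sum(g_i^2) + p^2 / h) / 2` with `g_i` the average base
#' frequencies over both sequences and
#' `h = sum_{i<j} x_ij^2 / (2 g_i g_j)` over the mismatch-pair frequencies
#' `x_ij`.
#'
#' @param seqA,seqB equal-length nucleotide strings (or character vectors);
#'   sites with gaps or ambiguity codes in either sequence are skipped.
#' @return corrected substitutions per site.
#' @export
tajima_nei_distance <- function(seqA, seqB) {
  a <- if (length(seqA) == 1L) strsplit(toupper(seqA), "")[[1]] else toupper(seqA)
  b <- if (length(seqB) == 1L) strsplit(toupper(seqB), "")[[1]] else toupper(seqB)
  stopifnot(length(a) == length(b))
  ok <- a %in% VALID_BASES & b %in% VALID_BASES
  a <- a[ok]; b <- b[ok]
  L <- length(a)
  if (L == 0L) stop("no comparable sites")
  p <- mean(a != b)
  if (p == 0) return(0)
  g <- (table(factor(a, VALID_BASES)) + table(factor(b, VALID_BASES))) / (2 * L)
  mm <- which(a != b)
  pair_key <- apply(cbind(pmin(a[mm], b[mm]), pmax(a[mm], b[mm])), 1, paste, collapse = "")
  x <- table(pair_key) / L
  keys <- names(x)
  gi <- g[substr(keys, 1, 1)]; gj <- g[substr(keys, 2, 2)]
  h <- sum(x^2 / (2 * gi * gj))
  bcoef <- (1 - sum(g^2) + p^2 / h) / 2
  if (p >= bcoef) stop("sequences are saturated (p >= b); distance undefined")
  -bcoef * log(1 - p / bcoef)
}

#' Calibrate a per-generation mutation rate from outgroup divergence
#'
#' Given the mean corrected distance `d` (substitutions/site) between the
#' ingroup and an outgroup whose split is dated at `divergence_years`,
#' the rate per site per generation is `d / (2 * divergence_years /
#' generation_years)` (the factor 2 counts both branches since the split).
#'
#' @param mean_distance substitutions per site.
#' @param divergence_years split date in years (default 12 MYA, the
#'   panda-bear calibration).
#' @param generation_years generation time in years.
#' @return an object of class `mutation_rate_estimate` with fields `rate`,
#'   `divergence_years`, `generation_years`.
#' @export
calibrate_mutation_rate <- function(mean_distance, divergence_years = 12e6,
                                    generation_years = generation_time_years()) {
  stopifnot(mean_distance >= 0, divergence_years > 0, generation_years > 0)
  rate <- mean_distance / (2 * divergence_years / generation_years)
  structure(list(rate = rate, divergence_years = divergence_years,
                 generation_years = generation_years),
            class = "mutation_rate_estimate")
}

#' @export
print.mutation_rate_estimate <- function(x, ...) {
  cat(sprintf("Mutation rate: %.4g /site/generation (calibration: %.3g y divergence, %g y/generation)\n",
              x$rate, x$divergence_years, x$generation_years))
  invisible(x)
}

#' Inference model configuration
#'
#' Bundles everything the simulator-and-summarizer side of the ABC needs:
#' the data mode, locus structure, mutation model, sample sizes and bin
#' specification.
#'
#' @param mode `"aDNA"` (multi-locus diploid, recombination equal to the
#'   mutation rate) or `"mtDNA"` (one haploid non-recombining locus).
#' @param n_loci,locus_length,mu_per_site locus structure.
#' @param n_uar,n_uma sampled chromosomes.
#' @param spec a [bin_spec()]; defaults to [adna_bin_spec()] /
#'   [mtdna_bin_spec()] for the respective mode.
#' @return an object of class `abc_model`.
#' @export
abc_model <- function(mode = c("aDNA", "mtDNA"), n_loci = NULL,
                      locus_length = NULL, mu_per_site = NULL,
                      n_uar = NULL, n_uma = NULL, spec = NULL) {
  mode <- match.arg(mode)
  if (mode == "aDNA") {
    n_loci <- n_loci %||% 14L
    locus_length <- locus_length %||% 500L
    mu_per_site <- mu_per_site %||% default_mutation_rates()[["aDNA"]]
    n_uar <- n_uar %||% 36L; n_uma <- n_uma %||% 36L
    spec <- spec %||% adna_bin_spec(n_uar, n_uma)
  } else {
    n_loci <- n_loci %||% 1L
    locus_length <- locus_length %||% 15403L
    mu_per_site <- mu_per_site %||% default_mutation_rates()[["mtDNA_set2"]]
    n_uar <- n_uar %||% 9L; n_uma <- n_uma %||% 26L
    spec <- spec %||% mtdna_bin_spec(n_uar, n_uma, exclude_fixed = FALSE)
  }
  structure(list(mode = mode, n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 mu_per_site = mu_per_site, n_uar = as.integer(n_uar),
                 n_uma = as.integer(n_uma), spec = spec),
            class = "abc_model")
}

model_locus_config <- function(model) {
  locus_config(length = model$locus_length, mu_per_site = model$mu_per_site,
               recombination = if (model$mode == "aDNA") "equal-to-mu" else "zero",
               ploidy = if (model$mode == "aDNA") "diploid-aDNA" else "haploid-mtDNA",
               n_uar = model$n_uar, n_uma = model$n_uma)
}

#' Simulate one dataset under a model and summarize it
#'
#' The simulator the ABC drivers plug into [run_abc()]: simulates
#' `n_loci` independent loci at the given parameter values and returns the
#' flattened summary vector. Also usable directly to generate observed
#' vectors for experiments.
#'
#' @param theta named vector / 1-row matrix with `N_uar`, `N_uma`, `T`.
#' @param model an [abc_model()].
#' @param seed optional seed.
#' @return a `summary_vector`.
#' @export
simulate_summary <- function(theta, model, seed = NULL) {
  stopifnot(inherits(model, "abc_model"))
  if (!is.null(names(theta)) && all(c("N_uar", "N_uma", "T") %in% names(theta)))
    theta <- theta[c("N_uar", "N_uma", "T")]
  theta <- as.numeric(theta)
  stopifnot(length(theta) == 3L, all(theta > 0))
  # lean path over the same simulator core as simulate_locus(): this
  # function sits in the inner loop of the ABC, so the per-locus object
  # construction is skipped and raw 0/1 matrices are tallied directly
  f <- if (model$mode == "aDNA") 2 else 1
  K1 <- f * theta[1]; K2 <- f * theta[2]; Tdiv <- theta[3]
  mu_locus <- model$mu_per_site * model$locus_length
  r_locus <- if (model$mode == "aDNA") mu_locus else 0
  n1 <- model$n_uar; n2 <- model$n_uma
  blocks <- names(model$spec$blocks)
  with_seed(seed, {
    if ("SFS2D" %in% blocks || identical(blocks, "SFS")) {
      nb <- (n1 + 1L) * (n2 + 1L)
      acc2d <- numeric(nb)
      acc1d <- numeric(n1 + n2)
      for (i in seq_len(model$n_loci)) {
        m <- if (r_locus > 0)
          cpp_sim_locus_arg(n1, n2, K1, K2, K1, Tdiv, mu_locus, r_locus)$mat
        else {
          tr <- cpp_sim_tree(n1, n2, K1, K2, K1, Tdiv)
          cpp_mutate_tree(tr$parent, tr$node_time, tr$n_tips, mu_locus, -1L)$mat
        }
        if (nrow(m)) {
          d1 <- if (n1) rowSums(m[, seq_len(n1), drop = FALSE]) else numeric(nrow(m))
          d2 <- if (n2) rowSums(m[, n1 + seq_len(n2), drop = FALSE]) else numeric(nrow(m))
          acc2d <- acc2d + tabulate(d2 * (n1 + 1L) + d1 + 1L, nbins = nb)
          dall <- d1 + d2
          acc1d <- acc1d + tabulate(dall[dall < n1 + n2], nbins = n1 + n2)
        }
      }
      if (identical(blocks, "SFS"))
        return(bin_and_flatten(list(SFS = acc1d), model$spec))
      tab <- matrix(acc2d, n1 + 1L, n2 + 1L)
      return(bin_and_flatten(list(SFS2D = tab), model$spec))
    }
    xi1 <- numeric(n1); xi2 <- numeric(n2)
    hfs <- matrix(0L, n1 + 1L, n2 + 1L)
    for (i in seq_len(model$n_loci)) {
      m <- if (r_locus > 0)
        cpp_sim_locus_arg(n1, n2, K1, K2, K1, Tdiv, mu_locus, r_locus)$mat
      else {
        tr <- cpp_sim_tree(n1, n2, K1, K2, K1, Tdiv)
        cpp_mutate_tree(tr$parent, tr$node_time, tr$n_tips, mu_locus, -1L)$mat
      }
      if (nrow(m)) {
        d1 <- rowSums(m[, seq_len(n1), drop = FALSE])
        d2 <- rowSums(m[, n1 + seq_len(n2), drop = FALSE])
        xi1 <- xi1 + tabulate(d1, nbins = n1)
        xi2 <- xi2 + tabulate(d2, nbins = n2)
      }
      hfs <- hfs + cpp_hap_tally(m, n1)
    }
    bin_and_flatten(list(SFS_uar = xi1, SFS_uma = xi2, HFS2D = hfs), model$spec)
  })
}

model_simulator <- function(model) {
  force(model)
  function(theta, seed = NULL) simulate_summary(theta, model, seed)
}

#' Full demographic inference pipeline
#'
#' Replicated kernel-ABC under the chosen model: draws parameters from the
#' priors, simulates multi-locus datasets, summarizes them with the model's
#' bin specification, selects kernel hyperparameters by cross-validation,
#' and reports per-parameter posterior means with their replication SD.
#' For the mtDNA mode the sampled `N_uar` / `N_uma` are the simulator's
#' haploid effective sizes; halving into mtDNA effective sizes is done at
#' reporting time by [report_derived_quantities()].
#'
#' @param obs observed `summary_vector` (layout must match the model spec).
#' @param priors a [prior_spec()].
#' @param model an [abc_model()].
#' @param n simulations per replication.
#' @param R replications.
#' @param seed master seed.
#' @param config optional fixed [kernel_config()].
#' @param cv cross-validation options, see [run_abc()].
#' @return a `posterior_estimate`.
#' @export
infer_demography <- function(obs, priors, model, n = 20000L, R = 100L,
                             seed = NULL, config = NULL,
                             cv = list(subsample = 1000L)) {
  stopifnot(inherits(priors, "prior_spec"), inherits(model, "abc_model"))
  if (length(obs) != model$spec$dimension)
    stop("observed summary has length ", length(obs),
         " but the model's bin specification expects ", model$spec$dimension)
  replicate_abc(as.numeric(obs), prior_sampler(priors), model_simulator(model),
                n = n, R = R, seed = seed, config = config, cv = cv)
}

#' TMRCA estimation by kernel-ABC
#'
#' Simulates genealogies under the fitted demographic model, records the
#' TMRCA of a chosen set of lineages in every replicate together with the
#' summary vector of the simulated data, and regresses TMRCA onto the
#' summaries by kernel ridge regression; the posterior mean at the observed
#' summary vector is returned in years. The default lineage set — the first
#' `uar` chromosome plus every `uma` chromosome — matches the geometry of
#' "one geographic brown-bear lineage against the polar clade"; `tips` may
#' name any subset. With `demography = "constant"` the polar-only variant
#' is run: a single population of constant size `N_uma`.
#'
#' @param obs observed `summary_vector` under `model$spec`.
#' @param fitted a [demographic_params()] with the fitted values.
#' @param model an [abc_model()] (mtDNA mode: the locus must be
#'   non-recombining so a single genealogy exists).
#' @param tips 1-based tip indices defining the lineage set (tips
#'   `1..n_uar` are uar, the rest uma).
#' @param demography `"divergence"` or `"constant"`.
#' @param n number of simulations.
#' @param seed,config,cv as in [run_abc()].
#' @param generation_years years per generation for the output scale.
#' @return an object of class `tmrca_estimate`: posterior mean TMRCA in
#'   years, the lineage label, and the fitted kernel configuration.
#' @export
estimate_tmrca_abc <- function(obs, fitted, model, tips = NULL,
                               demography = c("divergence", "constant"),
                               n = 2000L, seed = NULL, config = NULL,
                               cv = list(subsample = 1000L),
                               generation_years = generation_time_years()) {
  demography <- match.arg(demography)
  stopifnot(inherits(fitted, "demographic_params"), inherits(model, "abc_model"))
  if (model$mode != "mtDNA")
    stop("TMRCA regression requires a non-recombining (mtDNA) model")
  n_tot <- model$n_uar + model$n_uma
  tips <- tips %||% if (model$n_uar > 0L) c(1L, model$n_uar + seq_len(model$n_uma))
                    else seq_len(n_tot)
  if (any(tips < 1L | tips > n_tot))
    stop("lineage spec references samples outside 1..", n_tot)
  if (length(tips) < 2L) stop("need at least two lineages for a TMRCA")
  params <- if (demography == "constant")
    demographic_params(fitted$N_uma, fitted$N_uma, T = 1e-9, N_anc = fitted$N_uma)
  else fitted
  lc <- model_locus_config(model)
  seeds <- derive_seeds(seed, n + 1L)
  tm <- numeric(n); s_list <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulate_locus(params, lc, seed = seeds[[i]])
    tm[i] <- subset_tmrca(sim$genealogy, tips)
    ls <- locus_set(list(sim$matrix), mu_per_site = model$mu_per_site,
                    length = model$locus_length, recombination = "zero")
    s_list[[i]] <- as.numeric(summarize_dataset(ls, model$spec))
  }
  tab <- sim_table(matrix(tm, ncol = 1, dimnames = list(NULL, "TMRCA")),
                   do.call(rbind, s_list))
  if (is.null(config))
    config <- do.call(select_hyperparams_cv,
                      c(list(table = tab, seed = seeds[[n + 1L]]), cv))
  est <- krr_posterior_mean(tab, as.numeric(obs), config)
  structure(list(tmrca_years = max(0, est[["TMRCA"]]) * generation_years,
                 tmrca_generations = max(0, est[["TMRCA"]]),
                 lineage = paste(tips, collapse = ","),
                 demography = demography, n = n, config = config),
            class = "tmrca_estimate")
}

#' @export
print.tmrca_estimate <- function(x, ...) {
  cat(sprintf("TMRCA posterior mean: %.0f years (%.0f generations; lineages %s; %s model, n = %d)\n",
              x$tmrca_years, x$tmrca_generations, x$lineage, x$demography, x$n))
  invisible(x)
}

#' Classify segregating sites onto genealogy branches
#'
#' Counts derived mutations by the branch class they imply on the
#' brown/polar genealogy: derived only within the brown group
#' (`brown_lineage`), fixed derived in every polar chromosome and absent
#' from brown (`ancestral_polar_branch`, the stem of the polar clade),
#' polymorphic derived only within polar (`polar_lineage`), or derived in
#' both groups (`shared_unclassified`).
#'
#' @param hm a polarized [haplotype_matrix()].
#' @param groups list with integer column indices `brown` and `polar`
#'   partitioning the ingroup chromosomes.
#' @return an object of class `branch_mutation_counts` (named integer
#'   vector plus `total`).
#' @export
classify_branch_mutations <- function(hm, groups = list(brown = uar_cols(hm),
                                                        polar = uma_cols(hm))) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  if (!length(groups$brown) || !length(groups$polar))
    stop("both groups must be non-empty")
  db <- rowSums(hm$mat[, groups$brown, drop = FALSE])
  dp <- rowSums(hm$mat[, groups$polar, drop = FALSE])
  np <- length(groups$polar)
  counts <- c(
    brown_lineage = sum(db > 0 & dp == 0),
    ancestral_polar_branch = sum(db == 0 & dp == np),
    polar_lineage = sum(db == 0 & dp > 0 & dp < np),
    shared_unclassified = sum(db > 0 & dp > 0))
  structure(list(counts = counts, total = nrow(hm$mat)),
            class = "branch_mutation_counts")
}

#' @export
print.branch_mutation_counts <- function(x, ...) {
  cat("Branch-mutation counts:\n")
  for (nm in names(x$counts)) cat(sprintf("  %-24s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Prior-sensitivity experiment
#'
#' Re-runs the inference varying one parameter's log-normal prior mean over
#' a grid while the other two parameters keep their fixed priors, and
#' tabulates the posterior mean and replication SD under each prior — the
#' shrinkage of posterior means relative to the spread of prior means
#' measures how strongly the data constrain the parameter.
#'
#' @param obs observed `summary_vector`.
#' @param parameter `"N_uar"`, `"N_uma"` or `"T"`.
#' @param mu_grid vector of prior means to scan. Defaults to the study
#'   grid: 5000 to 140000 by 15000 for the size parameters, 25000 to
#'   250000 by 25000 for `T`.
#' @param fixed_spec the [prior_spec()] providing the non-scanned priors.
#' @param model an [abc_model()].
#' @param n,R,seed,config,cv forwarded to [infer_demography()].
#' @return a data.frame with one row per prior: `mu`, then posterior mean
#'   and SD per parameter.
#' @export
prior_sensitivity <- function(obs, parameter = c("N_uar", "N_uma", "T"),
                              mu_grid = NULL, fixed_spec = adna_priors(),
                              model = abc_model("aDNA"), n = 10000L, R = 100L,
                              seed = NULL, config = NULL,
                              cv = list(subsample = 1000L)) {
  parameter <- match.arg(parameter)
  mu_grid <- mu_grid %||% if (parameter == "T") seq(25000, 250000, by = 25000)
                          else seq(5000, 140000, by = 15000)
  if (!length(mu_grid)) stop("empty prior grid")
  seeds <- derive_seeds(seed, length(mu_grid))
  rows <- vector("list", length(mu_grid))
  for (g in seq_along(mu_grid)) {
    mus <- fixed_spec$mu
    mus[[parameter]] <- mu_grid[g]
    sp <- prior_spec(mus[["N_uar"]], mus[["N_uma"]], mus[["T"]])
    est <- infer_demography(obs, sp, model, n = n, R = R, seed = seeds[[g]],
                            config = config, cv = cv)
    rows[[g]] <- data.frame(mu = mu_grid[g],
                            N_uar = est$mean[["N_uar"]], N_uar_sd = est$sd[["N_uar"]],
                            N_uma = est$mean[["N_uma"]], N_uma_sd = est$sd[["N_uma"]],
                            T = est$mean[["T"]], T_sd = est$sd[["T"]])
  }
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- parameter
  out
}

#' Derived quantities: effective-size ratios and time conversions
#'
#' Combines the autosomal and mtDNA posterior means into the published
#' derived quantities: per-species autosomal effective sizes
#' `N_aDNA = 2 N_e` (chromosome-doubling of the diploid estimate), mtDNA
#' effective sizes `N_mtDNA` (half the simulator's haploid parameter when
#' `mtdna_scale = "raw"`; taken as-is when already on the mtDNA scale),
#' the ratios `N_mtDNA / (2 N_e)` per species and mtDNA set, and the
#' divergence times in years and MYA (MYA rounded to 2 decimals).
#'
#' @param adna named vector (or `posterior_estimate`) with autosomal
#'   `N_uar`, `N_uma`, `T` posterior means.
#' @param mtdna_set1,mtdna_set2 optional named vectors /
#'   `posterior_estimate`s for the two mtDNA edits.
#' @param mtdna_scale `"mtdna"` if the supplied mtDNA values are already
#'   `N_mtDNA` (as printed in reports), `"raw"` if they are the simulator's
#'   haploid sizes still to be halved.
#' @param generation_years years per generation.
#' @return a list of class `derived_report` with components `N_aDNA`,
#'   `N_mtDNA`, `ratios` (matrix sets x species), `T_years`, `T_mya`.
#' @export
report_derived_quantities <- function(adna, mtdna_set1 = NULL, mtdna_set2 = NULL,
                                      mtdna_scale = c("mtdna", "raw"),
                                      generation_years = generation_time_years()) {
  mtdna_scale <- match.arg(mtdna_scale)
  get_means <- function(x) if (inherits(x, "posterior_estimate")) x$mean else x
  a <- get_means(adna)
  stopifnot(all(c("N_uar", "N_uma", "T") %in% names(a)))
  sets <- list(set1 = mtdna_set1, set2 = mtdna_set2)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  if (!length(sets))
    warning("no mtDNA estimates supplied; ratio block omitted")

  N_aDNA <- c(uar = 2 * a[["N_uar"]], uma = 2 * a[["N_uma"]])
  T_years <- c(aDNA = a[["T"]] * generation_years)
  N_mtDNA <- NULL; ratios <- NULL
  for (nm in names(sets)) {
    m <- get_means(sets[[nm]])
    stopifnot(all(c("N_uar", "N_uma") %in% names(m)))
    half <- if (mtdna_scale == "raw") 0.5 else 1
    nmt <- c(uar = half * m[["N_uar"]], uma = half * m[["N_uma"]])
    N_mtDNA <- rbind(N_mtDNA, nmt)
    ratios <- rbind(ratios, nmt / (2 * c(a[["N_uar"]], a[["N_uma"]])))
    if ("T" %in% names(m)) T_years[[paste0("mtDNA_", nm)]] <- m[["T"]] * generation_years
  }
  if (!is.null(ratios)) {
    rownames(ratios) <- rownames(N_mtDNA) <- names(sets)
    colnames(ratios) <- colnames(N_mtDNA) <- c("uar", "uma")
  }
  structure(list(N_aDNA = N_aDNA, N_mtDNA = N_mtDNA,
                 ratios = if (!is.null(ratios)) round(ratios, 3) else NULL,
                 T_years = T_years, T_mya = round(T_years / 1e6, 2),
                 generation_years = generation_years),
            class = "derived_report")
}

#' @export
print.derived_report <- function(x, ...) {
  cat("Derived quantities:\n")
  cat(sprintf("  N_aDNA (2N_e): uar = %.0f, uma = %.0f\n",
              x$N_aDNA[["uar"]], x$N_aDNA[["uma"]]))
  if (!is.null(x$N_mtDNA))
    for (nm in rownames(x$N_mtDNA))
      cat(sprintf("  N_mtDNA %s: uar = %.0f, uma = %.0f  (ratios %.3f / %.3f)\n",
                  nm, x$N_mtDNA[nm, "uar"], x$N_mtDNA[nm, "uma"],
                  x$ratios[nm, "uar"], x$ratios[nm, "uma"]))
  for (nm in names(x$T_years))
    cat(sprintf("  T %s: %.0f years (%.2f MYA)\n", nm, x$T_years[[nm]], x$T_mya[[nm]]))
  cat(sprintf("  expected equilibrium N_mtDNA/N_aDNA ratio: %.3f\n",
              equilibrium_mtdna_ratio()))
  invisible(x)
}
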