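test_that("log-normal priors have mean mu and variance mu^2", {
  sp <- prior_spec(30000, 10000, 100000)
  draws <- sample_priors(sp, n = 100000, seed = 1)
  expect_true(all(draws > 0))
  # log-scale variance is ln 2 for every mu by construction
  for (col in colnames(draws))
    expect_equal(var(log(draws[, col])), log(2), tolerance = 0.02)
  mu <- 30000
  x <- draws[, "N_uar"]
  expect_lt(abs(mean(x) - mu), 3 * sd(x) / sqrt(length(x)))
  expect_error(prior_spec(-5, 1, 1))
})

test_that("Tajima-Nei distances match a step-by-step evaluation", {
  expect_equal(tajima_nei_distance("ACGTACGT", "ACGTACGT"), 0)
  # small divergence: correction is first-order equal to the raw proportion
  a <- strsplit(paste(rep("ACGT", 250), collapse = ""), "")[[1]]
  b <- a; b[c(10, 500)] <- c("G", "A")
  p <- mean(a != b)
  d <- tajima_nei_distance(a, b)
  expect_equal(d, p, tolerance = 0.01)
  expect_gt(d, p)  # the correction always inflates
  # random 1000-bp pair against the independent oracle
  set.seed(23)
  for (i in 1:5) {
    x <- sample(c("A", "C", "G", "T"), 1000, replace = TRUE,
                prob = c(0.4, 0.1, 0.2, 0.3))
    y <- x
    mut <- sample(1000, 60)
    y[mut] <- vapply(x[mut], function(bb)
      sample(setdiff(c("A", "C", "G", "T"), bb), 1), character(1))
    expect_equal(tajima_nei_distance(x, y), brute_tajima_nei(x, y),
                 tolerance = 1e-12)
  }
})

test_that("mutation-rate calibration is the two-branch divergence arithmetic", {
  expect_equal(calibrate_mutation_rate(0)$rate, 0)
  est <- calibrate_mutation_rate(0.0631, divergence_years = 12e6,
                                 generation_years = 10)
  expect_equal(est$rate, 0.0631 / (2 * 1.2e6), tolerance = 1e-12)
  rates <- default_mutation_rates()
  expect_equal(unname(rates["aDNA"]), 1.314e-8)
  expect_equal(unname(rates["mtDNA_set1"]), 7.036e-8)
})

test_that("branch-mutation classification partitions the segregating sites", {
  m <- rbind(c(1, 1, 0, 0, 0, 0, 0),  # brown only
             c(0, 0, 1, 1, 1, 1, 1),  # fixed in all 5 polar
             c(0, 0, 1, 1, 1, 0, 0),  # polymorphic within polar
             c(1, 0, 1, 0, 0, 0, 0))  # shared
  hm <- haplotype_matrix(m, n_uar = 2, n_uma = 5)
  bc <- classify_branch_mutations(hm)
  expect_equal(unname(bc$counts["brown_lineage"]), 1L)
  expect_equal(unname(bc$counts["ancestral_polar_branch"]), 1L)
  expect_equal(unname(bc$counts["polar_lineage"]), 1L)
  expect_equal(unname(bc$counts["shared_unclassified"]), 1L)
  expect_equal(sum(bc$counts), bc$total)
  expect_error(classify_branch_mutations(hm, list(brown = integer(0),
                                                  polar = 3:7)), "non-empty")
})

test_that("derived-quantity reporting computes ratios and time conversions", {
  # identical hypothetical values N_mt = 2 N_e give ratio 1
  rep1 <- report_derived_quantities(c(N_uar = 1000, N_uma = 500, T = 10000),
                                    mtdna_set1 = c(N_uar = 2000, N_uma = 1000))
  expect_equal(unname(rep1$ratios["set1", ]), c(1, 1))
  # raw simulator-scale mtDNA values are halved first
  rep2 <- report_derived_quantities(c(N_uar = 1000, N_uma = 500, T = 10000),
                                    mtdna_set1 = c(N_uar = 4000, N_uma = 2000),
                                    mtdna_scale = "raw")
  expect_equal(unname(rep2$ratios["set1", ]), c(1, 1))
  expect_equal(unname(rep2$N_aDNA["uma"]), 1000)
  expect_equal(unname(rep2$T_mya[["aDNA"]]), 0.1)
  expect_warning(report_derived_quantities(c(N_uar = 1, N_uma = 1, T = 1)),
                 "no mtDNA")
})

test_that("inference drivers validate the summary layout", {
  m <- abc_model("aDNA")
  expect_error(infer_demography(rep(0, 10), adna_priors(), m, n = 100, R = 1),
               "bin specification")
  mm <- abc_model("mtDNA", n_uar = 4, n_uma = 10,
                  spec = mtdna_bin_spec(4, 10))
  expect_equal(mm$spec$dimension, 53L)
  expect_error(estimate_tmrca_abc(rep(0, 53), demographic_params(1e5, 5e3, 3e4),
                                  mm, tips = c(1, 99), n = 10), "outside")
  expect_error(estimate_tmrca_abc(rep(0, 64), demographic_params(1e5, 5e3, 3e4),
                                  abc_model("aDNA"), n = 10),
               "non-recombining")
})

test_that("simulate_summary equals the compositional pipeline under one seed", {
  m <- abc_model("aDNA", n_loci = 4)
  th <- c(N_uar = 30000, N_uma = 9000, T = 90000)
  fast <- simulate_summary(th, m, seed = 77)
  set.seed(77)
  p <- demographic_params(30000, 9000, 90000)
  lc <- locus_config(length = m$locus_length, mu_per_site = m$mu_per_site,
                     recombination = "equal-to-mu", n_uar = 36, n_uma = 36)
  loci <- lapply(1:4, function(i) simulate_locus(p, lc)$matrix)
  slow <- summarize_dataset(locus_set(loci), m$spec)
  expect_equal(as.numeric(fast), as.numeric(slow))

  mm <- abc_model("mtDNA", n_uar = 5, n_uma = 7,
                  spec = mtdna_bin_spec(5, 7, exclude_fixed = FALSE))
  thm <- c(N_uar = 150000, N_uma = 6000, T = 30000)
  fast_m <- simulate_summary(thm, mm, seed = 31)
  set.seed(31)
  pm <- demographic_params(150000, 6000, 30000)
  lcm <- locus_config(length = mm$locus_length, mu_per_site = mm$mu_per_site,
                      recombination = "zero", ploidy = "haploid-mtDNA",
                      n_uar = 5, n_uma = 7)
  hm <- simulate_locus(pm, lcm)$matrix
  slow_m <- summarize_dataset(locus_set(list(hm)), mm$spec)
  expect_equal(as.numeric(fast_m), as.numeric(slow_m))
})

test_that("TMRCA regression recovers the constant-size closed form", {
  # two lineages in a constant population of K chromosomes: E[TMRCA] = K
  K <- 20000
  mm <- abc_model("mtDNA", n_uar = 0, n_uma = 2, locus_length = 8000,
                  mu_per_site = 7.036e-8, spec = sfs1d_bin_spec(2))
  fitted <- demographic_params(K, K, T = 1)
  cfg <- kernel_config(sigma2 = 2, lambda = 1e-3)
  lcm <- locus_config(length = 8000, mu_per_site = 7.036e-8,
                      recombination = "zero", ploidy = "haploid-mtDNA",
                      n_uar = 0, n_uma = 2)
  set.seed(55)
  ests <- numeric(40)
  for (i in seq_len(40)) {
    obs <- summarize_dataset(locus_set(list(simulate_locus(
      demographic_params(K, K, T = 1e-9, N_anc = K), lcm)$matrix),
      recombination = "zero"), sfs1d_bin_spec(2))
    tm <- estimate_tmrca_abc(obs, fitted, mm, demography = "constant",
                             n = 600, seed = i, config = cfg)
    expect_gte(tm$tmrca_years, 0)
    ests[i] <- tm$tmrca_generations
  }
  expect_lt(abs(mean(ests) - K) / K, 0.15)
})

test_that("posterior means shrink toward the data across prior choices", {
  m <- abc_model("aDNA", n_loci = 6)
  th <- c(N_uar = 30000, N_uma = 10000, T = 100000)
  obs <- simulate_summary(th, m, seed = 101)
  cfg <- kernel_config(sigma2 = 50, lambda = 1e-4)
  tab <- suppressWarnings(prior_sensitivity(obs, "N_uma", mu_grid = c(4000, 10000, 30000),
                           model = m, n = 500, R = 1, seed = 6, config = cfg))
  expect_equal(nrow(tab), 3L)
  spread_post <- diff(range(tab$N_uma))
  spread_prior <- diff(range(c(4000, 10000, 30000)))
  expect_lt(spread_post, spread_prior)
  # a one-point grid is a single run under that prior
  one <- suppressWarnings(prior_sensitivity(obs, "N_uma", mu_grid = 10000, model = m,
                           n = 500, R = 1, seed = 6, config = cfg))
  expect_equal(nrow(one), 1L)
})
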