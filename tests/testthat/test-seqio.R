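pops5 <- c("uar", "uar", "uma", "outgroup-blackbear", "outgroup-blackbear")

test_that("polarization follows the two-tier outgroup rule", {
  # black bears agree on A, which segregates in the ingroup -> A ancestral
  # (even though the panda carries G)
  al <- alignment(sprintf("s%d", 1:6),
                  c("uar", "uar", "uma", "outgroup-blackbear",
                    "outgroup-blackbear", "outgroup-panda"),
                  c("AG", "GG", "GG", "AG", "AG", "GT"))
  hm <- polarize_sites(al)
  expect_equal(nrow(hm$mat), 1L)          # site 2 monomorphic in ingroup
  expect_equal(as.integer(hm$mat[1, ]), c(0L, 1L, 1L))  # A ancestral, G derived

  # black bears disagree (A/G): fall back to the panda allele G
  al2 <- alignment(sprintf("s%d", 1:6),
                   c("uar", "uar", "uma", "outgroup-blackbear",
                     "outgroup-blackbear", "outgroup-panda"),
                   c("A", "G", "A", "A", "G", "G"))
  hm2 <- polarize_sites(al2)
  expect_equal(as.integer(hm2$mat[1, ]), c(1L, 0L, 1L))  # G ancestral

  # no rule applies: black bears C/C (absent from ingroup), panda T
  al3 <- alignment(sprintf("s%d", 1:6),
                   c("uar", "uar", "uma", "outgroup-blackbear",
                     "outgroup-blackbear", "outgroup-panda"),
                   c("A", "G", "A", "C", "C", "T"))
  hm3 <- polarize_sites(al3)
  expect_equal(nrow(hm3$mat), 0L)
  expect_equal(attr(hm3, "dropped")$reason, "no-polarization-rule")
})

test_that("triallelic and ambiguous sites are dropped and logged", {
  al <- alignment(sprintf("s%d", 1:6),
                  c("uar", "uar", "uma", "outgroup-blackbear",
                    "outgroup-blackbear", "outgroup-panda"),
                  c("AT", "GT", "CT", "AT", "AT", "AT"))
  hm <- polarize_sites(al)
  expect_equal(nrow(hm$mat), 0L)
  expect_true("more-than-two-ingroup-alleles" %in% attr(hm, "dropped")$reason)
  al2 <- alignment(sprintf("s%d", 1:6),
                   c("uar", "uar", "uma", "outgroup-blackbear",
                     "outgroup-blackbear", "outgroup-panda"),
                   c("AA", "GA", "-A", "AA", "AA", "AA"))
  expect_equal(nrow(polarize_sites(al2)$mat), 0L)
})

test_that("polarization is idempotent and order-invariant in derived counts", {
  set.seed(3)
  cfg <- synthetic_config(n_loci = 1, locus_length = 400,
                          samples_per_pop = c(6, 6), mode = "haploid-mtDNA",
                          true_params = demographic_params(20000, 8000, 40000),
                          mu_per_site = 2e-6, seed = 5)
  al <- generate_dataset(cfg)$alignments[[1]]
  hm1 <- polarize_sites(al)
  hm2 <- polarize_sites(al)
  expect_identical(hm1$mat, hm2$mat)
  # shuffle ingroup sequence order within populations
  idx <- c(sample(1:6), sample(7:12), 13:15)
  al_shuf <- alignment(al$ids[idx], al$populations[idx],
                       al$seq[idx, , drop = FALSE], positions = al$positions)
  hm3 <- polarize_sites(al_shuf)
  expect_equal(rowSums(hm3$mat), rowSums(hm1$mat))
})

test_that("fixed-derived sites are recovered only when requested", {
  al <- alignment(sprintf("s%d", 1:6),
                  c("uar", "uar", "uma", "outgroup-blackbear",
                    "outgroup-blackbear", "outgroup-panda"),
                  c("G", "G", "G", "A", "A", "A"))
  expect_equal(nrow(polarize_sites(al)$mat), 0L)
  hmf <- polarize_sites(al, include_fixed = TRUE)
  expect_equal(nrow(hmf$mat), 1L)
  expect_true(hmf$fixed[1])
  expect_equal(as.integer(hmf$mat[1, ]), c(1L, 1L, 1L))
})

test_that("four-gamete scan finds exactly the incompatible pairs", {
  m <- matrix(c(0, 0,
                0, 1,
                1, 0,
                1, 1), nrow = 2)  # columns are the 4 gametes
  expect_equal(nrow(four_gamete_scan(m)), 1L)
  expect_equal(nrow(four_gamete_scan(m[1, , drop = FALSE])), 0L)
  set.seed(8)
  for (i in 1:20) {
    mm <- matrix(rbinom(9 * 12, 1, 0.4), 9, 12)
    expect_equal(four_gamete_scan(mm), brute_four_gamete(mm))
  }
})

test_that("mtDNA set editing produces four-gamete-compatible alignments", {
  set.seed(21)
  cfg <- synthetic_config(n_loci = 1, locus_length = 1500,
                          samples_per_pop = c(5, 8), mode = "haploid-mtDNA",
                          true_params = demographic_params(30000, 6000, 50000),
                          mu_per_site = 3e-6, n_recurrent = 3, seed = 31)
  al <- generate_dataset(cfg)$alignments[[1]]
  enc_pairs <- function(a) {
    hm <- suppressWarnings(polarize_sites(a))
    four_gamete_scan(hm)
  }
  expect_gt(nrow(enc_pairs(al)), 0)       # injections created incompatibilities

  # exclude-sites: drops exactly the sites in incompatible pairs
  ed_sites <- build_mtdna_sets(al, "exclude-sites")
  expect_equal(nrow(enc_pairs(ed_sites)), 0L)
  removed <- attr(ed_sites, "removed_sites")
  expect_equal(ncol(ed_sites$seq), ncol(al$seq) - length(removed))
  expect_gt(length(removed), 0)

  # exclude-sequences: scan on the output is empty too
  ed_seq <- build_mtdna_sets(al, "exclude-sequences")
  expect_equal(nrow(enc_pairs(ed_seq)), 0L)

  # identity on an already compatible alignment
  clean <- build_mtdna_sets(ed_sites, "exclude-sites")
  expect_identical(clean$seq, ed_sites$seq)
  clean2 <- build_mtdna_sets(ed_sites, "exclude-sequences")
  expect_setequal(clean2$ids, ed_sites$ids)
  expect_equal(ncol(clean2$seq), ncol(ed_sites$seq))
})

test_that("alignments round-trip through FASTA and a population map", {
  al <- make_alignment(c("ACGT", "ACGA", "ACTA", "ACGA", "ACGA"), pops5)
  fa <- tempfile(fileext = ".fasta"); pm <- tempfile(fileext = ".tsv")
  write_alignment(al, fa, popmap = pm)
  back <- read_alignment(fa, popmap = pm)
  expect_identical(back$seq, al$seq)
  expect_identical(back$populations, al$populations)
})

test_that("haplotype_matrix enforces its invariants", {
  expect_error(haplotype_matrix(matrix(0L, 1, 4), n_uar = 2, n_uma = 2),
               "non-segregating")
  expect_error(haplotype_matrix(matrix(1L, 1, 4), n_uar = 2, n_uma = 2),
               "fixed-derived")
  expect_silent(haplotype_matrix(matrix(1L, 1, 4), n_uar = 2, n_uma = 2,
                                 fixed = TRUE))
  expect_error(locus_set(list(random_hm(3, 4, 4, seed = 1),
                              random_hm(3, 5, 3, seed = 2))),
               "sample sizes")
})
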