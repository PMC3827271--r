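test_that("site frequency spectra count derived alleles per population", {
  # 3 sites with uar derived counts 1, 1, 2 on a 4+2 matrix
  m <- rbind(c(1, 0, 0, 0, 0, 0),
             c(0, 1, 0, 0, 1, 0),
             c(1, 1, 0, 0, 0, 1))
  hm <- haplotype_matrix(m, n_uar = 4, n_uma = 2)
  expect_equal(sfs(hm, "uar"), c(2L, 1L, 0L, 0L))
  expect_equal(sfs(hm, "uma"), c(2L, 0L))
  expect_equal(sum(sfs(hm, "uar")), sum(rowSums(m[, 1:4]) > 0))
  # chromosome relabeling within a population leaves spectra unchanged
  hm_perm <- haplotype_matrix(m[, c(3, 1, 4, 2, 6, 5)], n_uar = 4, n_uma = 2)
  expect_equal(sfs(hm_perm, "uar"), sfs(hm, "uar"))
  expect_equal(sfs(hm_perm, "uma"), sfs(hm, "uma"))
})

test_that("joint SFS places sites by their two-population derived counts", {
  m <- rbind(c(0, 0, 1, 1, 1, 1),   # private to uma, 4 copies
             c(1, 1, 0, 0, 0, 0),   # private to uar, 2 copies
             c(1, 0, 1, 0, 0, 0))   # shared 1/1
  hm <- haplotype_matrix(m, n_uar = 2, n_uma = 4)
  js <- joint_sfs(hm)
  expect_equal(js["0", "4"], 1L)
  expect_equal(js["2", "0"], 1L)
  expect_equal(js["1", "1"], 1L)
  expect_equal(sum(js), nrow(m))
  expect_equal(js["0", "0"], 0L)
})

test_that("joint HFS tallies distinct haplotypes per locus and pools loci", {
  n1 <- 36L; n2 <- 36L
  # a locus with no segregating sites: one haplotype carried by everyone
  empty <- haplotype_matrix(matrix(0L, 0, 72), n_uar = n1, n_uma = n2)
  h <- joint_hfs(locus_set(list(empty)))
  expect_equal(h["36", "36"], 1L)
  expect_equal(sum(h), 1L)

  # two haplotypes split 30/6 in uar and 0/36 in uma
  m <- matrix(0L, 1, 72)
  m[1, c(31:36, 37:72)] <- 1L        # 6 uar + all uma carry the derived state
  hm <- haplotype_matrix(m, n_uar = n1, n_uma = n2)
  h2 <- joint_hfs(locus_set(list(hm)))
  expect_equal(h2["30", "0"], 1L)
  expect_equal(h2["6", "36"], 1L)
  expect_equal(sum(h2), 2L)

  # conservation: sum over cells of (i + j) x count = chromosomes x loci
  ls <- locus_set(list(hm, empty))
  h3 <- joint_hfs(ls)
  ij <- outer(0:n1, 0:n2, `+`)
  expect_equal(sum(ij * h3), 72 * 2)

  # brute-force string-count oracle on random data
  set.seed(5)
  loci <- lapply(1:3, function(i) random_hm(6, 5, 4))
  tal <- joint_hfs(locus_set(loci))
  brute <- matrix(0L, 6, 5)
  for (hm_i in loci) {
    keys <- apply(hm_i$mat, 2, paste0, collapse = "")
    for (k in unique(keys)) {
      i <- sum(keys[1:5] == k); j <- sum(keys[6:9] == k)
      brute[i + 1, j + 1] <- brute[i + 1, j + 1] + 1L
    }
  }
  expect_equal(unname(unclass(tal)), brute)
})

test_that("Sturges' rule rounds 1 + log2(x) to the nearest integer", {
  expect_identical(sturges_bins(96), 8L)
  expect_identical(sturges_bins(77), 7L)
  expect_identical(sturges_bins(2), 2L)
  expect_error(sturges_bins(0))
})

test_that("the autosomal bin specification flattens to 8 + 8 + 48 coordinates", {
  spec <- adna_bin_spec()
  expect_equal(spec$dimension, 64L)
  v <- bin_and_flatten(list(SFS_uar = integer(36), SFS_uma = integer(36),
                            HFS2D = matrix(0L, 37, 37)), spec)
  expect_length(v, 64)
  expect_true(all(v == 0))
})

test_that("binning preserves mass outside excluded cells", {
  set.seed(9)
  xi1 <- rpois(36, 2); xi2 <- rpois(36, 2)
  hfs <- matrix(rpois(37 * 37, 0.5), 37, 37)
  v <- bin_and_flatten(list(SFS_uar = xi1, SFS_uma = xi2, HFS2D = hfs),
                       adna_bin_spec())
  excluded <- hfs[1, 1]   # haplotype-count cell (0, 0)
  expect_equal(sum(v), sum(xi1) + sum(xi2) + sum(hfs) - excluded)
})

test_that("mtDNA bin specifications report their realized dimension", {
  # Set-I style: full 5 x 11 grid minus (0,0) and the fixed corner
  s1 <- mtdna_bin_spec(4, 10)
  expect_equal(s1$dimension, 5L * 11L - 2L)
  # Set-II style: full brown spectrum x the coarse polar intervals
  uma_breaks <- list(c(0, 0), c(1, 3), c(4, 6), c(7, 9), c(10, 12), c(13, 15),
                     c(16, 18), c(19, 21), c(22, 24), c(25, 26))
  s2 <- mtdna_bin_spec(9, 26, uma_breaks = uma_breaks, exclude_fixed = FALSE)
  expect_equal(s2$dimension, 10L * 10L - 1L)
  # a fixed-derived site lands in the corner cell, which Set-I excludes
  m <- matrix(1L, 1, 14)
  hm <- haplotype_matrix(m, n_uar = 4, n_uma = 10, fixed = TRUE)
  v <- summarize_dataset(locus_set(list(hm)), s1)
  expect_equal(sum(v), 0)
  s1_keep <- mtdna_bin_spec(4, 10, exclude_fixed = FALSE)
  v2 <- summarize_dataset(locus_set(list(hm)), s1_keep)
  expect_equal(sum(v2), 1)
})

test_that("dataset summaries are additive and order-invariant across loci", {
  set.seed(17)
  p <- demographic_params(30000, 8000, 80000)
  lc <- locus_config(n_uar = 36, n_uma = 36)
  loci <- lapply(1:4, function(i) simulate_locus(p, lc)$matrix)
  v1 <- summarize_dataset(locus_set(loci))
  v2 <- summarize_dataset(locus_set(loci[c(3, 1, 4, 2)]))
  expect_equal(as.numeric(v1), as.numeric(v2))
  # doubling a single-locus set doubles the pooled spectra
  one <- summarize_dataset(locus_set(loci[1]))
  two <- summarize_dataset(locus_set(loci[c(1, 1)]))
  expect_equal(as.numeric(two), 2 * as.numeric(one))
  # dimension mismatch is caught
  expect_error(bin_and_flatten(list(SFS_uar = integer(10)), adna_bin_spec()))
})
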