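#' Site frequency spectrum
#'
#' Counts `xi_i`, the number of segregating sites whose derived allele is
#' carried by exactly `i` chromosomes of the chosen population
#' (i = 1 .. sample size). Sites with derived count 0 in that population
#' (private to the other population) do not contribute. Fixed-derived rows
#' are excluded.
#'
#' @param hm a [haplotype_matrix()].
#' @param population `"uar"`, `"uma"` or `"all"` (pooled sample).
#' @return integer vector of length equal to the population's sample size.
#' @export
sfs <- function(hm, population = c("uar", "uma", "all")) {
  population <- match.arg(population)
  stopifnot(inherits(hm, "haplotype_matrix"))
  cols <- switch(population, uar = uar_cols(hm), uma = uma_cols(hm),
                 all = seq_len(hm$n_uar + hm$n_uma))
  n <- length(cols)
  mat <- hm$mat[!hm$fixed, , drop = FALSE]
  counts <- if (nrow(mat)) rowSums(mat[, cols, drop = FALSE]) else integer(0)
  counts <- counts[counts >= 1L & counts <= n]
  tabulate(counts, nbins = n)
}

#' Joint (2D) site frequency spectrum
#'
#' Cell `(i, j)` counts segregating sites with `i` derived copies among the
#' `uar` chromosomes and `j` among the `uma` chromosomes; indices run from
#' 0, so the table is `(n_uar + 1) x (n_uma + 1)` with cell (0, 0)
#' structurally empty. Fixed-derived rows (if present) land in the
#' `(n_uar, n_uma)` corner.
#'
#' @param hm a [haplotype_matrix()].
#' @return an integer matrix with dimnames giving the derived counts.
#' @export
joint_sfs <- function(hm) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  n1 <- hm$n_uar; n2 <- hm$n_uma
  out <- matrix(0L, n1 + 1L, n2 + 1L,
                dimnames = list(uar = 0:n1, uma = 0:n2))
  if (nrow(hm$mat)) {
    i <- rowSums(hm$mat[, uar_cols(hm), drop = FALSE])
    j <- rowSums(hm$mat[, uma_cols(hm), drop = FALSE])
    for (s in seq_along(i)) out[i[s] + 1L, j[s] + 1L] <- out[i[s] + 1L, j[s] + 1L] + 1L
  }
  out
}

#' Joint (2D) haplotype frequency spectrum
#'
#' For every locus, each distinct haplotype (its 0/1 vector over the
#' locus's segregating sites) contributes one tally at coordinates
#' (occurrences among `uar` chromosomes, occurrences among `uma`
#' chromosomes); tallies are pooled across loci. A locus with no
#' segregating sites has a single haplotype carried by every chromosome.
#'
#' @param x a [locus_set()] or a single [haplotype_matrix()].
#' @return an integer matrix `(n_uar + 1) x (n_uma + 1)` of haplotype
#'   tallies, with cell (0, 0) structurally empty.
#' @export
joint_hfs <- function(x) {
  ls <- if (inherits(x, "haplotype_matrix")) locus_set(list(x)) else x
  stopifnot(inherits(ls, "locus_set"))
  n1 <- ls$n_uar; n2 <- ls$n_uma
  out <- matrix(0L, n1 + 1L, n2 + 1L,
                dimnames = list(uar = 0:n1, uma = 0:n2))
  for (hm in ls$loci)
    out <- out + cpp_hap_tally(hm$mat, n1)
  dimnames(out) <- list(uar = 0:n1, uma = 0:n2)
  out
}

#' Sturges' rule bin count
#'
#' `1 + log2(x)` rounded to the nearest integer (ties round up), the rule
#' used to choose how many frequency bins summarize `x` pooled derived
#' alleles or haplotypes.
#'
#' @param x a positive count (vectorized).
#' @return integer bin count(s).
#' @export
sturges_bins <- function(x) {
  stopifnot(all(x >= 1))
  as.integer(floor(1 + log2(x) + 0.5))
}

#' Bin specification for flattened summary vectors
#'
#' Defines how raw spectra are aggregated into the fixed-length summary
#' vector fed to the kernel. `blocks` is a named list; each element is
#' either a list of inclusive integer ranges (1D spectrum block) or a list
#' with `rows`, `cols` (axis ranges) and `exclude` (2D coordinates of
#' dropped cells, in bin units).
#'
#' @param blocks named list as described above.
#' @return an object of class `bin_spec` with a `dimension` field.
#' @export
bin_spec <- function(blocks) {
  dim_of <- function(b) {
    if (!is.null(b$rows)) length(b$rows) * length(b$cols) - length(b$exclude %||% list())
    else length(b)
  }
  d <- sum(vapply(blocks, dim_of, numeric(1)))
  structure(list(blocks = blocks, dimension = as.integer(d)), class = "bin_spec")
}

# inclusive integer ranges helper
ranges <- function(...) lapply(list(...), function(r) as.integer(r))

#' Default bin specifications
#'
#' `adna_bin_spec()` is the autosomal layout: per-population SFS over
#' derived-allele counts binned 1-4, 5-8, ..., 25-28, 29-36 (8 bins each;
#' the last bin is wider), plus a 7x7 2D-HFS over haplotype counts binned
#' 0, 1-6, 7-12, ..., 31-36 with the structurally empty (0, 0) cell
#' excluded (48 cells): 64 coordinates in total, in block order SFS_uar,
#' SFS_uma, 2D-HFS row-major.
#'
#' `mtdna_bin_spec()` is the single-block mtDNA 2D-SFS layout. By default
#' each axis keeps the full spectrum (one bin per derived count, 0..n) and
#' the excluded cells are (0, 0) plus, when `exclude_fixed`, the fixed
#' corner (n_uar, n_uma); `uma_breaks` may supply coarser intervals for the
#' polar axis (e.g. 0, 1-3, ..., 25-26 for the 26-chromosome set). The
#' exact excluded-cell set is configurable because published bin totals are
#' not fully reconstructible; the realized dimension is always reported by
#' the object.
#'
#' @param n_uar,n_uma sample sizes (chromosomes).
#' @param uma_breaks optional list of inclusive ranges for the uma axis.
#' @param exclude_fixed drop the all-derived corner cell.
#' @param exclude extra excluded cells, a list of `c(i, j)` bin coordinates.
#' @return a [bin_spec()].
#' @export
adna_bin_spec <- function(n_uar = 36L, n_uma = 36L) {
  stopifnot(n_uar == 36L, n_uma == 36L) # the layout is tied to 2n = 36 samples
  sfs_ranges <- ranges(c(1, 4), c(5, 8), c(9, 12), c(13, 16), c(17, 20),
                       c(21, 24), c(25, 28), c(29, 36))
  hfs_ranges <- ranges(c(0, 0), c(1, 6), c(7, 12), c(13, 18), c(19, 24),
                       c(25, 30), c(31, 36))
  bin_spec(list(
    SFS_uar = sfs_ranges,
    SFS_uma = sfs_ranges,
    HFS2D = list(rows = hfs_ranges, cols = hfs_ranges,
                 exclude = list(c(1L, 1L)))))
}

#' @rdname adna_bin_spec
#' @export
mtdna_bin_spec <- function(n_uar, n_uma, uma_breaks = NULL,
                           exclude_fixed = TRUE, exclude = list()) {
  row_ranges <- lapply(0:n_uar, function(i) c(i, i))
  col_ranges <- uma_breaks %||% lapply(0:n_uma, function(j) c(j, j))
  excl <- c(list(c(1L, 1L)), exclude)
  if (exclude_fixed) {
    # bin coordinates of the all-derived corner
    corner <- c(length(row_ranges),
                which(vapply(col_ranges, function(r) r[1] <= n_uma && n_uma <= r[2],
                             logical(1)))[1])
    excl <- c(excl, list(as.integer(corner)))
  }
  bin_spec(list(SFS2D = list(rows = row_ranges, cols = col_ranges,
                             exclude = excl)))
}

#' @rdname adna_bin_spec
#' @param n sample size for the pooled 1D spectrum.
#' @param breaks optional list of inclusive ranges over derived counts
#'   1..n; default one bin per count.
#' @export
sfs1d_bin_spec <- function(n, breaks = NULL) {
  bin_spec(list(SFS = breaks %||% lapply(seq_len(n), function(i) c(i, i))))
}

bin_index <- function(values, ranges) {
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  vapply(values, function(v) {
    w <- which(v >= lo & v <= hi)
    if (!length(w)) NA_integer_ else w[1]
  }, integer(1))
}

bin_1d <- function(spectrum, rng) {
  # spectrum indexed by count 1..n
  idx <- bin_index(seq_along(spectrum), rng)
  keep <- !is.na(idx)
  out <- numeric(length(rng))
  if (any(keep)) {
    agg <- rowsum(as.numeric(spectrum[keep]), idx[keep])
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

bin_2d <- function(tab, block) {
  # tab indexed from count 0 on both axes
  ri <- bin_index(seq_len(nrow(tab)) - 1L, block$rows)
  ci <- bin_index(seq_len(ncol(tab)) - 1L, block$cols)
  nr <- length(block$rows); nc <- length(block$cols)
  out <- matrix(0, nr, nc)
  flat <- outer(ri, ci, function(a, b) (a - 1L) * nc + b) # row-major bin id
  ok <- !is.na(flat)
  if (any(ok)) {
    agg <- rowsum(as.numeric(tab[ok]), as.vector(flat[ok]))
    out_t <- t(out)
    out_t[as.integer(rownames(agg))] <- agg[, 1]
    out <- t(out_t)
  }
  keep <- matrix(TRUE, nr, nc)
  for (e in block$exclude %||% list()) keep[e[1], e[2]] <- FALSE
  # row-major flattening
  as.numeric(t(out))[as.logical(t(keep))]
}

#' Aggregate raw spectra into a flat summary vector
#'
#' Applies a [bin_spec()] to a named list of raw tables (1D spectra as
#' vectors indexed from count 1; 2D tables indexed from 0 with dimnames)
#' and concatenates the blocks in the spec's order, dropping excluded
#' cells. 2D blocks are flattened row-major.
#'
#' @param tables named list matching `spec$blocks`.
#' @param spec a [bin_spec()].
#' @return a named numeric vector of class `summary_vector` with attribute
#'   `bin_spec`.
#' @export
bin_and_flatten <- function(tables, spec) {
  stopifnot(inherits(spec, "bin_spec"),
            identical(sort(names(tables)), sort(names(spec$blocks))))
  out <- numeric(0)
  for (nm in names(spec$blocks)) {
    b <- spec$blocks[[nm]]
    piece <- if (!is.null(b$rows)) bin_2d(tables[[nm]], b) else bin_1d(tables[[nm]], b)
    names(piece) <- paste0(nm, "_", seq_along(piece))
    out <- c(out, piece)
  }
  if (length(out) != spec$dimension)
    stop("flattened length ", length(out), " does not match spec dimension ",
         spec$dimension)
  structure(out, class = "summary_vector", bin_spec = spec)
}

#' Summarize a multi-locus dataset into the kernel's input vector
#'
#' For the autosomal mode, per-locus site spectra are pooled onto the
#' shared derived-count axis, per-locus haplotype tallies are pooled into
#' one 2D-HFS table, and the result is binned with the given spec (blocks
#' `SFS_uar`, `SFS_uma`, `HFS2D`). For the mtDNA mode (spec with single
#' block `SFS2D`) the pooled joint SFS is binned instead.
#'
#' @param ls a [locus_set()].
#' @param spec a [bin_spec()]; defaults to [adna_bin_spec()] when the block
#'   structure is autosomal.
#' @return a `summary_vector`.
#' @export
summarize_dataset <- function(ls, spec = adna_bin_spec(ls$n_uar, ls$n_uma)) {
  stopifnot(inherits(ls, "locus_set"), inherits(spec, "bin_spec"))
  if ("SFS2D" %in% names(spec$blocks)) {
    tab <- Reduce(`+`, lapply(ls$loci, joint_sfs))
    return(bin_and_flatten(list(SFS2D = tab), spec))
  }
  if (identical(names(spec$blocks), "SFS")) { # pooled-sample 1D spectrum
    xi <- Reduce(`+`, lapply(ls$loci, sfs, population = "all"))
    return(bin_and_flatten(list(SFS = xi), spec))
  }
  xi1 <- Reduce(`+`, lapply(ls$loci, sfs, population = "uar"))
  xi2 <- Reduce(`+`, lapply(ls$loci, sfs, population = "uma"))
  hfs <- joint_hfs(ls)
  bin_and_flatten(list(SFS_uar = xi1, SFS_uma = xi2, HFS2D = hfs), spec)
}

#' Export a spectrum table as TSV
#'
#' @param tab a matrix or named vector produced by the spectrum functions.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
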