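#' Population alignment
#'
#' An in-memory multiple alignment of equal-length nucleotide sequences
#' with one population label per sequence. Recognized labels are `uar`
#' (brown bear), `uma` (polar bear), `outgroup-panda` and
#' `outgroup-blackbear`; coordinates are 1-based throughout.
#'
#' @param ids character vector of sequence identifiers (unique).
#' @param populations character vector of labels, one per sequence.
#' @param sequences character vector of nucleotide strings (equal length),
#'   or a character matrix (sequences x sites).
#' @param positions optional 1-based site coordinates (defaults to
#'   `1:length`); kept through site filtering so edited datasets remember
#'   their original coordinates.
#' @return an object of class `alignment` holding a character matrix
#'   `seq` (sequences x sites) with uppercase bases.
#' @export
alignment <- function(ids, populations, sequences, positions = NULL) {
  if (is.character(sequences) && !is.matrix(sequences)) {
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L)
      stop("all sequences must have the same length")
    sequences <- do.call(rbind, strsplit(toupper(sequences), ""))
  } else {
    sequences <- toupper(as.matrix(sequences))
  }
  stopifnot(length(ids) == nrow(sequences),
            length(populations) == nrow(sequences),
            !anyDuplicated(ids))
  ok <- populations %in% c("uar", "uma", "outgroup-panda", "outgroup-blackbear")
  if (!all(ok))
    stop("unknown population label(s): ", paste(unique(populations[!ok]), collapse = ", "))
  positions <- positions %||% seq_len(ncol(sequences))
  stopifnot(length(positions) == ncol(sequences))
  rownames(sequences) <- ids
  structure(list(ids = as.character(ids), populations = as.character(populations),
                 seq = sequences, positions = as.integer(positions)),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d sites (%s)\n",
              nrow(x$seq), ncol(x$seq),
              paste(sprintf("%s:%d", names(table(x$populations)),
                            as.integer(table(x$populations))), collapse = ", ")))
  invisible(x)
}

#' Read / write alignments as multi-FASTA plus a population map
#'
#' The population map is a two-column tab-separated file (id, population)
#' with no header. On write, ids are used verbatim as FASTA headers.
#'
#' @param fasta path to a FASTA file.
#' @param popmap path to the id-to-population map; if `NULL` on read,
#'   populations are inferred from id prefixes (`uar`, `uma`, `panda`,
#'   `blackbear`).
#' @param align an `alignment` object (for writing).
#' @return `read_alignment()` returns an `alignment`;
#'   `write_alignment()` returns the fasta path invisibly.
#' @export
read_alignment <- function(fasta, popmap = NULL) {
  dna <- ape::read.FASTA(fasta)
  seqs <- toupper(vapply(as.character(dna), paste0, character(1), collapse = ""))
  ids <- names(dna)
  if (!is.null(popmap)) {
    map <- utils::read.table(popmap, sep = "\t", header = FALSE,
                             col.names = c("id", "population"),
                             stringsAsFactors = FALSE)
    idx <- match(ids, map$id)
    if (anyNA(idx)) stop("popmap is missing ids: ",
                         paste(head(ids[is.na(idx)]), collapse = ", "))
    pops <- map$population[idx]
  } else {
    pops <- ifelse(grepl("^uar", ids), "uar",
            ifelse(grepl("^uma", ids), "uma",
            ifelse(grepl("panda", ids), "outgroup-panda",
            ifelse(grepl("blackbear", ids), "outgroup-blackbear", NA))))
    if (anyNA(pops)) stop("cannot infer populations from ids; supply a popmap")
  }
  alignment(ids, pops, seqs)
}

#' @rdname read_alignment
#' @export
write_alignment <- function(align, fasta, popmap = NULL) {
  stopifnot(inherits(align, "alignment"))
  lines <- character(0)
  for (i in seq_along(align$ids)) {
    lines <- c(lines, paste0(">", align$ids[i]),
               paste(align$seq[i, ], collapse = ""))
  }
  writeLines(lines, fasta)
  if (!is.null(popmap))
    utils::write.table(data.frame(align$ids, align$populations),
                       popmap, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(fasta)
}

#' Binary derived/ancestral haplotype matrix
#'
#' The unit all statistics are computed from: a sites x chromosomes 0/1
#' matrix (0 = ancestral, 1 = derived) for the ingroup, with the first
#' `n_uar` columns from population 1. Rows flagged `fixed` carry a derived
#' allele on every ingroup chromosome (relative to the outgroup); they are
#' retained only for mtDNA joint spectra whose bin structure includes the
#' fixed class.
#'
#' @param mat 0/1 integer matrix, sites x chromosomes.
#' @param positions site coordinates (1-based bp, or continuous locus
#'   fractions for simulated data).
#' @param n_uar,n_uma chromosomes per population (columns).
#' @param locus_id optional label.
#' @param fixed logical vector flagging fixed-derived rows.
#' @return an object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(mat, positions = NULL, n_uar, n_uma,
                             locus_id = NA_character_, fixed = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  stopifnot(ncol(mat) == n_uar + n_uma, all(mat %in% c(0L, 1L)))
  positions <- positions %||% seq_len(nrow(mat))
  fixed <- fixed %||% rep(FALSE, nrow(mat))
  stopifnot(length(positions) == nrow(mat), length(fixed) == nrow(mat))
  dac <- rowSums(mat)
  if (any(dac == 0L))
    stop("non-segregating (all-ancestral) rows are not allowed")
  if (any(dac == ncol(mat) & !fixed))
    stop("fixed-derived rows must be flagged via `fixed`")
  structure(list(mat = mat, positions = positions,
                 n_uar = as.integer(n_uar), n_uma = as.integer(n_uma),
                 locus_id = locus_id, fixed = as.logical(fixed)),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("Haplotype matrix%s: %d segregating sites x (%d uar + %d uma) chromosomes%s\n",
              if (is.na(x$locus_id)) "" else paste0(" [", x$locus_id, "]"),
              nrow(x$mat), x$n_uar, x$n_uma,
              if (any(x$fixed)) sprintf(" (%d fixed-derived)", sum(x$fixed)) else ""))
  invisible(x)
}

# Column index helpers
uar_cols <- function(hm) seq_len(hm$n_uar)
uma_cols <- function(hm) hm$n_uar + seq_len(hm$n_uma)

VALID_BASES <- c("A", "C", "G", "T")

#' Polarize segregating sites against outgroups
#'
#' Assigns the ancestral allele at every ingroup-segregating site using the
#' two-tier outgroup rule: (1) if both black-bear outgroup sequences carry
#' the same allele and that allele occurs among the ingroup alleles, it is
#' ancestral; (2) otherwise, if the giant-panda allele occurs among the
#' ingroup alleles, the panda allele is ancestral; (3) otherwise the site is
#' dropped and logged. Sites with more than two ingroup alleles violate the
#' infinite-sites model and are dropped, as are sites with gaps or
#' ambiguity codes in any retained sequence. When no black-bear sequences
#' are present, rule (2) alone applies.
#'
#' @param align an `alignment` containing `uar`/`uma` ingroup sequences and
#'   at least one outgroup sequence.
#' @param include_fixed if `TRUE`, ingroup-monomorphic sites whose allele
#'   differs from the (rule-determined) outgroup allele are retained as
#'   fixed-derived rows; used for mtDNA joint spectra.
#' @return a [haplotype_matrix()]; attribute `dropped` is a data.frame
#'   logging excluded sites and the reason.
#' @export
polarize_sites <- function(align, include_fixed = FALSE) {
  stopifnot(inherits(align, "alignment"))
  ing <- align$populations %in% c("uar", "uma")
  bb <- align$populations == "outgroup-blackbear"
  pd <- align$populations == "outgroup-panda"
  if (!any(bb) && !any(pd)) stop("at least one outgroup sequence is required")
  if (any(bb) && sum(bb) != 2L)
    stop("the black-bear rule requires exactly 2 black-bear sequences")
  # ingroup ordered uar first, uma second
  ord <- c(which(align$populations == "uar"), which(align$populations == "uma"))
  n1 <- sum(align$populations == "uar")
  n2 <- sum(align$populations == "uma")
  if (n1 + n2 == 0L) stop("no ingroup sequences")

  S <- align$seq
  keep_rows <- integer(0); anc <- character(0); fixed <- logical(0)
  dropped <- list()
  note <- function(site, reason)
    dropped[[length(dropped) + 1L]] <<- data.frame(position = align$positions[site],
                                                   reason = reason)
  for (s in seq_len(ncol(S))) {
    col <- S[, s]
    if (any(!col %in% VALID_BASES)) { # gaps/ambiguity anywhere -> excluded
      if (length(unique(col[ord])) > 1L) note(s, "gap-or-ambiguity")
      next
    }
    ing_alleles <- unique(col[ord])
    if (length(ing_alleles) > 2L) { note(s, "more-than-two-ingroup-alleles"); next }
    ancestral <- NA_character_
    bb_alleles <- col[bb]
    if (length(bb_alleles) == 2L && bb_alleles[1] == bb_alleles[2] &&
        bb_alleles[1] %in% ing_alleles) {
      ancestral <- bb_alleles[1]
    } else if (any(pd) && col[pd][1] %in% ing_alleles) {
      ancestral <- col[pd][1]
    }
    if (length(ing_alleles) == 1L) {
      # monomorphic ingroup: potentially fixed-derived relative to outgroup
      if (!include_fixed) next
      out_allele <- if (length(bb_alleles) == 2L && bb_alleles[1] == bb_alleles[2])
        bb_alleles[1] else if (any(pd)) col[pd][1] else NA_character_
      if (!is.na(out_allele) && out_allele != ing_alleles) {
        keep_rows <- c(keep_rows, s); anc <- c(anc, out_allele); fixed <- c(fixed, TRUE)
      }
      next
    }
    if (is.na(ancestral)) { note(s, "no-polarization-rule"); next }
    keep_rows <- c(keep_rows, s); anc <- c(anc, ancestral); fixed <- c(fixed, FALSE)
  }

  mat <- matrix(0L, length(keep_rows), n1 + n2)
  for (k in seq_along(keep_rows))
    mat[k, ] <- as.integer(S[ord, keep_rows[k]] != anc[k])
  hm <- haplotype_matrix(mat, positions = align$positions[keep_rows],
                         n_uar = n1, n_uma = n2, fixed = fixed)
  attr(hm, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(position = integer(0), reason = character(0))
  attr(hm, "ancestral") <- anc
  hm
}

#' Four-gamete scan
#'
#' Finds every pair of segregating sites exhibiting all four gametes
#' (00, 01, 10, 11) across chromosomes. Under infinite sites such a pair
#' implies recombination; in non-recombining mtDNA it implies recurrent
#' mutation.
#'
#' @param x a [haplotype_matrix()] or a plain 0/1 matrix (sites x
#'   chromosomes).
#' @return a data.frame with columns `site1`, `site2` (row indices,
#'   site1 < site2), empty when all pairs are compatible.
#' @export
four_gamete_scan <- function(x) {
  mat <- if (inherits(x, "haplotype_matrix")) x$mat else as.matrix(x)
  S <- nrow(mat)
  if (S < 2L) return(data.frame(site1 = integer(0), site2 = integer(0)))
  X <- mat
  n11 <- tcrossprod(X)                    # count of chromosomes with 1&1
  rs <- rowSums(X)
  n10 <- outer(rs, rep(1, S)) - n11       # 1 at i, 0 at j
  n01 <- outer(rep(1, S), rs) - n11
  n00 <- ncol(X) - n11 - n10 - n01
  bad <- (n11 > 0) & (n10 > 0) & (n01 > 0) & (n00 > 0)
  idx <- which(bad & upper.tri(bad), arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  data.frame(site1 = as.integer(idx[ord, 1]), site2 = as.integer(idx[ord, 2]))
}

# Binary encoding of the ingroup portion of an alignment for the
# four-gamete machinery; polarization is irrelevant to gamete counts, so
# each clean biallelic site is coded against its first observed allele.
# Returns NULL rows for sites that are not clean biallelic ingroup SNPs,
# plus the classification of every column.
ingroup_binary <- function(align) {
  ing <- which(align$populations %in% c("uar", "uma"))
  S <- align$seq[ing, , drop = FALSE]
  n_sites <- ncol(S)
  class <- character(n_sites)
  rows <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    col <- S[, s]
    if (any(!col %in% VALID_BASES)) { class[s] <- "unusable"; next }
    al <- unique(col)
    if (length(al) == 1L) { class[s] <- "monomorphic"; next }
    if (length(al) > 2L) { class[s] <- "multiallelic"; next }
    class[s] <- "biallelic"
    rows[[s]] <- as.integer(col != al[1])
  }
  list(rows = rows, class = class, ingroup = ing)
}

#' Edit a non-recombining alignment into four-gamete-compatible sets
#'
#' Two editing strategies for alignments (typically whole mtDNA) that
#' contain recurrent mutations: `"exclude-sequences"` iteratively removes
#' the sequence involved in the most four-gamete-incompatible site pairs
#' (carrying a minimal-count gamete; ties broken by removing the
#' lexicographically smallest id) while removal keeps resolving pairs, then
#' truncates the alignment to the longest prefix free of incompatibilities;
#' `"exclude-sites"` removes every site that participates in at least one
#' incompatible pair (and every multi-allelic site). The result always
#' passes [four_gamete_scan()] empty.
#'
#' @param align an `alignment` (outgroup sequences, if present, are carried
#'   through unchanged and ignored by the scan).
#' @param mode `"exclude-sequences"` or `"exclude-sites"`.
#' @return an edited `alignment`; attributes `removed_sequences` /
#'   `removed_sites` log the edits.
#' @export
build_mtdna_sets <- function(align, mode = c("exclude-sequences", "exclude-sites")) {
  mode <- match.arg(mode)
  stopifnot(inherits(align, "alignment"))

  if (mode == "exclude-sites") {
    enc <- ingroup_binary(align)
    bi <- which(enc$class == "biallelic")
    mat <- do.call(rbind, enc$rows[bi])
    bad_sites <- integer(0)
    if (!is.null(mat) && nrow(mat) >= 2L) {
      pairs <- four_gamete_scan(mat)
      bad_sites <- bi[unique(c(pairs$site1, pairs$site2))]
    }
    bad_sites <- sort(unique(c(bad_sites, which(enc$class == "multiallelic"))))
    keep <- setdiff(seq_len(ncol(align$seq)), bad_sites)
    out <- alignment(align$ids, align$populations,
                     align$seq[, keep, drop = FALSE],
                     positions = align$positions[keep])
    attr(out, "removed_sites") <- align$positions[bad_sites]
    return(out)
  }

  # exclude-sequences
  keep_ids <- align$ids
  ing_pops <- c("uar", "uma")
  repeat {
    sub <- subset_alignment(align, keep_ids)
    enc <- ingroup_binary(sub)
    bi <- which(enc$class == "biallelic")
    mat <- do.call(rbind, enc$rows[bi])
    pairs <- if (is.null(mat) || nrow(mat) < 2L)
      data.frame(site1 = integer(0), site2 = integer(0)) else four_gamete_scan(mat)
    if (nrow(pairs) == 0L) break
    ing_ids <- sub$ids[enc$ingroup]
    degree <- stats::setNames(numeric(length(ing_ids)), ing_ids)
    for (p in seq_len(nrow(pairs))) {
      g1 <- enc$rows[[bi[pairs$site1[p]]]]
      g2 <- enc$rows[[bi[pairs$site2[p]]]]
      gam <- paste0(g1, g2)
      tab <- table(gam)
      rare <- names(tab)[tab == min(tab)]
      carriers <- ing_ids[gam %in% rare]
      degree[carriers] <- degree[carriers] + 1
    }
    if (max(degree) <= 0) break
    n_ing_left <- sum(align$populations[match(keep_ids, align$ids)] %in% ing_pops)
    if (n_ing_left <= 2L) break   # refuse to empty the ingroup; fall through to truncation
    worst <- names(degree)[degree == max(degree)]
    victim <- sort(worst)[1]
    keep_ids <- setdiff(keep_ids, victim)
  }
  sub <- subset_alignment(align, keep_ids)
  if (!any(sub$populations %in% ing_pops)) stop("all ingroup sequences removed")

  # prefix truncation: drop everything from the first surviving
  # incompatibility onward
  enc <- ingroup_binary(sub)
  bi <- which(enc$class == "biallelic")
  mat <- do.call(rbind, enc$rows[bi])
  cutoff <- ncol(sub$seq)
  if (!is.null(mat) && nrow(mat) >= 2L) {
    pairs <- four_gamete_scan(mat)
    if (nrow(pairs) > 0L)
      cutoff <- min(pmax(bi[pairs$site1], bi[pairs$site2])) - 1L
  }
  keep_sites <- seq_len(cutoff)
  out <- alignment(sub$ids, sub$populations,
                   sub$seq[, keep_sites, drop = FALSE],
                   positions = sub$positions[keep_sites])
  attr(out, "removed_sequences") <- setdiff(align$ids, keep_ids)
  attr(out, "prefix_end") <- if (cutoff >= 1L) sub$positions[cutoff] else 0L
  out
}

subset_alignment <- function(align, ids) {
  idx <- match(ids, align$ids)
  alignment(align$ids[idx], align$populations[idx],
            align$seq[idx, , drop = FALSE], positions = align$positions)
}

#' Multi-locus dataset
#'
#' A list of per-locus haplotype matrices with shared sample sizes, plus
#' the per-locus mutation model, as pooled by the summary statistics.
#'
#' @param loci list of [haplotype_matrix()] objects.
#' @param mu_per_site,length,recombination per-locus mutation model (scalars,
#'   recycled).
#' @return an object of class `locus_set`.
#' @export
locus_set <- function(loci, mu_per_site = NA_real_, length = NA_integer_,
                      recombination = NA_character_) {
  stopifnot(length(loci) >= 1, all(vapply(loci, inherits, logical(1), "haplotype_matrix")))
  n1 <- unique(vapply(loci, function(l) l$n_uar, integer(1)))
  n2 <- unique(vapply(loci, function(l) l$n_uma, integer(1)))
  if (length(n1) != 1L || length(n2) != 1L)
    stop("all loci must share the same sample sizes")
  structure(list(loci = loci, n_uar = n1, n_uma = n2,
                 mu_per_site = mu_per_site, length = length,
                 recombination = recombination),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("Locus set: %d loci, %d + %d chromosomes, %d segregating sites total\n",
              length(x$loci), x$n_uar, x$n_uma,
              sum(vapply(x$loci, function(l) nrow(l$mat), integer(1)))))
  invisible(x)
}
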