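# Positive-selection scan on the hybrid lineage: per-gene polymorphism /
# divergence counts, the gene-vs-genome HKA chi-square, fixed
# non-synonymous counts, parent-of-origin assignment from haplotype
# trees, and the three-criterion PSG / two-criterion hybrid-signal calls
# under the two groupings (hybrid+C vs O, hybrid+O vs C).

GROUPINGS <- c("DC_vs_O", "DO_vs_C")

.grouping_sides <- function(grouping) {
  grouping <- gsub("-", "_", grouping)
  switch(grouping,
         DC_vs_O = list(pair = c("D", "C"), contrast = "O"),
         DO_vs_C = list(pair = c("D", "O"), contrast = "C"),
         stop("grouping must be 'DC_vs_O' or 'DO_vs_C'"))
}

# rows of an alignment belonging to the given groups
.aln_rows <- function(aln, groups, which_groups) {
  g <- .tip_groups(rownames(aln), groups)
  which(g %in% which_groups)
}

# integer-code an alignment; anything outside ACGT (gap, ambiguity) -> NA
.aln_int <- function(aln) {
  m <- match(aln, BASES)
  dim(m) <- dim(aln)
  m
}

#' Per-gene polymorphism and divergence counts
#'
#' Counts, over alignment columns, `S`: sites polymorphic within the
#' combined pair (the hybrid plus one parent), and `K`: sites at which
#' the combined pair and the contrast lineage are each fixed for
#' different states.  Columns containing a gap or ambiguity among the
#' used haplotypes are excluded and counted.
#'
#' @param aln haplotype x position character matrix.
#' @param groups group map resolving row names (or `NULL` to parse
#'   labels).
#' @param grouping `"DC_vs_O"` (hybrid+C against O) or `"DO_vs_C"`.
#' @return A list with `S`, `K` and `n_excluded`.
#' @export
polymorphism_divergence <- function(aln, groups = NULL,
                                    grouping = "DC_vs_O") {
  sides <- .grouping_sides(grouping)
  pair <- .aln_rows(aln, groups, sides$pair)
  con <- .aln_rows(aln, groups, sides$contrast)
  if (!length(pair) || !length(con))
    stop("empty side: alignment lacks haplotypes for the grouping")
  m <- .aln_int(aln)
  mp <- m[pair, , drop = FALSE]
  mc <- m[con, , drop = FALSE]
  usable <- colSums(is.na(mp)) == 0L & colSums(is.na(mc)) == 0L
  poly_p <- colSums(mp != mp[rep(1L, nrow(mp)), , drop = FALSE]) > 0L
  fixed_c <- colSums(mc != mc[rep(1L, nrow(mc)), , drop = FALSE]) == 0L
  S <- sum(usable & poly_p)
  K <- sum(usable & !poly_p & fixed_c & mp[1L, ] != mc[1L, ])
  list(S = S, K = K, n_excluded = sum(!usable))
}

#' Gene-versus-genome HKA chi-square
#'
#' The operational HKA contrast: a 2x2 chi-square (1 df, no continuity
#' correction) of the focal gene's polymorphism/divergence counts against
#' the remainder of the genome-wide totals,
#' `[[S_gene, K_gene], [S_genome - S_gene, K_genome - K_gene]]`.
#' Genome totals include the focal gene (it is subtracted in the second
#' row).  Under neutrality the gene's S:K proportion matches the genome's
#' and the statistic is ~0.
#'
#' @param s_gene,k_gene focal-gene counts.
#' @param s_genome,k_genome genome-wide totals (each >= the gene count).
#' @return A list with `statistic` and `p_value` (`NA` with a note when a
#'   margin is zero).
#' @export
hka_test <- function(s_gene, k_gene, s_genome, k_genome) {
  if (s_gene > s_genome || k_gene > k_genome)
    stop("genome totals must be at least the gene counts")
  if (s_genome + k_genome <= 0) stop("genome totals must be positive")
  a <- s_gene; b <- k_gene
  c <- s_genome - s_gene; d <- k_genome - k_gene
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    return(list(statistic = NA_real_, p_value = NA_real_,
                note = "zero margin"))
  N <- a + b + c + d
  stat <- N * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fixed non-synonymous differences between the two sides
#'
#' Counts codon positions at which the combined pair and the contrast
#' lineage are each fixed for different codons encoding different amino
#' acids.  Codons containing a gap or ambiguity in any used haplotype are
#' skipped (and counted); a consensus codon that is a stop triggers a
#' warning and is skipped.
#'
#' @inheritParams polymorphism_divergence
#' @return Integer count, with attribute `n_skipped`.
#' @export
count_fixed_nonsynonymous <- function(aln, groups = NULL,
                                      grouping = "DC_vs_O") {
  if (ncol(aln) %% 3L != 0L)
    stop("alignment length must be divisible by 3")
  sides <- .grouping_sides(grouping)
  pair <- .aln_rows(aln, groups, sides$pair)
  con <- .aln_rows(aln, groups, sides$contrast)
  if (!length(pair) || !length(con))
    stop("empty side: alignment lacks haplotypes for the grouping")
  m <- .aln_int(aln)
  mp <- m[pair, , drop = FALSE]
  mc <- m[con, , drop = FALSE]
  ok <- colSums(is.na(mp)) == 0L & colSums(is.na(mc)) == 0L
  fix_p <- ok & colSums(mp != mp[rep(1L, nrow(mp)), , drop = FALSE]) == 0L
  fix_c <- ok & colSums(mc != mc[rep(1L, nrow(mc)), , drop = FALSE]) == 0L
  n_cod <- ncol(aln) %/% 3L
  i1 <- 3L * seq_len(n_cod) - 2L
  cod_ok <- ok[i1] & ok[i1 + 1L] & ok[i1 + 2L]
  cod_fix <- fix_p[i1] & fix_p[i1 + 1L] & fix_p[i1 + 2L] &
    fix_c[i1] & fix_c[i1 + 1L] & fix_c[i1 + 2L]
  diff_cod <- cod_fix &
    (mp[1L, i1] != mc[1L, i1] | mp[1L, i1 + 1L] != mc[1L, i1 + 1L] |
       mp[1L, i1 + 2L] != mc[1L, i1 + 2L])
  n_fix <- 0L
  n_stop <- 0L
  if (any(diff_cod)) {
    tab <- .codon_aa()
    for (ci in which(diff_cod)) {
      cols <- (3L * ci - 2L):(3L * ci)
      cp <- paste(BASES[mp[1L, cols]], collapse = "")
      cc <- paste(BASES[mc[1L, cols]], collapse = "")
      ap <- tab[[cp]]; ac <- tab[[cc]]
      if (ap == "*" || ac == "*") { n_stop <- n_stop + 1L; next }
      if (ap != ac) n_fix <- n_fix + 1L
    }
  }
  if (n_stop > 0L)
    warning(n_stop, " consensus stop codon(s) skipped")
  structure(n_fix, n_skipped = sum(!cod_ok))
}

#' Flag values in the top fraction of a ranking
#'
#' `TRUE` for values at or above the cutoff, defined as the
#' `ceiling(fraction * n)`-th largest value; all ties at the cutoff are
#' included.  A value of zero never ranks in the top fraction (for count
#' data, zero is the absence of signal, and a zero cutoff would otherwise
#' flag everything through the tie rule).  With all (positive) values
#' equal every gene is flagged (degenerate, reported via a message).
#'
#' @param values numeric vector (`NA` never flagged).
#' @param fraction top fraction to keep (default 0.025).
#' @return Logical vector along `values`.
#' @export
rank_top_fraction <- function(values, fraction = 0.025) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  ok <- !is.na(values)
  if (!any(ok)) return(rep(FALSE, length(values)))
  k <- max(1L, ceiling(fraction * sum(ok)))
  thr <- sort(values[ok], decreasing = TRUE)[k]
  out <- !is.na(values) & values >= thr & values > 0
  if (any(out) && all(out[ok])) message("degenerate ranking: all values tied")
  out
}

# p-distance matrix between amino-acid haplotype rows ("X" = missing)
.aa_pdist <- function(aa) {
  n <- nrow(aa)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- aa[i, ] != "X" & aa[j, ] != "X"
    d[i, j] <- d[j, i] <- if (any(ok)) mean(aa[i, ok] != aa[j, ok]) else 0
  }
  d
}

# codon character matrix -> amino-acid matrix (unknown codons -> "X")
.translate_aln <- function(aln) {
  n_cod <- ncol(aln) %/% 3L
  i1 <- 3L * seq_len(n_cod) - 2L
  cod <- matrix(paste0(aln[, i1], aln[, i1 + 1L], aln[, i1 + 2L]),
                nrow = nrow(aln))
  tab <- .codon_aa()
  aa <- matrix(tab[cod], nrow = nrow(aln))
  aa[is.na(aa)] <- "X"
  rownames(aa) <- rownames(aln)
  aa
}

#' Parent-of-origin assignment from a haplotype tree
#'
#' Builds a neighbour-joining tree (p-distance) on the unique protein
#' haplotypes of the C, D and O haplotypes, then assigns every
#' hybrid-lineage (D) haplotype copy to the parent whose nearest
#' haplotype is closer on the tree (patristic distance).  The origin is
#' called for a parent holding at least `threshold` of the D copies
#' (ties count for neither parent); otherwise `"ambiguous"`.
#'
#' @param aln codon-frame haplotype alignment (rows named by haplotype).
#' @param groups optional group map.
#' @param threshold fraction of D copies required for a call (default
#'   0.8).
#' @return `"parentC"`, `"parentO"` or `"ambiguous"` with attribute
#'   `fraction_c`.
#' @export
assign_origin <- function(aln, groups = NULL, threshold = 0.8) {
  if (ncol(aln) %% 3L != 0L)
    stop("alignment length must be divisible by 3")
  g <- .tip_groups(rownames(aln), groups)
  use <- g %in% c("C", "D", "O")
  if (!any(g == "D") || !any(g == "C") || !any(g == "O"))
    stop("need haplotypes from D and both parents")
  aa <- .translate_aln(aln[use, , drop = FALSE])
  gu <- g[use]
  seqs <- apply(aa, 1L, paste, collapse = "")
  uniq <- unique(seqs)
  if (length(uniq) < 2L)
    return(structure("ambiguous", fraction_c = NA_real_,
                     note = "fewer than two unique haplotypes"))
  hap_of <- match(seqs, uniq)
  mult <- function(grp) tabulate(hap_of[gu == grp], nbins = length(uniq))
  mc <- mult("C"); md <- mult("D"); mo <- mult("O")
  aa_u <- aa[match(uniq, seqs), , drop = FALSE]
  pd <- .aa_pdist(aa_u)
  if (length(uniq) >= 3L) {
    rownames(pd) <- colnames(pd) <- paste0("h", seq_along(uniq))
    tree <- ape::nj(stats::as.dist(pd))
    pat <- ape::cophenetic.phylo(tree)
    pd <- pat[paste0("h", seq_along(uniq)), paste0("h", seq_along(uniq))]
  }
  votes_c <- votes_o <- 0
  for (h in which(md > 0)) {
    dc <- if (mc[h] > 0) 0 else min(pd[h, mc > 0])
    do_ <- if (mo[h] > 0) 0 else min(pd[h, mo > 0])
    if (dc < do_) votes_c <- votes_c + md[h]
    else if (do_ < dc) votes_o <- votes_o + md[h]
  }
  total <- sum(md)
  frac_c <- votes_c / total
  out <- if (frac_c >= threshold) "parentC"
         else if (votes_o / total >= threshold) "parentO"
         else "ambiguous"
  structure(out, fraction_c = frac_c)
}

#' Alternating parent-fixed amino-acid states within a gene
#'
#' Over amino-acid positions where C and O are fixed for different
#' residues and D is fixed, counts positions where D matches the C
#' residue (`k_from_c`) and where it matches the O residue (`k_from_o`).
#' A recombinant gene inherits blocks from both parents, so both counts
#' are positive.
#'
#' @inheritParams assign_origin
#' @return A list with `k_from_c` and `k_from_o`.
#' @export
alternating_fixed_aa <- function(aln, groups = NULL) {
  if (ncol(aln) %% 3L != 0L)
    stop("alignment length must be divisible by 3")
  g <- .tip_groups(rownames(aln), groups)
  aa <- .translate_aln(aln)
  fixed_res <- function(grp) {
    sub <- aa[g == grp, , drop = FALSE]
    ok <- colSums(sub == "X") == 0L &
      colSums(sub != sub[rep(1L, nrow(sub)), , drop = FALSE]) == 0L
    ifelse(ok, sub[1L, ], NA_character_)
  }
  rc <- fixed_res("C"); ro <- fixed_res("O"); rd <- fixed_res("D")
  informative <- !is.na(rc) & !is.na(ro) & !is.na(rd) & rc != ro
  list(k_from_c = sum(informative & rd == rc),
       k_from_o = sum(informative & rd == ro))
}

#' Per-gene statistics for one grouping
#'
#' Computes `S`, `K`, the fixed non-synonymous count, and the
#' gene-vs-genome HKA test for every gene under one grouping, plus the
#' top-fraction flag on the non-synonymous counts.
#'
#' @param alignments an `alignment_set` (or named list of codon
#'   matrices).
#' @param groups group map (defaults to the set's own `groups`
#'   attribute).
#' @param grouping `"DC_vs_O"` or `"DO_vs_C"`.
#' @param top_fraction top fraction for the non-synonymous ranking.
#' @return A data frame, one row per gene.
#' @export
gene_statistics <- function(alignments, groups = NULL,
                            grouping = "DC_vs_O", top_fraction = 0.025) {
  if (is.null(groups)) groups <- attr(alignments, "groups")
  genes <- names(alignments)
  if (is.null(genes)) genes <- sprintf("gene%04d", seq_along(alignments))
  S <- K <- nfx <- integer(length(alignments))
  for (i in seq_along(alignments)) {
    pd <- polymorphism_divergence(alignments[[i]], groups, grouping)
    S[i] <- pd$S; K[i] <- pd$K
    nfx[i] <- as.integer(count_fixed_nonsynonymous(alignments[[i]],
                                                   groups, grouping))
  }
  s_tot <- sum(S); k_tot <- sum(K)
  hka <- lapply(seq_along(S), function(i)
    hka_test(S[i], K[i], s_tot, k_tot))
  data.frame(gene = genes, grouping = grouping, S = S, K = K,
             n_fix = nfx,
             hka_chisq = vapply(hka, function(h)
               if (is.na(h$statistic)) NA_real_ else h$statistic, 0),
             hka_p = vapply(hka, function(h)
               if (is.na(h$p_value)) NA_real_ else h$p_value, 0),
             top_nfix = rank_top_fraction(nfx, top_fraction),
             stringsAsFactors = FALSE)
}

#' Three-criterion PSG calls
#'
#' A gene is a positively selected gene (PSG) derived from parent C when,
#' under the hybrid+C-vs-O grouping, its HKA p value is at most
#' `hka_alpha`, its fixed non-synonymous count is in the top fraction,
#' and its origin call is `parentC`; symmetrically for parent O under
#' the hybrid+O-vs-C grouping.  The two lists are disjoint because a
#' gene has a single origin call.
#'
#' @param stats row-bound [gene_statistics()] for both groupings.
#' @param origins named character vector of origin calls per gene
#'   (genes absent from it are treated as unassessed/ambiguous).
#' @param hka_alpha HKA significance threshold (default 0.01).
#' @return A list with `from_c` and `from_o` gene-id vectors.
#' @export
call_psgs <- function(stats, origins, hka_alpha = 0.01) {
  pass <- function(grp) {
    s <- stats[stats$grouping == grp, , drop = FALSE]
    s$gene[!is.na(s$hka_p) & s$hka_p <= hka_alpha & s$top_nfix]
  }
  org <- function(genes, lab)
    genes[!is.na(origins[genes]) & origins[genes] == lab]
  list(from_c = sort(org(pass("DC_vs_O"), "parentC")),
       from_o = sort(org(pass("DO_vs_C"), "parentO")))
}

#' Two-criterion hybrid-signal calls
#'
#' Genes passing the HKA and top-fraction criteria under BOTH groupings
#' (no phylogenetic criterion): candidates for hybrid recombination,
#' carrying selected material from each parent.
#'
#' @inheritParams call_psgs
#' @return Sorted vector of gene ids.
#' @export
call_hybrid_signal <- function(stats, hka_alpha = 0.01) {
  pass <- function(grp) {
    s <- stats[stats$grouping == grp, , drop = FALSE]
    s$gene[!is.na(s$hka_p) & s$hka_p <= hka_alpha & s$top_nfix]
  }
  sort(intersect(pass("DC_vs_O"), pass("DO_vs_C")))
}

#' Full positive-selection and hybrid-signal scan
#'
#' Runs [gene_statistics()] under both groupings, assigns origins (only
#' for genes that already pass the two cheap criteria in some grouping),
#' and produces the PSG lists, the hybrid-signal list and alternating
#' amino-acid counts for the hybrid-signal genes.
#'
#' @param alignments an `alignment_set`.
#' @param groups group map (defaults to the set's attribute).
#' @param hka_alpha HKA threshold (default 0.01).
#' @param top_fraction non-synonymous ranking fraction (default 0.025).
#' @param origin_threshold fraction of D haplotype copies required for an
#'   origin call (default 0.8).
#' @return A `psg_call_set`: `stats`, `origins`, `psg_from_c`,
#'   `psg_from_o`, `hybrid_signal`, `alternating`.
#' @export
psg_scan <- function(alignments, groups = NULL, hka_alpha = 0.01,
                     top_fraction = 0.025, origin_threshold = 0.8) {
  if (is.null(groups)) groups <- attr(alignments, "groups")
  stats <- rbind(
    gene_statistics(alignments, groups, "DC_vs_O", top_fraction),
    gene_statistics(alignments, groups, "DO_vs_C", top_fraction))
  pass2 <- unique(stats$gene[!is.na(stats$hka_p) &
                               stats$hka_p <= hka_alpha & stats$top_nfix])
  origins <- vapply(pass2, function(g)
    as.character(assign_origin(alignments[[g]], groups,
                               origin_threshold)), "")
  calls <- call_psgs(stats, origins, hka_alpha)
  hybrid <- call_hybrid_signal(stats, hka_alpha)
  altern <- if (length(hybrid)) {
    do.call(rbind, lapply(hybrid, function(g) {
      k <- alternating_fixed_aa(alignments[[g]], groups)
      data.frame(gene = g, k_from_c = k$k_from_c, k_from_o = k$k_from_o,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene = character(), k_from_c = integer(),
               k_from_o = integer())
  }
  structure(list(stats = stats, origins = origins,
                 psg_from_c = calls$from_c, psg_from_o = calls$from_o,
                 hybrid_signal = hybrid, alternating = altern,
                 hka_alpha = hka_alpha, top_fraction = top_fraction),
            class = "psg_call_set")
}

#' @export
print.psg_call_set <- function(x, ...) {
  cat(sprintf(
    "PSG scan: %d genes from C, %d from O, %d hybrid-signal genes\n",
    length(x$psg_from_c), length(x$psg_from_o), length(x$hybrid_signal)))
  invisible(x)
}
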