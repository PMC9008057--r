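# Reading and writing the standard formats: VCF 4.2, newick, FASTA, TSV.

#' Write a variant table as uncompressed VCF 4.2
#'
#' Emits biallelic records with a GT FORMAT field; coordinates are 1-based
#' as usual in VCF.  Dosages 0/1/2 become `0/0`, `0/1`, `1/1` (haploid: `0`
#' / `1`); missing calls become `./.`.
#'
#' @param vt a [variant_table()].
#' @param path output path.
#' @export
write_vcf <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  m <- vt$markers
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", unique(m$chrom)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vt$samples), collapse = "\t"))
  gt_code <- if (vt$ploidy == 2) c("0/0", "0/1", "1/1") else c("0", "1")
  g <- vt$geno
  gt <- matrix(gt_code[g + 1L], nrow = nrow(g))
  gt[is.na(g)] <- if (vt$ploidy == 2) "./." else "."
  body <- paste(m$chrom, m$pos, ".", m$ref, m$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  if (!nrow(m)) body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read biallelic variants from a VCF and attach a group map
#'
#' Multi-allelic records are skipped (their count is reported in the
#' `n_multiallelic_skipped` attribute and via a message).  The marker class
#' and indel length are computed from REF/ALT.  Every sample in the VCF
#' must appear in the group map.
#'
#' @param vcf_path path to a VCF (plain or gzipped).
#' @param groups path to a sample-to-group TSV, or a `group_map`.
#' @return A list with elements `variants` (a [variant_table()]) and
#'   `groups` (a `group_map`).
#' @export
read_variants <- function(vcf_path, groups) {
  gm <- if (is.character(groups) && length(groups) == 1L &&
            file.exists(groups)) read_group_map(groups)
        else as_group_map(groups)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1L]
  if (is.null(samples)) stop("VCF has no sample columns")
  missing <- setdiff(samples, gm$sample)
  if (length(missing))
    stop("sample(s) in VCF missing from group map: ",
         paste(missing, collapse = ", "))
  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT)
  n_skip <- sum(multi)
  if (n_skip) message(n_skip, " multi-allelic record(s) skipped")
  keep <- !multi
  fix <- fix[keep, , drop = FALSE]
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = sum(keep),
                                     dimnames = list(NULL, samples))
  dos <- .gt_to_dosage(gt)
  ploidy <- attr(dos, "ploidy")
  attributes(dos) <- list(dim = dim(dos),
                          dimnames = list(NULL, colnames(gt)))
  ilen <- abs(nchar(fix$REF) - nchar(fix$ALT))
  markers <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    class = ifelse(ilen > 0, "indel", "snp"),
    indel_len = as.integer(ilen),
    stringsAsFactors = FALSE)
  vt <- variant_table(markers, dos, ploidy = ploidy)
  attr(vt, "n_multiallelic_skipped") <- n_skip
  list(variants = vt, groups = gm)
}

# GT strings -> ALT dosage matrix (NA for missing)
.gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  dos_u <- vapply(u, function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al == "1")
  }, integer(1))
  ploidy_u <- vapply(u, function(s) {
    if (is.na(s)) return(NA_integer_)
    length(strsplit(s, "[/|]")[[1]])
  }, integer(1))
  ploidy <- max(c(1L, ploidy_u), na.rm = TRUE)
  out <- matrix(dos_u[match(as.vector(gt), u)], nrow = nrow(gt),
                dimnames = dimnames(gt))
  attr(out, "ploidy") <- ploidy
  out
}

#' Keep only long indels
#'
#' Retains markers of class `indel` with length at least `min_len`
#' (default 5 bp, the long-indel threshold used throughout); order is
#' preserved and the operation is idempotent.
#'
#' @param vt a [variant_table()].
#' @param min_len minimum indel length in bp (integer >= 1).
#' @return A `variant_table` restricted to long indels.
#' @export
filter_long_indels <- function(vt, min_len = 5) {
  stopifnot(inherits(vt, "variant_table"))
  if (!is.numeric(min_len) || min_len < 1 || min_len != round(min_len))
    stop("min_len must be an integer >= 1")
  keep <- vt$markers$class == "indel" & vt$markers$indel_len >= min_len
  vt_subset(vt, keep)
}

#' Per-group allele summaries
#'
#' For every marker and group computes the ALT-allele frequency over
#' called genotypes, the call rate, and a fixedness state:
#' `"fixed-ref"` / `"fixed-alt"` when the call rate reaches
#' `min_call_rate` and every called genotype is homozygous for that
#' allele; `"polymorphic"` otherwise; `"insufficient"` when the call rate
#' is below the threshold (or no genotype is called).  Markers are
#' outgroup-polarized where group A is fixed: the derived-allele frequency
#' is the frequency of the allele A does not carry; markers where A is
#' polymorphic or insufficient are flagged unpolarizable.
#'
#' @param vt a [variant_table()].
#' @param groups a `group_map` (or coercible).
#' @param min_call_rate completeness floor for frequency/fixedness calls.
#' @return A `group_allele_summary` with matrices `freq`, `call_rate`,
#'   `state` and `derived` (markers x groups) plus the marker table.
#' @export
summarize_groups <- function(vt, groups, min_call_rate = 0.7) {
  stopifnot(inherits(vt, "variant_table"))
  gm <- as_group_map(groups)
  m <- n_markers(vt)
  freq <- cr <- matrix(NA_real_, m, 4L, dimnames = list(NULL, GROUPS))
  state <- matrix("insufficient", m, 4L, dimnames = list(NULL, GROUPS))
  for (g in GROUPS) {
    cols <- .group_cols(vt, gm, g)
    if (!length(cols)) next
    sub <- vt$geno[, cols, drop = FALSE]
    ncall <- rowSums(!is.na(sub))
    cr[, g] <- ncall / length(cols)
    tot <- rowSums(sub, na.rm = TRUE)
    freq[, g] <- ifelse(ncall > 0, tot / (vt$ploidy * ncall), NA_real_)
    ok <- cr[, g] >= min_call_rate & ncall > 0
    all_ref <- rowSums(sub != 0L, na.rm = TRUE) == 0L
    all_alt <- rowSums(sub != vt$ploidy, na.rm = TRUE) == 0L
    state[ok & all_ref, g] <- "fixed-ref"
    state[ok & all_alt, g] <- "fixed-alt"
    state[ok & !all_ref & !all_alt, g] <- "polymorphic"
  }
  polarizable <- state[, "A"] %in% c("fixed-ref", "fixed-alt")
  derived <- freq
  flip <- polarizable & state[, "A"] == "fixed-alt"
  derived[flip, ] <- 1 - derived[flip, , drop = FALSE]
  derived[!polarizable, ] <- NA_real_
  structure(list(markers = vt$markers, freq = freq, call_rate = cr,
                 state = state, derived = derived,
                 polarizable = polarizable,
                 min_call_rate = min_call_rate, ploidy = vt$ploidy),
            class = "group_allele_summary")
}

#' @export
print.group_allele_summary <- function(x, ...) {
  cat(sprintf("Group allele summary: %d markers x %d groups (%d polarizable)\n",
              nrow(x$freq), ncol(x$freq), sum(x$polarizable)))
  invisible(x)
}

#' Subset a group allele summary by marker index
#' @param x a `group_allele_summary`.
#' @param i integer or logical marker index.
#' @export
summary_subset <- function(x, i) {
  structure(list(markers = x$markers[i, , drop = FALSE],
                 freq = x$freq[i, , drop = FALSE],
                 call_rate = x$call_rate[i, , drop = FALSE],
                 state = x$state[i, , drop = FALSE],
                 derived = x$derived[i, , drop = FALSE],
                 polarizable = x$polarizable[i],
                 min_call_rate = x$min_call_rate, ploidy = x$ploidy),
            class = "group_allele_summary")
}

#' Read rooted gene trees from a newick file
#'
#' One tree per line; internal node labels, when present, are interpreted
#' as support values by the topology census.
#'
#' @param path newick file.
#' @return A `gene_tree_set`.
#' @export
read_gene_trees <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "phylo")) tr <- list(tr)
  gene_tree_set(unclass(tr))
}

#' @rdname read_gene_trees
#' @param trees a `gene_tree_set` (or list of `phylo`).
#' @export
write_gene_trees <- function(trees, path) {
  cls <- trees
  class(cls) <- "multiPhylo"
  ape::write.tree(cls, file = path)
  invisible(path)
}

#' Read per-gene FASTA alignments from a directory
#'
#' Every `*.fa` / `*.fasta` file becomes one gene, named after the file.
#' Sequences within a gene must be equal length; in codon mode downstream
#' operations additionally require length divisible by 3.
#'
#' @param dir directory of FASTA files.
#' @return A named list of character matrices (haplotypes x positions),
#'   class `alignment_set`.
#' @export
read_alignments <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  out <- lapply(files, function(f) {
    seqs <- seqinr::read.fasta(f, as.string = FALSE, forceDNAtolower = FALSE)
    lens <- lengths(seqs)
    if (length(unique(lens)) > 1L)
      stop("unequal sequence lengths in gene ",
           sub("\\.(fa|fasta)$", "", basename(f)))
    mat <- do.call(rbind, lapply(seqs, as.character))
    rownames(mat) <- names(seqs)
    toupper(mat)
  })
  names(out) <- sub("\\.(fa|fasta)$", "", basename(files))
  structure(out, class = c("alignment_set", "list"))
}

#' @rdname read_alignments
#' @param alignments an `alignment_set` (named list of character matrices).
#' @export
write_alignments <- function(alignments, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (g in names(alignments)) {
    mat <- alignments[[g]]
    seqinr::write.fasta(
      lapply(seq_len(nrow(mat)), function(i) mat[i, ]),
      names = rownames(mat),
      file.out = file.path(dir, paste0(g, ".fasta")))
  }
  invisible(dir)
}
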