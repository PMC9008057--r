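# VariantTable and GroupMap containers shared by all analysis modules.

#' Biallelic variant table
#'
#' Container for biallelic markers (SNPs and indels) with per-individual
#' genotype dosages.  `markers` holds one row per marker with 1-based VCF
#' coordinates, REF/ALT alleles, the marker class (`"snp"` or `"indel"`)
#' and the indel length (`abs(nchar(ref) - nchar(alt))`, 0 for SNPs).
#' `geno` is a markers x individuals integer matrix of ALT-allele dosages
#' (0..ploidy, `NA` for missing calls).
#'
#' @param markers data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `class`, `indel_len` (extra columns are kept).
#' @param geno integer dosage matrix, `nrow(markers)` rows, one column per
#'   individual (column names are the sample ids).
#' @param ploidy 1 or 2.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(markers, geno, ploidy = 2) {
  stopifnot(is.data.frame(markers),
            all(c("chrom", "pos", "ref", "alt", "class", "indel_len")
                %in% names(markers)),
            is.matrix(geno), nrow(geno) == nrow(markers))
  if (is.null(colnames(geno))) stop("geno must have sample column names")
  if (!all(markers$class %in% c("snp", "indel")))
    stop("marker class must be 'snp' or 'indel'")
  bad <- markers$class == "indel" & markers$indel_len < 1
  if (any(bad)) stop("indels must have indel_len >= 1")
  if (nrow(geno) && !all(is.na(geno))) {
    rng <- range(geno, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > ploidy)
      stop("genotype dosages must lie in 0..ploidy")
  }
  rownames(markers) <- NULL
  structure(list(markers = markers, geno = geno,
                 samples = colnames(geno), ploidy = ploidy),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("Variant table: %d markers (%d SNP, %d indel) x %d samples\n",
              nrow(x$markers), sum(x$markers$class == "snp"),
              sum(x$markers$class == "indel"), length(x$samples)))
  invisible(x)
}

#' Number of markers in a variant table
#' @param vt a `variant_table`.
#' @export
n_markers <- function(vt) nrow(vt$markers)

#' Subset a variant table by marker index
#' @param vt a `variant_table`.
#' @param i integer or logical marker index.
#' @export
vt_subset <- function(vt, i) {
  variant_table(vt$markers[i, , drop = FALSE],
                vt$geno[i, , drop = FALSE], ploidy = vt$ploidy)
}

#' Sample-to-lineage group map
#'
#' Maps each individual to one of the four groups C, D, O, A.
#'
#' @param sample character vector of sample ids (unique).
#' @param group character vector of group labels, one of `"C"`, `"D"`,
#'   `"O"`, `"A"`.
#' @return A `group_map` data frame.
#' @export
group_map <- function(sample, group) {
  sample <- as.character(sample)
  group <- as.character(group)
  stopifnot(length(sample) == length(group))
  if (anyDuplicated(sample))
    stop("duplicated sample id(s): ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "))
  if (!all(group %in% GROUPS))
    stop("group labels must be one of C, D, O, A")
  structure(data.frame(sample = sample, group = group,
                       stringsAsFactors = FALSE),
            class = c("group_map", "data.frame"))
}

#' @rdname group_map
#' @param x an object coercible to a group map (a `group_map`, a data
#'   frame with `sample`/`group` columns, or a named character vector of
#'   groups).
#' @export
as_group_map <- function(x) {
  if (inherits(x, "group_map")) return(x)
  if (is.data.frame(x)) return(group_map(x$sample, x$group))
  if (is.character(x) && !is.null(names(x)))
    return(group_map(names(x), unname(x)))
  stop("cannot interpret group map")
}

#' Read / write a two-column sample-to-group TSV
#'
#' The file has a header line `sample<TAB>group`.
#'
#' @param path file path.
#' @return `read_group_map` returns a `group_map`.
#' @export
read_group_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df)))
    stop("group map must have columns 'sample' and 'group'")
  group_map(df$sample, df$group)
}

#' @rdname read_group_map
#' @param gm a `group_map`.
#' @export
write_group_map <- function(gm, path) {
  gm <- as_group_map(gm)
  write.table(gm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# indices of samples belonging to a group
.group_cols <- function(vt, gm, g) {
  gm <- as_group_map(gm)
  idx <- match(vt$samples, gm$sample)
  if (anyNA(idx))
    stop("sample(s) missing from group map: ",
         paste(vt$samples[is.na(idx)], collapse = ", "))
  which(gm$group[idx] == g)
}
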