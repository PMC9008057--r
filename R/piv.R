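# Classification of inter-group fixed long indels into the six
# two-lineage sharing classes, the Yates chi-square signal tests, and the
# genome-wide window map.  Long indels are treated as homoplasy-free, so
# a variant fixed in exactly two ingroups either arose on their shared
# internal branch (a phylogenetically informative variant, PIV, when the
# outgroup carries the other allele) or reflects ancestral variation /
# lineage-specific change (an AV, when the outgroup shares it).

#' Markers fixed within every group but not across groups
#'
#' Restricts a group allele summary (normally computed over long indels)
#' to markers where C, D, O and A are each fixed (per the summary's
#' fixedness states) and the four fixed states are not all identical.
#'
#' @param summary a [summarize_groups()] result.
#' @return The subsetted `group_allele_summary`.
#' @export
fixed_intergroup_indels <- function(summary) {
  stopifnot(inherits(summary, "group_allele_summary"))
  st <- summary$state
  all_fixed <- rowSums(st == "fixed-ref" | st == "fixed-alt") == 4L
  varying <- rowSums(st == "fixed-alt") %in% 1:3
  summary_subset(summary, all_fixed & varying)
}

#' Sharing class of a fixed four-group pattern
#'
#' Given the fixed allele of each group, assigns the marker to one of the
#' six sharing classes.  PIV classes (`CD`, `OD`, `CO`): two ingroups
#' share an allele absent from the outgroup while the third ingroup
#' matches the outgroup.  AV classes (`CDA`, `ODA`, `COA`): the shared
#' allele is also carried by the outgroup, i.e. one ingroup alone carries
#' the other allele.  Patterns fitting neither definition (all four
#' equal, or all three ingroups jointly differing from the outgroup) are
#' `"unclassifiable"`.
#'
#' @param x_c,x_d,x_o,x_a fixed states per group; vectors of `"ref"` /
#'   `"alt"` (the `"fixed-ref"` / `"fixed-alt"` spellings are accepted).
#' @return A character vector of class labels.
#' @export
classify_sharing <- function(x_c, x_d, x_o, x_a) {
  norm <- function(x) {
    x <- sub("^fixed-", "", x)
    if (!all(x %in% c("ref", "alt")))
      stop("states must be fixed ('ref' or 'alt')")
    x
  }
  x_c <- norm(x_c); x_d <- norm(x_d); x_o <- norm(x_o); x_a <- norm(x_a)
  n <- length(x_c)
  stopifnot(length(x_d) == n, length(x_o) == n, length(x_a) == n)
  out <- rep("unclassifiable", n)
  out[x_c == x_d & x_c != x_a & x_o == x_a] <- "CD"
  out[x_o == x_d & x_o != x_a & x_c == x_a] <- "OD"
  out[x_c == x_o & x_c != x_a & x_d == x_a] <- "CO"
  out[x_c == x_d & x_c == x_a & x_o != x_a] <- "CDA"
  out[x_o == x_d & x_o == x_a & x_c != x_a] <- "ODA"
  out[x_c == x_o & x_c == x_a & x_d != x_a] <- "COA"
  out
}

#' Census of PIV/AV sharing classes over long indels
#'
#' The composition of [filter_long_indels()], [summarize_groups()],
#' [fixed_intergroup_indels()] and [classify_sharing()]: counts the six
#' sharing classes among inter-group fixed long indels, keeping each
#' classified marker's genomic anchor for the window map.
#'
#' @param vt a [variant_table()] (the long-indel filter is applied
#'   internally).
#' @param groups a `group_map`.
#' @param min_indel_len long-indel threshold in bp (default 5).
#' @param min_call_rate completeness floor for fixedness calls.
#' @return A `piv_counts` object: the six class counts, the number of
#'   markers entering classification, the unclassifiable count, and a
#'   `classified` data frame (`chrom`, `pos`, `class`).
#' @export
piv_census <- function(vt, groups, min_indel_len = 5, min_call_rate = 0.7) {
  stopifnot(inherits(vt, "variant_table"))
  long <- filter_long_indels(vt, min_indel_len)
  if (n_markers(long) == 0L) return(piv_counts_zero())
  summ <- summarize_groups(long, groups, min_call_rate)
  fixed <- fixed_intergroup_indels(summ)
  n_fixed <- nrow(fixed$markers)
  if (n_fixed == 0L) return(piv_counts_zero())
  cls <- classify_sharing(fixed$state[, "C"], fixed$state[, "D"],
                          fixed$state[, "O"], fixed$state[, "A"])
  counts <- vapply(c("CD", "OD", "CO", "CDA", "ODA", "COA"),
                   function(k) sum(cls == k), integer(1))
  structure(list(CD = counts[["CD"]], OD = counts[["OD"]],
                 CO = counts[["CO"]], CDA = counts[["CDA"]],
                 ODA = counts[["ODA"]], COA = counts[["COA"]],
                 n_fixed = n_fixed,
                 n_unclassifiable = sum(cls == "unclassifiable"),
                 classified = data.frame(chrom = fixed$markers$chrom,
                                         pos = fixed$markers$pos,
                                         class = cls,
                                         stringsAsFactors = FALSE)),
            class = "piv_counts")
}

piv_counts_zero <- function() {
  structure(list(CD = 0L, OD = 0L, CO = 0L, CDA = 0L, ODA = 0L, COA = 0L,
                 n_fixed = 0L, n_unclassifiable = 0L,
                 classified = data.frame(chrom = integer(),
                                         pos = integer(),
                                         class = character())),
            class = "piv_counts")
}

#' @export
print.piv_counts <- function(x, ...) {
  cat(sprintf(
    "PIV/AV census over %d inter-group fixed long indels:\n", x$n_fixed))
  cat(sprintf("  PIV: CD = %d, OD = %d, CO = %d\n", x$CD, x$OD, x$CO))
  cat(sprintf("  AV : CDA = %d, ODA = %d, COA = %d (unclassifiable %d)\n",
              x$CDA, x$ODA, x$COA, x$n_unclassifiable))
  invisible(x)
}

# Yates-corrected chi-square on a 2x2 table c(a, b, c, d) = rows
# (a,b), (c,d); correction floored so the statistic is never negative
.yates_chisq <- function(a, b, c, d) {
  N <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    return(list(statistic = NA_real_, p_value = NA_real_,
                note = "zero margin"))
  corr <- max(0, abs(a * d - b * c) - N / 2)
  stat <- N * corr^2 / prod(margins)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       note = NULL)
}

#' Chi-square tests for PIV signal in the two hybrid-sharing groups
#'
#' Tests whether the hybrid lineage's sharing with each parent carries
#' more phylogenetic signal than the C-O reference: for the CD group the
#' 2x2 table `[CD, CDA; CO, COA]`, for the OD group `[OD, ODA; CO, COA]`.
#' C-O sharing is the natural ILS-plus-homoplasy reference because C and
#' O can never be sisters under any placement of D, so any C-O "signal"
#' is noise.  Each table gets a Pearson chi-square with Yates' continuity
#' correction (1 df); the correction term is floored at zero.
#'
#' @param counts a `piv_counts` (or a list with fields `CD`, `OD`, `CO`,
#'   `CDA`, `ODA`, `COA`).
#' @param alpha significance level for the verdict flags (default 0.05).
#' @return A `piv_signal_result` with per-table statistics, p values and
#'   verdicts.
#' @export
piv_signal_test <- function(counts, alpha = 0.05) {
  need <- c("CD", "OD", "CO", "CDA", "ODA", "COA")
  if (!all(need %in% names(counts))) stop("counts lacks the six classes")
  cd <- .yates_chisq(counts$CD, counts$CDA, counts$CO, counts$COA)
  od <- .yates_chisq(counts$OD, counts$ODA, counts$CO, counts$COA)
  structure(list(
    table_cd = matrix(c(counts$CD, counts$CO, counts$CDA, counts$COA), 2L,
                      dimnames = list(c("CD", "CO"), c("PIV", "AV"))),
    table_od = matrix(c(counts$OD, counts$CO, counts$ODA, counts$COA), 2L,
                      dimnames = list(c("OD", "CO"), c("PIV", "AV"))),
    chisq_cd = cd$statistic, p_cd = cd$p_value,
    chisq_od = od$statistic, p_od = od$p_value,
    signal_cd = !is.na(cd$p_value) && cd$p_value < alpha,
    signal_od = !is.na(od$p_value) && od$p_value < alpha,
    alpha = alpha),
    class = "piv_signal_result")
}

#' @export
print.piv_signal_result <- function(x, ...) {
  cat("PIV signal tests (Yates chi-square, 1 df):\n")
  cat(sprintf("  CD vs CO: chi2 = %.3f, p = %.4g%s\n", x$chisq_cd, x$p_cd,
              if (isTRUE(x$signal_cd)) " *" else ""))
  cat(sprintf("  OD vs CO: chi2 = %.3f, p = %.4g%s\n", x$chisq_od, x$p_od,
              if (isTRUE(x$signal_od)) " *" else ""))
  invisible(x)
}

#' Genome-wide window map of CD and OD sharing
#'
#' Bins classified PIV markers into fixed-width windows and tests the
#' homogeneity of the CD:OD ratio across windows (same machinery as
#' [windowed_distribution()]).
#'
#' @param counts a `piv_counts` from [piv_census()], or a data frame with
#'   `chrom`, `pos`, `class`.
#' @param window_size window width in bp (default 1 Mb).
#' @param classes the two classes to map (default `c("CD", "OD")`).
#' @return As [windowed_distribution()].
#' @export
piv_genome_map <- function(counts, window_size = 1e6,
                           classes = c("CD", "OD")) {
  df <- if (inherits(counts, "piv_counts")) counts$classified else counts
  stopifnot(all(c("chrom", "pos", "class") %in% names(df)))
  windowed_distribution(
    data.frame(chrom = df$chrom, pos = df$pos, label = df$class),
    window_size = window_size, classes = classes)
}
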