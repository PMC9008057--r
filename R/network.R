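#' @useDynLib hybridsig, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rpois rgeom rbinom rmultinom runif pnorm pchisq qnorm
#'   pt qt binom.test chisq.test t.test quantile sd
#' @importFrom utils read.delim write.table
NULL

GROUPS <- c("C", "D", "O", "A")

#' Four-lineage species network with an optional hybrid edge
#'
#' Describes the species history used throughout the package: three ingroup
#' lineages C (sect. Carpinus-like parent), O (Ostrya-like parent) and D
#' (the putative hybrid, sect. Distegocarpus-like), plus the outgroup A.
#' D originates at `t_h` from the two parental ancestors; a fraction
#' `gamma` of its ancestry is drawn from the O-side parent and `1 - gamma`
#' from the C-side parent.  With `gamma = 0` the network collapses to the
#' species tree `(((C,D),O),A)`.  All times are in coalescent units,
#' measured backwards from the present; calendar-time calibration is out of
#' scope, only the ordering `0 < t_h < t_co < t_root` matters.
#'
#' The defaults describe deep, well-differentiated lineages: tip branches
#' several coalescent units long (within-lineage variation fixes well
#' before the splits), an internal branch of `t_co - t_h = 1` coalescent
#' unit (substantial but not overwhelming incomplete lineage sorting), and
#' the published minor-parent contribution `gamma = 0.11`.
#'
#' @param t_h hybrid origin time of D (coalescent units, > 0).
#' @param t_co split time of the C- and O-side ancestors; must exceed `t_h`.
#' @param t_root ingroup/outgroup split; must exceed `t_co`.
#' @param gamma proportion of D's ancestry drawn from the O-side parent,
#'   in `[0, 1]`.
#' @param ne relative population sizes for the six branches
#'   (C, D, O, A tip branches, the C/O ancestor, and the root population);
#'   coalescence within a branch runs at rate `choose(k,2)/ne`.
#' @return An object of class `species_network`.
#' @examples
#' species_network()                      # default: hybrid D, gamma = 0.11
#' species_network(gamma = 0)             # pure tree (((C,D),O),A)
#' @export
species_network <- function(t_h = 4, t_co = 5, t_root = 8, gamma = 0.11,
                            ne = c(C = 1, D = 1, O = 1, A = 1,
                                   CO = 1, root = 1)) {
  stopifnot(is.numeric(t_h), is.numeric(t_co), is.numeric(t_root),
            is.numeric(gamma), length(gamma) == 1L)
  if (!all(is.finite(c(t_h, t_co, t_root))) ||
      t_h <= 0 || t_co <= t_h || t_root <= t_co)
    stop("times must be finite and satisfy 0 < t_h < t_co < t_root")
  if (is.na(gamma) || gamma < 0 || gamma > 1)
    stop("gamma must lie in [0, 1]")
  ne <- rep_len(as.numeric(ne), 6L)
  if (any(!is.finite(ne)) || any(ne <= 0))
    stop("population sizes must be positive and finite")
  names(ne) <- c("C", "D", "O", "A", "CO", "root")
  structure(list(t_h = t_h, t_co = t_co, t_root = t_root,
                 gamma = gamma, ne = ne),
            class = "species_network")
}

#' @export
print.species_network <- function(x, ...) {
  cat("Species network (((C,D),O),A) with hybrid edge into D\n")
  cat(sprintf("  t_h = %g, t_co = %g, t_root = %g (coalescent units)\n",
              x$t_h, x$t_co, x$t_root))
  cat(sprintf("  gamma = %g (ancestry of D from the O-side parent)\n",
              x$gamma))
  cat(sprintf("  internal branch T = t_co - t_h = %g\n", x$t_co - x$t_h))
  invisible(x)
}

#' Sampling design: individuals per lineage
#'
#' How many individuals are sampled from each group and at what ploidy.
#' Haplotypes are simulated individually and paired within an individual on
#' genotype emission (no intra-individual phase error).  The default
#' mirrors a 44-individual resequencing panel (16 C, 12 D, 12 O, 4 A).
#'
#' @param n_c,n_d,n_o,n_a individuals sampled per group (each >= 1).
#' @param ploidy 1 or 2; diploid genotypes pair the two haplotypes of an
#'   individual.
#' @return An object of class `sample_design`.
#' @export
sample_design <- function(n_c = 16, n_d = 12, n_o = 12, n_a = 4, ploidy = 2) {
  n <- c(C = n_c, D = n_d, O = n_o, A = n_a)
  if (any(n < 1) || any(n != round(n)))
    stop("each group needs at least one sampled individual")
  if (!ploidy %in% c(1, 2)) stop("ploidy must be 1 or 2")
  structure(list(n_ind = n, ploidy = ploidy,
                 n_hap = n * ploidy),
            class = "sample_design")
}

#' @export
print.sample_design <- function(x, ...) {
  cat(sprintf("Sampling design: C=%d D=%d O=%d A=%d individuals, ploidy %d\n",
              x$n_ind["C"], x$n_ind["D"], x$n_ind["O"], x$n_ind["A"],
              x$ploidy))
  invisible(x)
}

#' Mutation model for variant simulation
#'
#' Infinite-sites mutations are dropped on gene-tree branches as a Poisson
#' process with rate `theta` per unit branch length.  Each mutation becomes
#' a biallelic marker: an indel with probability `indel_fraction` (length
#' `indel_min_len + Geometric(indel_geom_p)`), otherwise a SNP.  The
#' infinite-sites assumption (no recurrent hits) makes long indels behave
#' as homoplasy-free markers, which is what the downstream sharing
#' classification relies on.
#'
#' @param theta scaled mutation rate per unit branch length (>= 0).
#' @param indel_fraction fraction of mutations emitted as indels, in `[0,1]`.
#' @param indel_min_len minimum indel length in bp (>= 1; default 5, the
#'   long-indel threshold).
#' @param indel_geom_p geometric tail parameter for lengths above the
#'   minimum.
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(theta = 5, indel_fraction = 0.15,
                           indel_min_len = 5, indel_geom_p = 0.5) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta < 0)
    stop("theta must be a single non-negative number")
  if (indel_fraction < 0 || indel_fraction > 1)
    stop("indel_fraction must lie in [0, 1]")
  if (indel_min_len < 1 || indel_min_len != round(indel_min_len))
    stop("indel_min_len must be an integer >= 1")
  if (indel_geom_p <= 0 || indel_geom_p > 1)
    stop("indel_geom_p must lie in (0, 1]")
  structure(list(theta = theta, indel_fraction = indel_fraction,
                 indel_min_len = indel_min_len, indel_geom_p = indel_geom_p,
                 infinite_sites = TRUE),
            class = "mutation_model")
}

# haplotype labels "<group><individual>_<hap>", e.g. "C3_2"
.hap_labels <- function(design) {
  unlist(lapply(GROUPS, function(g) {
    n <- design$n_ind[g]
    as.vector(vapply(seq_len(n), function(i)
      paste0(g, i, "_", seq_len(design$ploidy)),
      character(design$ploidy)))
  }), use.names = FALSE)
}

# individual ids in haplotype order
.ind_labels <- function(design) {
  unlist(lapply(GROUPS, function(g)
    paste0(g, seq_len(design$n_ind[g]))), use.names = FALSE)
}

#' Group map for the simulated design
#'
#' @param design a [sample_design()].
#' @return A `group_map` data frame with columns `sample` and `group`.
#' @export
design_group_map <- function(design) {
  stopifnot(inherits(design, "sample_design"))
  group_map(.ind_labels(design),
            rep(GROUPS, design$n_ind))
}
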