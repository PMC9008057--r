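# Per-gene codon alignments simulated on coalescent gene trees, with
# optionally planted parent-of-origin selection signals: an elevated
# count of fixed non-synonymous differences inherited from one parent,
# and/or an alternating pattern of parent-fixed amino-acid states.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

.codon_env <- new.env(parent = emptyenv())

# 64-codon -> amino acid lookup (standard code, via seqinr)
.codon_aa <- function() {
  if (is.null(.codon_env$tab)) {
    codons <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
    aa <- vapply(codons, function(cd)
      seqinr::translate(strsplit(cd, "")[[1]]), "")
    names(aa) <- codons
    .codon_env$tab <- aa
  }
  .codon_env$tab
}

.sense_codons <- function() {
  tab <- .codon_aa()
  names(tab)[tab != "*"]
}

# single-bp-apart codon pairs encoding different amino acids, no stops
NONSYN_PAIRS <- list(c("AAA", "GAA"), c("GAT", "GCT"), c("CGT", "CAT"),
                     c("ACC", "GCC"), c("ATG", "ATA"), c("TTC", "TCC"),
                     c("GGA", "GCA"), c("CTG", "CCG"))

#' Planted selection-signal specification
#'
#' Describes which simulated genes carry a forced parent-of-origin signal:
#' all hybrid-lineage haplotypes descend from the stated parent at that
#' gene, `n_fix` fixed non-synonymous differences separate the
#' hybrid+parent pair from the other parent, and optionally `k_from_c` /
#' `k_from_o` codon positions carry alternating parent-fixed amino-acid
#' states (the hybrid matching the C-fixed or O-fixed residue
#' respectively).
#'
#' @param gene integer indices of the planted genes (within `1..n_genes`).
#' @param origin `"C"` or `"O"` per planted gene.
#' @param n_fix planted fixed non-synonymous differences (recycled).
#' @param k_from_c,k_from_o alternating-pattern counts (recycled;
#'   default 0).
#' @return A `planted_signals` data frame.
#' @export
planted_signals <- function(gene, origin, n_fix = 10,
                            k_from_c = 0, k_from_o = 0) {
  gene <- as.integer(gene)
  if (anyDuplicated(gene)) stop("planted gene indices must be unique")
  if (!all(origin %in% c("C", "O")))
    stop("planted origin must be 'C' or 'O'")
  df <- data.frame(gene = gene,
                   origin = rep_len(origin, length(gene)),
                   n_fix = rep_len(as.integer(n_fix), length(gene)),
                   k_from_c = rep_len(as.integer(k_from_c), length(gene)),
                   k_from_o = rep_len(as.integer(k_from_o), length(gene)),
                   stringsAsFactors = FALSE)
  structure(df, class = c("planted_signals", "data.frame"))
}

#' Simulate per-gene codon alignments with optional planted signals
#'
#' For each gene a coalescent gene tree is drawn from the network
#' ([simulate_gene_trees()] machinery); a planted gene's hybrid lineages
#' are forced to descend from the stated parent (the hybrid edge is set
#' to that parent for that gene).  Neutral infinite-sites mutations are
#' dropped on the tree at rate `theta` per unit branch length and applied
#' to a random ancestral codon sequence, rejecting changes that create
#' internal stop codons.  A planted gene then emulates a completed
#' selective sweep: one haplotype is fixed across the hybrid+donor side
#' (collapsing its within-side polymorphism, as a sweep does), `n_fix`
#' fixed non-synonymous differences are written between the sides, and
#' any alternating positions are planted on untouched codons.
#'
#' @param network a [species_network()].
#' @param design a [sample_design()].
#' @param n_genes number of genes (>= 1).
#' @param planted optional [planted_signals()].
#' @param seed optional integer seed.
#' @param n_codons codons per gene (default 300).
#' @param theta neutral mutation rate per unit branch length per gene.
#' @return An `alignment_set` (named list of haplotype x position
#'   character matrices) with attributes `planting` (the oracle record),
#'   `groups` and `design`.
#' @export
simulate_gene_alignments <- function(network, design, n_genes,
                                     planted = NULL, seed = NULL,
                                     n_codons = 300, theta = 0.5) {
  stopifnot(inherits(network, "species_network"),
            inherits(design, "sample_design"))
  if (n_genes < 1 || n_genes != round(n_genes))
    stop("n_genes must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  plant <- if (is.null(planted)) {
    planted_signals(integer(), character())
  } else {
    stopifnot(inherits(planted, "planted_signals"))
    if (any(planted$gene < 1 | planted$gene > n_genes))
      stop("planted gene index out of range")
    if (any(planted$n_fix + planted$k_from_c + planted$k_from_o > n_codons))
      stop("planted counts exceed gene length in codons")
    planted
  }
  labels <- .hap_labels(design)
  ntip <- length(labels)
  tipg <- .tip_groups(labels)
  len <- 3L * n_codons
  sense <- .sense_codons()
  out <- vector("list", n_genes)
  names(out) <- sprintf("gene%04d", seq_len(n_genes))
  for (gidx in seq_len(n_genes)) {
    prow <- match(gidx, plant$gene)
    gamma_g <- if (is.na(prow)) network$gamma
               else if (plant$origin[prow] == "C") 0 else 1
    tr <- .sim_msc_loci(1L, as.integer(design$n_hap),
                        network$t_h, network$t_co, network$t_root,
                        gamma_g, as.numeric(network$ne))[[1L]]
    anc <- unlist(strsplit(sample(sense, n_codons, replace = TRUE), ""),
                  use.names = FALSE)
    aln <- matrix(rep(anc, each = ntip), nrow = ntip,
                  dimnames = list(labels, NULL))
    touched_codon <- logical(n_codons)
    m <- rpois(1L, theta * sum(tr$`edge.length`))
    m <- min(m, len)
    if (m > 0L) {
      der <- .drop_mutations(tr$edge, as.numeric(tr$`edge.length`),
                             ntip, m)
      sites <- sample.int(len, m)
      for (j in seq_len(m)) {
        rows <- der[, j]
        if (!any(rows) || all(rows)) next
        s <- sites[j]
        ci <- (s - 1L) %/% 3L + 1L
        old <- aln[1L, s]  # site untouched, column is monomorphic
        for (new in sample(setdiff(BASES, old))) {
          aln[rows, s] <- new
          cod <- paste0(aln[rows, 3L * ci - 2L], aln[rows, 3L * ci - 1L],
                        aln[rows, 3L * ci])
          if (!any(cod %in% STOP_CODONS)) break
          aln[rows, s] <- old
        }
        if (any(aln[, s] != old)) touched_codon[ci] <- TRUE
      }
    }
    if (!is.na(prow)) {
      need <- plant$n_fix[prow] + plant$k_from_c[prow] +
        plant$k_from_o[prow]
      free <- which(!touched_codon)
      if (length(free) < need)
        stop("gene ", gidx, ": not enough untouched codons for planting")
      picks <- sample(free, need)
      orient <- function() {
        pr <- NONSYN_PAIRS[[sample.int(length(NONSYN_PAIRS), 1L)]]
        if (runif(1) < 0.5) pr else rev(pr)
      }
      set_codon <- function(ci, rows, codon) {
        cols <- (3L * ci - 2L):(3L * ci)
        aln[rows, cols] <<- matrix(rep(strsplit(codon, "")[[1]],
                                       each = length(rows)),
                                   nrow = length(rows))
      }
      k <- 0L
      par_rows <- which(tipg == plant$origin[prow] | tipg == "D")
      oth_rows <- which(!(tipg %in% c(plant$origin[prow], "D")))
      # a completed selective sweep in the hybrid+donor group: one
      # haplotype is fixed, collapsing within-side polymorphism
      aln[par_rows, ] <- matrix(rep(aln[par_rows[1L], ],
                                    each = length(par_rows)),
                                nrow = length(par_rows))
      for (i in seq_len(plant$n_fix[prow])) {
        k <- k + 1L; pr <- orient()
        set_codon(picks[k], par_rows, pr[1])
        set_codon(picks[k], oth_rows, pr[2])
      }
      c_rows <- which(tipg == "C"); o_rows <- which(tipg == "O")
      d_rows <- which(tipg == "D"); a_rows <- which(tipg == "A")
      for (i in seq_len(plant$k_from_c[prow])) {
        k <- k + 1L; pr <- orient()
        set_codon(picks[k], c(c_rows, d_rows), pr[1])
        set_codon(picks[k], c(o_rows, a_rows), pr[2])
      }
      for (i in seq_len(plant$k_from_o[prow])) {
        k <- k + 1L; pr <- orient()
        set_codon(picks[k], c_rows, pr[1])
        set_codon(picks[k], c(o_rows, d_rows, a_rows), pr[2])
      }
    }
    out[[gidx]] <- aln
  }
  planting <- plant
  planting$gene_id <- names(out)[plant$gene]
  structure(out, class = c("alignment_set", "list"),
            planting = planting, groups = design_group_map(design),
            design = design)
}

#' @export
print.alignment_set <- function(x, ...) {
  np <- if (!is.null(attr(x, "planting"))) nrow(attr(x, "planting")) else 0L
  cat(sprintf("Alignment set: %d genes%s\n", length(x),
              if (np) sprintf(" (%d planted)", np) else ""))
  invisible(x)
}
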