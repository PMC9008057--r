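# Synthetic-data generation: gene trees under the multispecies coalescent
# with a hybrid edge, infinite-sites variant tables, and codon alignments
# with optionally planted selection signals.

N_CHROM <- 8L          # synthetic karyotype
CHROM_LEN <- 10e6      # bp per synthetic chromosome
LOCUS_SPAN <- 10e3     # bp window a locus' markers occupy around its anchor

#' Simulate gene trees under the coalescent with a hybrid edge
#'
#' Draws `n_loci` independent gene trees from the multispecies coalescent
#' on a [species_network()].  At the hybrid node each D lineage is routed,
#' independently per locus, to the O-side ancestor with probability
#' `gamma`, otherwise to the C-side ancestor (admixture semantics; with a
#' single D lineage per locus this coincides with routing the whole
#' lineage).  Branch lengths are in coalescent units.  Each tree is given
#' a uniform genomic anchor on one of eight synthetic chromosomes.
#'
#' @param network a [species_network()].
#' @param design a [sample_design()].
#' @param n_loci number of independent loci (>= 1).
#' @param seed optional integer seed; the same seed reproduces the output
#'   bit for bit.
#' @return A `gene_tree_set`: a list of `phylo` trees with attributes
#'   `design`, `network` and `anchors` (chromosome/start per tree).
#' @examples
#' trees <- simulate_gene_trees(species_network(gamma = 0), sample_design(1, 1, 1, 1, ploidy = 1), 5, seed = 1)
#' length(trees)
#' @export
simulate_gene_trees <- function(network, design, n_loci, seed = NULL) {
  stopifnot(inherits(network, "species_network"),
            inherits(design, "sample_design"))
  if (!is.numeric(n_loci) || length(n_loci) != 1L || n_loci < 1 ||
      n_loci != round(n_loci))
    stop("n_loci must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  n_loci <- as.integer(n_loci)
  raw <- .sim_msc_loci(n_loci, as.integer(design$n_hap),
                       network$t_h, network$t_co, network$t_root,
                       network$gamma, as.numeric(network$ne))
  labels <- .hap_labels(design)
  ntip <- length(labels)
  trees <- lapply(raw, function(l) {
    structure(list(edge = l$edge,
                   edge.length = as.numeric(l$`edge.length`),
                   tip.label = labels,
                   Nnode = ntip - 1L),
              class = "phylo", order = "postorder")
  })
  anchors <- data.frame(
    chrom = sample.int(N_CHROM, n_loci, replace = TRUE),
    start = floor(runif(n_loci, 0, CHROM_LEN - LOCUS_SPAN))
  )
  structure(trees, class = c("gene_tree_set", "list"),
            design = design, network = network, anchors = anchors)
}

#' @export
print.gene_tree_set <- function(x, ...) {
  cat(sprintf("Gene tree set: %d trees, %d tips each\n",
              length(x), if (length(x)) length(x[[1]]$tip.label) else 0L))
  invisible(x)
}

#' Construct a gene tree set from existing trees
#'
#' Wraps a list of `phylo` trees (for example, trees read from newick) so
#' the census and simulation machinery can consume them.  Tip labels must
#' either follow the simulator's `"<group><i>_<h>"` convention or be
#' resolvable through `groups`.
#'
#' @param trees a `phylo` or list of `phylo` objects.
#' @param anchors optional data frame with columns `chrom` and `start`,
#'   one row per tree.
#' @return A `gene_tree_set`.
#' @export
gene_tree_set <- function(trees, anchors = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees) || !all(vapply(trees, inherits, TRUE, "phylo")))
    stop("trees must be phylo objects")
  if (!is.null(anchors)) {
    stopifnot(is.data.frame(anchors),
              all(c("chrom", "start") %in% names(anchors)),
              nrow(anchors) == length(trees))
  }
  structure(trees, class = c("gene_tree_set", "list"), anchors = anchors)
}

# derive the group of each tip from its label, optionally via a group map
.tip_groups <- function(tip_labels, groups = NULL) {
  if (!is.null(groups)) {
    gm <- as_group_map(groups)
    idx <- match(tip_labels, gm$sample)
    miss <- is.na(idx)
    if (any(miss)) {
      stripped <- sub("_[0-9]+$", "", tip_labels[miss])
      idx[miss] <- match(stripped, gm$sample)
    }
    out <- gm$group[idx]
    if (anyNA(out))
      stop("tip label(s) not found in group map: ",
           paste(utils::head(tip_labels[is.na(out)], 3), collapse = ", "))
    return(out)
  }
  g <- sub("^([CDOA])[0-9].*$", "\\1", tip_labels)
  if (!all(g %in% GROUPS))
    stop("cannot derive groups from tip labels; supply a group map")
  g
}

#' Simulate biallelic variants on gene trees
#'
#' Places infinite-sites mutations on each tree as a Poisson process with
#' rate `theta` per unit branch length.  Each mutation becomes a biallelic
#' marker (SNP or indel according to the [mutation_model()]); the tips
#' below the mutated edge carry the derived allele.  The ancestral (REF)
#' state is defined by the outgroup side: if all A haplotypes carry the
#' mutation, the orientation is flipped so that REF is the allele seen in
#' the outgroup.  Diploid genotypes pair the two haplotypes of each
#' individual; markers inherit their tree's genomic anchor, with unique
#' positions inside the locus span.
#'
#' @param trees a `gene_tree_set` (with branch lengths).
#' @param model a [mutation_model()].
#' @param seed optional integer seed.
#' @return A `variant_table`; see [variant_table()].
#' @export
simulate_variants <- function(trees, model, seed = NULL) {
  stopifnot(inherits(trees, "gene_tree_set"),
            inherits(model, "mutation_model"))
  if (!is.null(seed)) set.seed(seed)
  if (!length(trees)) stop("empty tree set")
  if (is.null(trees[[1]]$edge.length))
    stop("trees must carry branch lengths")
  labels <- trees[[1]]$tip.label
  tipg <- .tip_groups(labels)
  a_rows <- which(tipg == "A")
  ploidy <- if (!is.null(attr(trees, "design")))
    attr(trees, "design")$ploidy else .infer_ploidy(labels)
  inds <- unique(sub("_[0-9]+$", "", labels))
  ind_of_hap <- match(sub("_[0-9]+$", "", labels), inds)
  anchors <- attr(trees, "anchors")
  if (is.null(anchors))
    anchors <- data.frame(chrom = sample.int(N_CHROM, length(trees), TRUE),
                          start = floor(runif(length(trees), 0,
                                              CHROM_LEN - LOCUS_SPAN)))

  n_tree <- length(trees)
  lens <- vapply(trees, function(t) sum(t$edge.length), 0)
  m_per <- rpois(n_tree, model$theta * lens)
  geno_l <- vector("list", n_tree)
  pos_l <- vector("list", n_tree)
  for (k in seq_len(n_tree)) {
    m <- m_per[k]
    if (m == 0L) next
    tr <- trees[[k]]
    der <- .drop_mutations(tr$edge, tr$edge.length, length(labels), m)
    # outgroup polarization: flip markers where every A haplotype is derived
    if (length(a_rows)) {
      flip <- colSums(der[a_rows, , drop = FALSE]) == length(a_rows)
      if (any(flip)) der[, flip] <- !der[, flip]
    }
    # diploid (or haploid) ALT dosage per individual
    geno_l[[k]] <- t(rowsum(1L * der, ind_of_hap))  # markers x individuals
    pos_l[[k]] <- anchors$start[k] + sample.int(LOCUS_SPAN, m)
  }
  keep <- m_per > 0L
  if (!any(keep)) {
    return(variant_table(
      markers = data.frame(chrom = integer(), pos = integer(),
                           ref = character(), alt = character(),
                           class = character(), indel_len = integer(),
                           locus = integer()),
      geno = matrix(integer(), 0, length(inds),
                    dimnames = list(NULL, inds)),
      ploidy = ploidy))
  }
  geno <- do.call(rbind, geno_l[keep])
  colnames(geno) <- inds
  n <- nrow(geno)
  chrom <- rep(anchors$chrom[keep], m_per[keep])
  locus <- rep(which(keep), m_per[keep])
  pos <- unlist(pos_l[keep], use.names = FALSE)
  # marker classes and alleles
  is_indel <- runif(n) < model$indel_fraction
  ilen <- integer(n)
  ilen[is_indel] <- model$indel_min_len +
    rgeom(sum(is_indel), model$indel_geom_p)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  # derived allele: shift within the base alphabet, uniformly non-equal
  alt <- bases[(match(ref, bases) + sample.int(3L, n, replace = TRUE) - 1L)
               %% 4L + 1L]
  if (any(is_indel)) {
    w <- which(is_indel)
    ins <- runif(length(w)) < 0.5
    anchor <- ref[w]
    draws <- sample(bases, sum(ilen[w]), replace = TRUE)
    seqs <- vapply(split(draws, factor(rep.int(seq_along(w), ilen[w]),
                                       levels = seq_along(w))),
                   paste, "", collapse = "")
    long <- paste0(anchor, seqs)
    ref[w] <- ifelse(ins, anchor, long)
    alt[w] <- ifelse(ins, long, anchor)
  }
  markers <- data.frame(chrom = chrom, pos = pos, ref = ref,
                        alt = alt,
                        class = ifelse(is_indel, "indel", "snp"),
                        indel_len = ilen, locus = locus,
                        stringsAsFactors = FALSE)
  ord <- order(markers$chrom, markers$pos)
  variant_table(markers[ord, , drop = FALSE],
                geno[ord, , drop = FALSE], ploidy = ploidy)
}

.infer_ploidy <- function(labels) {
  h <- as.integer(sub("^.*_([0-9]+)$", "\\1", labels))
  if (anyNA(h)) 1L else max(h)
}
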