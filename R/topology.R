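# Rooted topology census of gene trees over the three ingroups, the
# binomial asymmetry test on the two minor topologies, the ILS-only
# simulation null for the minor-topology ratio, and the genome-wide
# window distribution.

#' Classify the rooted topology of one gene tree
#'
#' Roots the tree on the outgroup (A) edge, prunes A, and reports which
#' ingroup pair is sister: `"I"` (C+D), `"II"` (D+O) or `"III"` (C+O).
#' A tree is `"discarded"` when A or any ingroup is non-monophyletic, when
#' the ingroup node is unresolved, or when a support value is present at
#' the sister-pair node and falls below `support_min`.
#'
#' @param tree a rooted (or A-rootable) `phylo` with at least one tip from
#'   each of C, D, O and A.
#' @param groups optional group map resolving tip labels; by default
#'   groups are parsed from labels of the form `"<group><i>_<h>"`.
#' @param support_min minimum support (same scale as the node labels,
#'   typically 0-100) for the sister-pair node; default 50.
#' @return One of `"I"`, `"II"`, `"III"`, `"discarded"`.
#' @examples
#' tr <- ape::read.tree(text = "(((C1_1,D1_1),O1_1),A1_1);")
#' classify_topology(tr)
#' @export
classify_topology <- function(tree, groups = NULL, support_min = 50) {
  stopifnot(inherits(tree, "phylo"))
  tipg <- .tip_groups(tree$tip.label, groups)
  for (g in c("C", "D", "O", "A"))
    if (!any(tipg == g)) stop("no tips from group ", g)
  a_tips <- tree$tip.label[tipg == "A"]
  rooted <- tryCatch(
    ape::root(tree, outgroup = a_tips, resolve.root = TRUE),
    error = function(e) NULL)
  if (is.null(rooted)) return("discarded")
  ing <- ape::drop.tip(rooted, a_tips)
  if (is.null(ing) || is.null(ing$tip.label)) return("discarded")
  ing_g <- .tip_groups(ing$tip.label, groups)
  for (g in c("C", "D", "O"))
    if (!.is_clade(ing, ing$tip.label[ing_g == g])) return("discarded")
  pairs <- list(I = c("C", "D"), II = c("D", "O"), III = c("C", "O"))
  label <- NA_character_
  pair_tips <- NULL
  for (nm in names(pairs)) {
    tt <- ing$tip.label[ing_g %in% pairs[[nm]]]
    if (.is_clade(ing, tt)) {
      if (!is.na(label)) return("discarded")  # unresolved/polytomy
      label <- nm
      pair_tips <- tt
    }
  }
  if (is.na(label)) return("discarded")
  if (!is.null(tree$node.label) && any(nzchar(tree$node.label))) {
    # support is read off the ORIGINAL tree (ape's root/drop.tip shuffle
    # node labels): the sister-pair split is located as the clade holding
    # exactly the pair tips, or its complement
    pair_orig <- tree$tip.label[tipg %in% pairs[[label]]]
    comp_orig <- setdiff(tree$tip.label, pair_orig)
    sup <- .split_support(tree, pair_orig, comp_orig)
    if (!is.na(sup) && sup < support_min) return("discarded")
  }
  label
}

# tips descending from a node
.clade_tips <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[1]
    stack <- stack[-1]
    ch <- kids[[as.character(v)]]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  phy$tip.label[out]
}

# support value on the edge splitting side_a from side_b, NA if absent
.split_support <- function(phy, side_a, side_b) {
  ntip <- length(phy$tip.label)
  for (side in list(side_a, side_b)) {
    if (length(side) < 2L) next
    node <- ape::getMRCA(phy, side)
    if (is.null(node) || node - ntip > length(phy$node.label)) next
    if (setequal(.clade_tips(phy, node), side)) {
      sup <- suppressWarnings(as.numeric(phy$node.label[node - ntip]))
      return(sup)
    }
  }
  NA_real_
}

# monophyly that treats a single tip as a (trivial) clade
.is_clade <- function(phy, tips) {
  if (length(tips) <= 1L) return(TRUE)
  ape::is.monophyletic(phy, tips)
}

#' Census of rooted topologies across a gene tree set
#'
#' Applies [classify_topology()] to every tree and tallies the three
#' topologies; discarded trees are excluded from all denominators.
#'
#' @param trees a `gene_tree_set` (or list of `phylo`).
#' @param groups optional group map (see [classify_topology()]).
#' @param support_min support threshold passed through.
#' @return A `topology_counts` object with fields `n_I`, `n_II`, `n_III`,
#'   `n_discarded`, a per-tree `labels` vector, and the trees' genomic
#'   anchors when available.
#' @export
topology_census <- function(trees, groups = NULL, support_min = 50) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("empty tree set")
  labels <- vapply(trees, classify_topology, "", groups = groups,
                   support_min = support_min)
  topology_counts(sum(labels == "I"), sum(labels == "II"),
                  sum(labels == "III"), sum(labels == "discarded"),
                  labels = labels, anchors = attr(trees, "anchors"))
}

#' @rdname topology_census
#' @param n_I,n_II,n_III,n_discarded topology counts (non-negative
#'   integers).
#' @param labels optional per-tree label vector.
#' @param anchors optional per-tree anchor data frame (`chrom`, `start`).
#' @export
topology_counts <- function(n_I, n_II, n_III, n_discarded = 0,
                            labels = NULL, anchors = NULL) {
  counts <- c(n_I, n_II, n_III, n_discarded)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  structure(list(n_I = as.integer(n_I), n_II = as.integer(n_II),
                 n_III = as.integer(n_III),
                 n_discarded = as.integer(n_discarded),
                 total = as.integer(n_I + n_II + n_III),
                 labels = labels, anchors = anchors),
            class = "topology_counts")
}

#' @export
print.topology_counts <- function(x, ...) {
  cat(sprintf(
    "Topology census: I (C+D) = %d, II (D+O) = %d, III (C+O) = %d; discarded = %d\n",
    x$n_I, x$n_II, x$n_III, x$n_discarded))
  invisible(x)
}

#' Exact binomial test on the two minor topologies
#'
#' Under incomplete lineage sorting alone the two minor topologies (II and
#' III) are equally likely, so their counts are Binomial(n, 1/2).  The
#' exact two-tailed p sums the probabilities of all outcomes no more
#' likely than the observed count.
#'
#' @param counts a `topology_counts`, or the count of topology-II trees.
#' @param n_III count of topology-III trees (when `counts` is a number).
#' @return The two-tailed p value, with the counts attached as attributes.
#' @export
minor_topology_binomial_test <- function(counts, n_III = NULL) {
  if (inherits(counts, "topology_counts")) {
    n2 <- counts$n_II; n3 <- counts$n_III
  } else {
    n2 <- counts; n3 <- n_III
  }
  if (is.null(n3)) stop("supply both minor-topology counts")
  if (n2 + n3 == 0)
    stop("binomial test undefined: no minor-topology trees")
  p <- binom.test(n2, n2 + n3, p = 0.5)$p.value
  structure(p, n_II = n2, n_III = n3)
}

#' Internal branch length matching an observed concordant fraction
#'
#' Under the multispecies coalescent with one lineage per group the
#' concordant topology has probability `1 - (2/3) exp(-T)`; this inverts
#' that relation so an ILS-only null can be calibrated to an observed
#' topology-I fraction.
#'
#' @param p_I observed fraction of topology-I trees, in `(1/3, 1)`.
#' @return The internal branch length T in coalescent units.
#' @export
calibrate_internal_branch <- function(p_I) {
  if (!is.numeric(p_I) || p_I <= 1 / 3 || p_I >= 1)
    stop("p_I must lie in (1/3, 1)")
  -log(1.5 * (1 - p_I))
}

#' ILS-only simulation null for the minor-topology ratio
#'
#' Simulates the distribution of the ratio N_III / N_II expected under
#' incomplete lineage sorting alone (`gamma = 0`), and locates the
#' observed ratio in it.  Two replicate engines are available:
#' `"trees"` simulates and classifies `loci_per_rep` gene trees per
#' replicate; `"multinomial"` draws the topology counts directly from the
#' closed-form MSC probabilities (`P(I) = 1 - (2/3)e^-T`,
#' `P(II) = P(III) = e^-T / 3`), which is the identical null distribution
#' when one lineage is sampled per group, at a fraction of the cost.
#' `"auto"` (default) picks multinomial exactly in that case.
#' Replicates with `N_II = 0` are redrawn (bounded retries) and counted.
#'
#' Both the empirical two-sided p (the headline figure) and a one-sample
#' two-tailed t test of the replicate ratios against the observed ratio
#' are reported; the t test on a ratio distribution is distributionally
#' fragile and included for comparability only.
#'
#' @param counts observed `topology_counts`.
#' @param network a [species_network()] with `gamma = 0`; defaults to the
#'   null calibrated via [calibrate_internal_branch()] to the observed
#'   topology-I fraction.
#' @param loci_per_rep gene trees per replicate; defaults to the observed
#'   census size.
#' @param n_reps number of simulated replicates.
#' @param seed optional integer seed.
#' @param method `"auto"`, `"multinomial"` or `"trees"`.
#' @param design sampling design for `method = "trees"`; defaults to one
#'   haploid lineage per group.
#' @param max_retries bound on redraws of degenerate replicates.
#' @return A `ratio_test_result`.
#' @export
ils_null_ratio_test <- function(counts, network = NULL, loci_per_rep = NULL,
                                n_reps = 10000, seed = NULL,
                                method = c("auto", "multinomial", "trees"),
                                design = NULL, max_retries = 100) {
  stopifnot(inherits(counts, "topology_counts"))
  method <- match.arg(method)
  if (counts$n_II == 0) stop("observed ratio undefined (N_II = 0)")
  if (is.null(loci_per_rep)) loci_per_rep <- counts$total
  if (loci_per_rep < 1) stop("loci_per_rep must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(network)) {
    T_cal <- calibrate_internal_branch(counts$n_I / counts$total)
    network <- species_network(t_h = 1, t_co = 1 + T_cal,
                               t_root = 2 + T_cal, gamma = 0)
  }
  if (network$gamma != 0)
    stop("the ILS null requires a network with gamma = 0")
  if (is.null(design)) design <- sample_design(1, 1, 1, 1, ploidy = 1)
  one_per_group <- all(design$n_hap == 1)
  if (method == "auto")
    method <- if (one_per_group) "multinomial" else "trees"
  if (method == "multinomial" && !one_per_group)
    stop("multinomial nulls require one sampled lineage per group")
  Tb <- network$t_co - network$t_h
  probs <- c(1 - 2 / 3 * exp(-Tb), exp(-Tb) / 3, exp(-Tb) / 3)
  ratios <- numeric(n_reps)
  n_redrawn <- 0L
  for (r in seq_len(n_reps)) {
    for (try in seq_len(max_retries)) {
      if (method == "multinomial") {
        cnt <- as.vector(rmultinom(1L, loci_per_rep, probs))
        n2 <- cnt[2L]; n3 <- cnt[3L]
      } else {
        tr <- simulate_gene_trees(network, design, loci_per_rep)
        cen <- topology_census(tr)
        n2 <- cen$n_II; n3 <- cen$n_III
      }
      if (n2 > 0) break
      n_redrawn <- n_redrawn + 1L
      if (try == max_retries)
        stop("could not obtain a replicate with N_II > 0")
    }
    ratios[r] <- n3 / n2
  }
  r_obs <- counts$n_III / counts$n_II
  p_emp <- 2 * min(mean(ratios <= r_obs), mean(ratios >= r_obs))
  p_emp <- min(1, max(p_emp, 1 / n_reps))
  tt <- t.test(ratios, mu = r_obs)
  structure(list(r_obs = r_obs, ratios = ratios,
                 p_empirical = p_emp,
                 t_statistic = unname(tt$statistic),
                 p_t = tt$p.value,
                 n_reps = n_reps, loci_per_rep = loci_per_rep,
                 n_redrawn = n_redrawn, method = method,
                 null_T = Tb),
            class = "ratio_test_result")
}

#' @export
print.ratio_test_result <- function(x, ...) {
  cat(sprintf(
    "ILS-only null (T = %.3f, %d reps x %d loci, %s):\n",
    x$null_T, x$n_reps, x$loci_per_rep, x$method))
  cat(sprintf("  observed N_III/N_II = %.4f; empirical two-sided p %s\n",
              x$r_obs,
              if (x$p_empirical <= 1 / x$n_reps)
                sprintf("< %.2g", 1 / x$n_reps)
              else sprintf("= %.4g", x$p_empirical)))
  cat(sprintf("  one-sample t = %.2f, two-tailed p = %.3g\n",
              x$t_statistic, x$p_t))
  invisible(x)
}

#' Genome-wide window distribution of two topology classes
#'
#' Bins classified loci into fixed-width windows (BED-style 0-based
#' half-open intervals) and tests homogeneity of the class proportion
#' across windows with a chi-square test; windows are pooled with an
#' adjacent neighbour until every expected cell count reaches 5.
#'
#' @param loci data frame with columns `chrom`, `pos` and `label`, or a
#'   `topology_counts` carrying labels and anchors.
#' @param window_size window width in bp (default 1 Mb).
#' @param classes the two labels to tabulate (default topologies I and II).
#' @return A list with `windows` (per-window counts, BED coordinates),
#'   `pooled` (the table actually tested), and `p_homogeneity` (`NA` when
#'   fewer than two pooled windows remain).
#' @export
windowed_distribution <- function(loci, window_size = 1e6,
                                  classes = c("I", "II")) {
  if (inherits(loci, "topology_counts")) {
    if (is.null(loci$anchors))
      stop("census carries no genomic anchors")
    loci <- data.frame(chrom = loci$anchors$chrom,
                       pos = loci$anchors$start,
                       label = loci$labels)
  }
  stopifnot(all(c("chrom", "pos", "label") %in% names(loci)))
  if (window_size < 1) stop("window_size must be positive")
  loci <- loci[loci$label %in% classes, , drop = FALSE]
  if (!nrow(loci)) stop("no loci in the requested classes")
  win <- floor(loci$pos / window_size)
  key <- paste(loci$chrom, win, sep = ":")
  keys <- sort(unique(key))
  tab <- matrix(0L, length(keys), 2L,
                dimnames = list(keys, classes))
  for (j in 1:2)
    tab[, j] <- as.integer(table(factor(key[loci$label == classes[j]],
                                        levels = keys)))
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  windows <- data.frame(chrom = parts[, 1L],
                        start = as.numeric(parts[, 2L]) * window_size,
                        end = (as.numeric(parts[, 2L]) + 1) * window_size,
                        tab, check.names = FALSE,
                        stringsAsFactors = FALSE)
  pooled <- .pool_small_windows(tab)
  p <- if (nrow(pooled) < 2L || any(colSums(pooled) == 0)) NA_real_
       else suppressWarnings(chisq.test(pooled, correct = FALSE)$p.value)
  list(windows = windows, pooled = pooled, p_homogeneity = p)
}

# merge adjacent windows until all expected counts are >= 5
.pool_small_windows <- function(tab, min_expected = 5) {
  while (nrow(tab) > 1L) {
    N <- sum(tab)
    expd <- outer(rowSums(tab), colSums(tab)) / N
    if (min(expd) >= min_expected) break
    i <- which.min(rowSums(tab))
    j <- if (i == 1L) 2L else i - 1L
    tab[j, ] <- tab[j, ] + tab[i, ]
    tab <- tab[-i, , drop = FALSE]
  }
  tab
}
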