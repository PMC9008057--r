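# Shared fixtures: small designs and datasets built in code.

tiny_design <- function() sample_design(2, 2, 2, 1)

null_network <- function() species_network(gamma = 0)

# a variant table built directly from a dosage matrix (one diploid
# individual per group unless geno says otherwise)
vt_from_geno <- function(geno, class = "snp", indel_len = 0,
                         chrom = 1L, ploidy = 2) {
  n <- nrow(geno)
  markers <- data.frame(chrom = rep_len(chrom, n), pos = seq_len(n) * 100L,
                        ref = rep("A", n), alt = rep("T", n),
                        class = rep_len(class, n),
                        indel_len = rep_len(indel_len, n),
                        stringsAsFactors = FALSE)
  variant_table(markers, geno, ploidy = ploidy)
}

one_per_group_map <- function() {
  group_map(c("C1", "D1", "O1", "A1"), c("C", "D", "O", "A"))
}

# simulated dataset summarized by group, for the frequency-based tests
sim_summary <- function(gamma, n_loci, theta = 1, indel_fraction = 0.15,
                        design = tiny_design(), seed = NULL) {
  net <- species_network(gamma = gamma)
  trees <- simulate_gene_trees(net, design, n_loci, seed = seed)
  vt <- simulate_variants(trees, mutation_model(theta = theta,
                                                indel_fraction = indel_fraction))
  summarize_groups(vt, design_group_map(design))
}

# codon alignment built from codon strings per group:
# cod is a list with elements C, D, O, A, each a character vector of
# codons (same length); n_hap haplotypes per group
aln_from_codons <- function(cod, n_hap = 2) {
  groups <- names(cod)
  rows <- list()
  for (g in groups) {
    seqv <- unlist(strsplit(paste(cod[[g]], collapse = ""), ""))
    for (h in seq_len(n_hap))
      rows[[paste0(g, "1_", h)]] <- seqv
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(rows)
  mat
}
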