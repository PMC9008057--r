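# The coalescent-with-hybridization generator: parameter validation,
# closed-form topology frequencies, determinism, and the mutation model.

test_that("species_network validates its invariants", {
  expect_error(species_network(t_h = 2, t_co = 1), "t_h < t_co")
  expect_error(species_network(t_h = -1), "t_h < t_co")
  expect_error(species_network(gamma = 1.2), "gamma")
  expect_error(species_network(ne = c(1, 1, 0, 1, 1, 1)), "positive")
  net <- species_network(gamma = 0)
  expect_s3_class(net, "species_network")
  expect_identical(net$gamma, 0)
  expect_error(sample_design(0, 1, 1, 1), "at least one")
  expect_error(mutation_model(theta = -1), "non-negative")
  expect_error(mutation_model(indel_min_len = 0), "indel_min_len")
})

test_that("gamma = 0 topology frequencies match the MSC closed form", {
  # P(I) = 1 - (2/3) e^-T, P(II) = P(III) = e^-T / 3
  net <- species_network(t_h = 1, t_co = 2, t_root = 3, gamma = 0)
  d1 <- sample_design(1, 1, 1, 1, ploidy = 1)
  n <- 3000
  trees <- simulate_gene_trees(net, d1, n, seed = 101)
  cen <- topology_census(trees)
  p1 <- 1 - 2 / 3 * exp(-1)
  se <- sqrt(p1 * (1 - p1) / n)
  expect_equal(cen$total, n)
  expect_lt(abs(cen$n_I / n - p1), 3 * se)
  # minor topologies symmetric
  se2 <- sqrt(2 * exp(-1) / 3 / n)
  expect_lt(abs((cen$n_II - cen$n_III) / n), 3 * se2)
})

test_that("extreme gammas behave as the network symmetry dictates", {
  d1 <- sample_design(1, 1, 1, 1, ploidy = 1)
  # T large: coalescence forced on the internal branch, all topology I
  deep <- species_network(t_h = 1, t_co = 51, t_root = 52, gamma = 0)
  cen <- topology_census(simulate_gene_trees(deep, d1, 200, seed = 7))
  expect_equal(cen$n_I, 200L)
  # gamma = 1 makes D sister to O as often as gamma = 0 makes it sister to C
  net0 <- species_network(t_h = 1, t_co = 2, t_root = 3, gamma = 0)
  net1 <- species_network(t_h = 1, t_co = 2, t_root = 3, gamma = 1)
  n <- 2500
  c0 <- topology_census(simulate_gene_trees(net0, d1, n, seed = 11))
  c1 <- topology_census(simulate_gene_trees(net1, d1, n, seed = 12))
  se <- 3 * sqrt(0.755 * 0.245 / n) * n
  expect_lt(abs(c1$n_II - c0$n_I), 2 * se)  # swapped roles, same frequency
})

test_that("minor-topology excess is positive and monotone in gamma", {
  d1 <- sample_design(1, 1, 1, 1, ploidy = 1)
  gammas <- c(0, 0.1, 0.3, 0.5)
  n <- 3000
  excess <- vapply(seq_along(gammas), function(i) {
    net <- species_network(t_h = 1, t_co = 2, t_root = 3,
                           gamma = gammas[i])
    cen <- topology_census(simulate_gene_trees(net, d1, n,
                                               seed = 300 + i))
    (cen$n_II - cen$n_III) / cen$total
  }, 0)
  expect_true(all(diff(excess) > 0))
  expect_lt(abs(excess[1]), 3 * sqrt(2 * exp(-1) / 3 / n))
})

test_that("the same seed reproduces trees and variants bit for bit", {
  net <- species_network()
  d <- tiny_design()
  t1 <- simulate_gene_trees(net, d, 20, seed = 42)
  t2 <- simulate_gene_trees(net, d, 20, seed = 42)
  expect_identical(t1, t2)
  v1 <- simulate_variants(t1, mutation_model(theta = 1), seed = 43)
  v2 <- simulate_variants(t2, mutation_model(theta = 1), seed = 43)
  expect_identical(v1, v2)
  v3 <- simulate_variants(t1, mutation_model(theta = 1), seed = 44)
  expect_false(identical(v1$markers$pos, v3$markers$pos))
})

test_that("theta = 0 yields an empty variant table", {
  trees <- simulate_gene_trees(species_network(), tiny_design(), 5,
                               seed = 1)
  vt <- simulate_variants(trees, mutation_model(theta = 0), seed = 2)
  expect_equal(n_markers(vt), 0L)
})

test_that("marker counts are Poisson with mean theta x tree length", {
  tr <- ape::read.tree(text = "(((C1_1:1,D1_1:1):1,O1_1:2):1,A1_1:3);")
  trees <- gene_tree_set(list(tr))
  L <- sum(tr$edge.length)  # 9
  theta <- 2
  set.seed(55)
  counts <- vapply(1:400, function(i)
    n_markers(simulate_variants(trees, mutation_model(theta = theta))),
    0L)
  expect_lt(abs(mean(counts) - theta * L), 0.05 * theta * L)
})

test_that("indel fraction one with minimum length five emits only long indels", {
  trees <- simulate_gene_trees(species_network(), tiny_design(), 30,
                               seed = 9)
  vt <- simulate_variants(trees,
                          mutation_model(theta = 0.5, indel_fraction = 1,
                                         indel_min_len = 5), seed = 10)
  expect_gt(n_markers(vt), 0)
  expect_true(all(vt$markers$class == "indel"))
  expect_true(all(vt$markers$indel_len >= 5))
  expect_true(all(abs(nchar(vt$markers$ref) - nchar(vt$markers$alt)) ==
                    vt$markers$indel_len))
})

test_that("every marker is biallelic and the outgroup defines the ancestral allele", {
  trees <- simulate_gene_trees(species_network(), tiny_design(), 100,
                               seed = 13)
  vt <- simulate_variants(trees, mutation_model(theta = 1), seed = 14)
  expect_true(all(vt$markers$ref != vt$markers$alt))
  expect_true(all(vt$geno %in% 0:2))
  # the outgroup is never fixed for the ALT (derived) allele
  s <- summarize_groups(vt, design_group_map(tiny_design()),
                        min_call_rate = 0)
  expect_false(any(s$state[, "A"] == "fixed-alt"))
})

test_that("planted alignments satisfy their specification exactly", {
  net <- species_network()
  d <- sample_design(2, 2, 2, 1)
  pl <- planted_signals(gene = 3, origin = "C", n_fix = 6,
                        k_from_c = 7, k_from_o = 4)
  aln <- simulate_gene_alignments(net, d, 5, planted = pl, seed = 77,
                                  n_codons = 100, theta = 0.3)
  expect_length(aln, 5)
  expect_true(all(vapply(aln, ncol, 0L) == 300))
  k <- alternating_fixed_aa(aln[["gene0003"]])
  expect_gte(k$k_from_c, 7)  # planted positions; background can add
  expect_gte(k$k_from_o, 4)
  nf <- count_fixed_nonsynonymous(aln[["gene0003"]], grouping = "DC_vs_O")
  expect_gte(as.integer(nf), 6 + 7)  # planted fixed + D-matches-C sites
  # no internal stops anywhere
  for (g in names(aln)) {
    aa <- hybridsig:::.translate_aln(aln[[g]])
    expect_false(any(aa == "*"), info = g)
  }
})

test_that("zero mutation rate with no planting gives identical sequences", {
  aln <- simulate_gene_alignments(species_network(), tiny_design(), 2,
                                  seed = 5, n_codons = 50, theta = 0)
  for (g in names(aln))
    expect_true(all(aln[[g]] == rep(aln[[g]][1, ], each = nrow(aln[[g]]))))
})

test_that("planting more codons than the gene holds is rejected", {
  expect_error(
    simulate_gene_alignments(species_network(), tiny_design(), 2,
                             planted = planted_signals(1, "C",
                                                       n_fix = 60),
                             n_codons = 50, seed = 1),
    "exceed")
  expect_error(planted_signals(c(1, 1), c("C", "O")), "unique")
})
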