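# Per-gene selection statistics: polymorphism/divergence, the HKA
# contrast, fixed non-synonymous counting, ranking, origin assignment,
# the PSG/hybrid-signal calls, and the alternating amino-acid scan.

gm_aln <- function() group_map(c("C1", "D1", "O1", "A1"),
                               c("C", "D", "O", "A"))

test_that("polymorphism and divergence are counted per column", {
  # identical sequences: (0, 0)
  a0 <- aln_from_codons(list(C = c("GAA", "AAA"), D = c("GAA", "AAA"),
                             O = c("GAA", "AAA")))
  pd0 <- polymorphism_divergence(a0, gm_aln(), "DC_vs_O")
  expect_equal(c(pd0$S, pd0$K), c(0L, 0L))
  # one column fixed ref|alt between the sides: (0, 1)
  a1 <- aln_from_codons(list(C = c("GAA"), D = c("GAA"), O = c("GAT")))
  pd1 <- polymorphism_divergence(a1, gm_aln(), "DC_vs_O")
  expect_equal(c(pd1$S, pd1$K), c(0L, 1L))
  # 12-column toy, hand enumeration: rows C,D pair vs O contrast
  mat <- rbind(
    C1_1 = strsplit("ACGTACGTACGT", "")[[1]],
    C1_2 = strsplit("ACGTACGTACGT", "")[[1]],
    D1_1 = strsplit("ACGAACGTACGT", "")[[1]],  # col 4 polymorphic in pair
    D1_2 = strsplit("ACGAACGTACGT", "")[[1]],
    O1_1 = strsplit("ACGTAAGTACGA", "")[[1]])  # col 6, 12 fixed diffs? see below
  # col 4: pair T/T/A/A poly; col 6: pair C, contrast A -> K;
  # col 12: pair T, contrast A -> K
  pd <- polymorphism_divergence(mat, gm_aln(), "DC_vs_O")
  expect_equal(pd$S, 1L)
  expect_equal(pd$K, 2L)
  # gap columns are excluded and counted
  mat2 <- mat; mat2[1, 1] <- "-"
  pd2 <- polymorphism_divergence(mat2, gm_aln(), "DC_vs_O")
  expect_equal(pd2$n_excluded, 1L)
  expect_error(polymorphism_divergence(mat[1:2, , drop = FALSE],
                                       gm_aln(), "DC_vs_O"), "empty side")
})

test_that("the HKA chi-square matches its closed form", {
  # gene proportions equal to genome proportions: statistic 0
  h0 <- hka_test(5, 10, 50, 100)
  expect_equal(h0$statistic, 0)
  expect_equal(h0$p_value, 1)
  # toy table against direct evaluation
  h1 <- hka_test(5, 20, 1000, 2000)
  a <- 5; b <- 20; c <- 995; d <- 1980; N <- a + b + c + d
  chi <- N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(h1$statistic, chi)
  expect_equal(h1$p_value, pchisq(chi, 1, lower.tail = FALSE))
  expect_error(hka_test(10, 0, 5, 100), "at least the gene counts")
  expect_true(is.na(hka_test(0, 0, 0, 10)$p_value))
})

test_that("fixed non-synonymous codons are counted via the genetic code", {
  # GAA vs GAG both Glu: synonymous, contributes 0
  syn <- aln_from_codons(list(C = "GAA", D = "GAA", O = "GAG"))
  expect_equal(as.integer(count_fixed_nonsynonymous(syn, gm_aln())), 0L)
  # GAA (Glu) vs GAT (Asp): contributes 1
  nsyn <- aln_from_codons(list(C = "GAA", D = "GAA", O = "GAT"))
  expect_equal(as.integer(count_fixed_nonsynonymous(nsyn, gm_aln())), 1L)
  # 5-codon toy with two planted replacements
  five <- aln_from_codons(list(
    C = c("GAA", "AAA", "CGT", "TTC", "GGA"),
    D = c("GAA", "AAA", "CGT", "TTC", "GGA"),
    O = c("GAG", "GAA", "CGT", "TCC", "GGA")))  # codon 2 and 4 nonsyn
  expect_equal(as.integer(count_fixed_nonsynonymous(five, gm_aln())), 2L)
  # codons with gaps are skipped and counted
  gappy <- five
  gappy[1, 1] <- "-"
  n <- count_fixed_nonsynonymous(gappy, gm_aln())
  expect_equal(attr(n, "n_skipped"), 1L)
  expect_error(count_fixed_nonsynonymous(five[, 1:4], gm_aln()),
               "divisible by 3")
})

test_that("rank_top_fraction keeps the stated fraction with ties included", {
  set.seed(111)
  v <- sample(1000)
  expect_equal(sum(rank_top_fraction(v, 0.025)), 25L)
  expect_true(all(v[rank_top_fraction(v, 0.025)] > 975))
  # ties spanning the cutoff are all kept
  v2 <- c(10, 9, rep(8, 5), seq(0.1, 4, length.out = 40))
  expect_equal(sum(rank_top_fraction(v2, 3 / length(v2))), 7L)
  # degenerate all-equal input flags everything (with a message)
  expect_message(out <- rank_top_fraction(rep(3, 10), 0.1), "degenerate")
  expect_true(all(out))
})

test_that("origin assignment follows the haplotype tree", {
  # D identical to C, O divergent: parentC
  a <- aln_from_codons(list(C = c("GAA", "AAA", "CGT", "ACC"),
                            D = c("GAA", "AAA", "CGT", "ACC"),
                            O = c("GAT", "GAA", "CAT", "GCC")))
  expect_equal(as.character(assign_origin(a, gm_aln())), "parentC")
  # D exactly intermediate: ambiguous
  b <- aln_from_codons(list(C = c("GAA", "GAA", "AAA", "AAA"),
                            D = c("GAA", "GAA", "GAT", "GAT"),
                            O = c("GAT", "GAT", "GAT", "GAT")))
  b2 <- b; b2["D1_1", ] <- b["D1_2", ]  # keep D haplotypes identical
  expect_equal(as.character(assign_origin(b2, gm_aln())), "ambiguous")
  # swapping the parents' labels swaps the call
  a_sw <- a
  rownames(a_sw) <- sub("^C", "X", rownames(a_sw))
  rownames(a_sw) <- sub("^O", "C", rownames(a_sw))
  rownames(a_sw) <- sub("^X", "O", rownames(a_sw))
  expect_equal(as.character(assign_origin(a_sw, gm_aln())), "parentO")
  # monomorphic gene: ambiguous with a diagnostic
  mono <- aln_from_codons(list(C = "GAA", D = "GAA", O = "GAA"))
  expect_equal(as.character(assign_origin(mono, gm_aln())), "ambiguous")
})

test_that("the alternating amino-acid scan matches a brute-force oracle", {
  # 2 positions D matches C, 1 position D matches O
  a <- aln_from_codons(list(
    C = c("GAA", "CGT", "TTC", "AAA"),
    D = c("GAA", "CGT", "TCC", "AAA"),
    O = c("GAT", "CAT", "TCC", "AAA")))
  k <- alternating_fixed_aa(a, gm_aln())
  expect_equal(c(k$k_from_c, k$k_from_o), c(2L, 1L))
  # no C/O fixed differences: (0, 0)
  none <- aln_from_codons(list(C = c("GAA", "AAA"), D = c("GAT", "AAA"),
                               O = c("GAA", "AAA")))
  k0 <- alternating_fixed_aa(none, gm_aln())
  expect_equal(c(k0$k_from_c, k0$k_from_o), c(0L, 0L))
  # random 50-codon alignment against an exhaustive position-wise scan
  set.seed(121)
  sense <- hybridsig:::.sense_codons()
  cods <- list(C = sample(sense, 50, TRUE), O = sample(sense, 50, TRUE))
  cods$D <- ifelse(runif(50) < 0.5, cods$C, cods$O)
  a3 <- aln_from_codons(cods)
  k3 <- alternating_fixed_aa(a3, gm_aln())
  tab <- hybridsig:::.codon_aa()
  kc <- ko <- 0L
  for (i in 1:50) {
    ac <- tab[[cods$C[i]]]; ao <- tab[[cods$O[i]]]; ad <- tab[[cods$D[i]]]
    if (ac != ao) {
      if (ad == ac) kc <- kc + 1L
      if (ad == ao) ko <- ko + 1L
    }
  }
  expect_equal(c(k3$k_from_c, k3$k_from_o), c(kc, ko))
})

test_that("PSG and hybrid-signal calls apply the stated criteria", {
  stats <- data.frame(
    gene = rep(c("g1", "g2", "g3", "g4"), 2),
    grouping = rep(c("DC_vs_O", "DO_vs_C"), each = 4),
    hka_p = c(0.001, 0.02, 0.005, 0.5,   # DC
              0.2, 0.001, 0.004, 0.9),   # DO
    top_nfix = c(TRUE, TRUE, TRUE, TRUE,
                 FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  origins <- c(g1 = "parentC", g2 = "parentC", g3 = "ambiguous",
               g4 = "parentO")
  calls <- call_psgs(stats, origins)
  expect_equal(calls$from_c, "g1")            # g2 fails HKA (p = 0.02)
  expect_equal(calls$from_o, character(0))    # g2 wrong origin for DO
  expect_equal(call_hybrid_signal(stats), "g3")
})

test_that("the scan recovers planted selection and origin end to end", {
  net <- species_network()
  d <- sample_design(3, 3, 3, 1)
  pl <- planted_signals(gene = c(11, 52, 93, 140, 30, 77, 163),
                        origin = c(rep("C", 4), rep("O", 3)),
                        n_fix = 10)
  aln <- simulate_gene_alignments(net, d, 200, planted = pl, seed = 131)
  res <- psg_scan(aln)
  planted_c <- sort(attr(aln, "planting")$gene_id[1:4])
  planted_o <- sort(attr(aln, "planting")$gene_id[5:7])
  expect_true(all(planted_c %in% res$psg_from_c))
  expect_true(all(planted_o %in% res$psg_from_o))
  expect_lte(length(res$psg_from_c) - 4, 2)
  expect_lte(length(res$psg_from_o) - 3, 2)
  # scan output does not depend on gene order
  perm <- sample(length(aln))
  aln_p <- aln[perm]
  class(aln_p) <- class(aln)
  attr(aln_p, "groups") <- attr(aln, "groups")
  res_p <- psg_scan(aln_p)
  expect_equal(res_p$psg_from_c, res$psg_from_c)
  expect_equal(res_p$psg_from_o, res$psg_from_o)
})

test_that("a recombinant gene is seen by both groupings", {
  net <- species_network()
  d <- sample_design(3, 3, 3, 1)
  pl <- planted_signals(gene = 7, origin = "C", n_fix = 0,
                        k_from_c = 7, k_from_o = 4)
  aln <- simulate_gene_alignments(net, d, 60, planted = pl, seed = 141)
  g <- aln[["gene0007"]]
  k <- alternating_fixed_aa(g)
  expect_equal(c(k$k_from_c, k$k_from_o) >= c(7L, 4L), c(TRUE, TRUE))
  # under DC_vs_O the k_from_c sites are fixed differences, under
  # DO_vs_C the k_from_o sites are
  expect_gte(as.integer(count_fixed_nonsynonymous(g, grouping = "DC_vs_O")), 7L)
  expect_gte(as.integer(count_fixed_nonsynonymous(g, grouping = "DO_vs_C")), 4L)
})
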