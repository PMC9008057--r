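# VCF round trip, marker classification from REF/ALT, the long-indel
# filter, and group allele summaries.

test_that("simulate -> write VCF -> read reproduces the genotype matrix", {
  d <- tiny_design()
  trees <- simulate_gene_trees(species_network(), d, 60, seed = 2)
  vt <- simulate_variants(trees,
                          mutation_model(theta = 1, indel_fraction = 0.5),
                          seed = 3)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vt, f)
  rr <- read_variants(f, design_group_map(d))
  expect_identical(unname(rr$variants$geno), unname(vt$geno))
  expect_equal(rr$variants$markers$pos, vt$markers$pos)
  expect_equal(rr$variants$markers$class, vt$markers$class)
  expect_equal(rr$variants$markers$indel_len, vt$markers$indel_len)
})

test_that("REF/ALT determine marker class and indel length; multi-allelics are skipped", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    "1\t100\t.\tACGTGA\tA\t.\tPASS\t.\tGT\t0/0\t1/1",
    "1\t200\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t./.",
    "1\t300\t.\tA\tA,T\t.\tPASS\t.\tGT\t0/1\t0/2"), f)
  gm <- group_map(c("s1", "s2"), c("C", "O"))
  expect_message(rr <- read_variants(f, gm), "1 multi-allelic")
  m <- rr$variants$markers
  expect_equal(nrow(m), 2L)
  expect_equal(m$class, c("indel", "snp"))
  expect_equal(m$indel_len, c(5L, 0L))
  expect_equal(attr(rr$variants, "n_multiallelic_skipped"), 1L)
  expect_equal(rr$variants$geno[, "s1"], c(0L, 1L))
  expect_true(is.na(rr$variants$geno[2, "s2"]))
})

test_that("a VCF sample missing from the group map is named in the error", {
  d <- tiny_design()
  trees <- simulate_gene_trees(species_network(), d, 5, seed = 4)
  vt <- simulate_variants(trees, mutation_model(theta = 1), seed = 5)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vt, f)
  gm <- design_group_map(d)
  expect_error(read_variants(f, gm[gm$sample != "O1", ]), "O1")
})

test_that("filter_long_indels honours the 5 bp threshold and is idempotent", {
  geno <- matrix(0L, 4, 2, dimnames = list(NULL, c("s1", "s2")))
  vt <- vt_from_geno(geno,
                     class = c("indel", "indel", "snp", "indel"),
                     indel_len = c(4L, 5L, 0L, 12L))
  out <- filter_long_indels(vt)
  expect_equal(out$markers$indel_len, c(5L, 12L))
  expect_identical(filter_long_indels(out), out)
  # order preserved, commutes with subsetting
  expect_identical(filter_long_indels(vt_subset(vt, c(4, 2, 1))),
                   vt_subset(filter_long_indels(vt_subset(vt, c(4, 2, 1))),
                             1:2))
  # SNP-only and empty tables give empty results
  expect_equal(n_markers(filter_long_indels(vt_from_geno(geno))), 0L)
  expect_equal(n_markers(filter_long_indels(vt_subset(vt, integer()))), 0L)
  expect_error(filter_long_indels(vt, min_len = 0), "min_len")
})

test_that("summarize_groups computes fixedness per the call-rate contract", {
  gm <- group_map(c("c1", "c2", "c3", "a1"), c("C", "C", "C", "A"))
  geno <- rbind(c(2L, 2L, 2L, 0L),    # all hom-alt -> fixed-alt
                c(1L, 2L, 2L, 0L),    # one het -> polymorphic
                c(2L, NA, NA, 0L))    # call rate 1/3 -> insufficient
  colnames(geno) <- gm$sample
  s <- summarize_groups(vt_from_geno(geno), gm, min_call_rate = 0.7)
  expect_equal(s$state[, "C"],
               c("fixed-alt", "polymorphic", "insufficient"))
  expect_equal(unname(s$freq[1, "C"]), 1.0)
  expect_equal(unname(s$freq[2, "C"]), 5 / 6)
  expect_equal(unname(s$call_rate[3, "C"]), 1 / 3)
})

test_that("summary frequencies equal a brute-force recount", {
  d <- tiny_design()
  gm <- design_group_map(d)
  trees <- simulate_gene_trees(species_network(), d, 60, seed = 21)
  vt <- simulate_variants(trees, mutation_model(theta = 1), seed = 22)
  s <- summarize_groups(vt, gm)
  set.seed(23)
  idx <- sample(n_markers(vt), min(100, n_markers(vt)))
  for (i in idx) {
    for (g in c("C", "D", "O", "A")) {
      cols <- which(gm$group[match(vt$samples, gm$sample)] == g)
      x <- vt$geno[i, cols]
      expect_equal(unname(s$freq[i, g]), sum(x, na.rm = TRUE) /
                     (2 * sum(!is.na(x))))
    }
  }
})

test_that("polarization uses the outgroup fixed state", {
  gm <- group_map(c("c1", "d1", "o1", "a1"), c("C", "D", "O", "A"))
  geno <- rbind(c(2L, 0L, 0L, 0L),  # A fixed-ref: derived = alt freq
                c(0L, 2L, 0L, 2L),  # A fixed-alt: derived flipped
                c(0L, 0L, 2L, 1L))  # A heterozygous: unpolarizable
  colnames(geno) <- gm$sample
  s <- summarize_groups(vt_from_geno(geno), gm)
  expect_equal(s$polarizable, c(TRUE, TRUE, FALSE))
  expect_equal(unname(s$derived[1, "C"]), 1.0)
  expect_equal(unname(s$derived[2, "C"]), 1.0)   # flipped: C carries ref = derived
  expect_equal(unname(s$derived[2, "D"]), 0.0)
  expect_true(all(is.na(s$derived[3, ])))
})

test_that("newick and FASTA inputs are parsed with their edge cases", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(((C1_1,D1_1)95,O1_1)88,A1_1);", f)
  trees <- read_gene_trees(f)
  expect_length(trees, 1L)
  expect_true("95" %in% trees[[1]]$node.label)
  expect_equal(classify_topology(trees[[1]]), "I")

  dir <- withr::local_tempdir()
  writeLines(c(">h1", "ACGACG", ">h2", "ACGACT"),
             file.path(dir, "g1.fasta"))
  alns <- read_alignments(dir)
  expect_length(alns, 1L)
  expect_equal(dim(alns[["g1"]]), c(2L, 6L))
  writeLines(c(">h1", "ACGACG", ">h2", "ACGAC"),
             file.path(dir, "bad.fasta"))
  expect_error(read_alignments(dir), "bad")
  expect_length(read_alignments(withr::local_tempdir()), 0L)
})

test_that("group map round trip and validation", {
  gm <- group_map(c("s1", "s2"), c("C", "O"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_group_map(gm, f)
  expect_equal(as.data.frame(read_group_map(f)), as.data.frame(gm))
  expect_error(group_map(c("s1", "s1"), c("C", "O")), "s1")
  expect_error(group_map("s1", "X"), "C, D, O, A")
})
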