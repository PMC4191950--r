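# enumeration oracle for the two-sided Fisher test: sum the probabilities of
# all tables sharing the margins whose point probability <= the observed one
fisher_enum <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(m[, 2]) == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(ks, r1, r2, c1)
  obs <- dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

test_that("plus-strand codon substitution classifies by the genetic code", {
  # contig: one gene, CDS 4..12 = ATG GAA TAA; site 9 A->G is GAA->GAG (Glu)
  fx <- write_gene_fixture("TTTATGGAATAATTTTTT", data.frame(start = 4L, end = 12L))
  gm <- read_gene_models(fx$gff, fx$fasta)
  eff <- annotate_effects("ctg1", 9L, "A", "G", gm)
  expect_equal(eff$effect, "synonymous")
  expect_equal(c(eff$codon_before, eff$codon_after), c("GAA", "GAG"))
  expect_equal(c(eff$aa_before, eff$aa_after), c("E", "E"))
  # second codon position A->C: GAA->GCA, Glu->Ala
  eff2 <- annotate_effects("ctg1", 8L, "A", "C", gm)
  expect_equal(eff2$effect, "nonsynonymous")
  # outside any CDS
  expect_equal(annotate_effects("ctg1", 2L, "T", "A", gm)$effect, "noncoding")
  # reference mismatch is a data-integrity error
  expect_error(annotate_effects("ctg1", 9L, "C", "G", gm), "reference base mismatch")
})

test_that("minus-strand sites are complemented into the coding frame", {
  # genome 4..12 on minus strand reads ATG CAT TAA (revcomp of TTAATGCAT);
  # genomic T->C at position 8 flips coding CAT -> CGT (His -> Arg)
  fx <- write_gene_fixture("TTTTTAATGCATTTTTTT", data.frame(start = 4L, end = 12L),
                           strand = "-")
  gm <- read_gene_models(fx$gff, fx$fasta)
  expect_equal(gm$cds$strand, "-")
  eff <- annotate_effects("ctg1", 8L, "T", "C", gm)
  expect_equal(c(eff$codon_before, eff$codon_after), c("CAT", "CGT"))
  expect_equal(eff$effect, "nonsynonymous")
  expect_equal(c(eff$aa_before, eff$aa_after), c("H", "R"))
})

test_that("effect calls agree with simulator-planted truth", {
  sim <- simulate_metapopulation(
    small_sim_config(seed = 17, chromosomes = stats::setNames(
                       rep(400000L, 3L), c("chrI", "chrII", "chrIII")),
                     n_islands = 9L, island_length_range = c(15000L, 40000L),
                     gene_fraction = 1, n_background_genes = 12L,
                     background_snp_rate = 0.05),
    dir = tempfile())
  truth <- sim$truth$effects
  expect_gte(nrow(truth), 500L)
  gm <- read_gene_models(sim$paths$gff, sim$paths$fasta)
  ts <- sim$truth$sites
  idx <- match(paste(truth$chrom, truth$pos), paste(ts$chrom, ts$pos))
  eff <- annotate_effects(truth$chrom, truth$pos, ts$ref[idx], ts$alt[idx], gm)
  expect_identical(eff$effect, truth$effect)
  expect_identical(eff$gene_id, truth$gene_id)
})

test_that("effect classification is invariant to allele order", {
  fx <- write_gene_fixture("TTTATGGAATAATTTTTT", data.frame(start = 4L, end = 12L))
  gm <- read_gene_models(fx$gff, fx$fasta)
  a <- annotate_effects("ctg1", 9L, "A", "G", gm)
  b <- annotate_effects("ctg1", 9L, "G", "A", gm)
  expect_equal(a$effect, b$effect)
  expect_equal(a$codon_after, b$codon_after)
})

test_that("NS/S tables and ratios follow the published conventions", {
  t1 <- ns_s_table(c(139, 146), c(17, 4))
  expect_equal(unname(t1$ratios), c(4.25, 0.95)[c(2, 1)])
  expect_equal(t1$table["within", ], c(nonsynonymous = 139L, synonymous = 146L))
  t0 <- ns_s_table(c(0, 5), c(1, 0))
  expect_equal(unname(t0$ratios[1]), 0)
  expect_true(t0$infinite_ratio[2])
  # from effect-call data frames
  eff_in <- data.frame(effect = c("nonsynonymous", "synonymous", "synonymous"))
  eff_out <- data.frame(effect = "nonsynonymous")
  t2 <- ns_s_table(eff_in, eff_out)
  expect_equal(unname(t2$table[, "nonsynonymous"]), c(1L, 1L))
})

test_that("two-tailed Fisher matches the published value and an enumeration oracle", {
  tab <- matrix(c(17, 139, 4, 146), 2)
  expect_equal(round(fisher_exact_two_tailed(tab), 4), 0.0056)
  expect_equal(fisher_exact_two_tailed(matrix(c(5, 5, 5, 5), 2)), 1.0)
  expect_equal(fisher_exact_two_tailed(matrix(c(0, 0, 3, 4), 2)), 1)  # zero margin
  set.seed(99)
  for (i in 1:25) {
    m <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact_two_tailed(m), fisher_enum(m), tolerance = 1e-10)
    # invariance under transposition and simultaneous row/column swaps
    expect_equal(fisher_exact_two_tailed(t(m)), fisher_exact_two_tailed(m))
    expect_equal(fisher_exact_two_tailed(m[2:1, 2:1]), fisher_exact_two_tailed(m))
  }
})
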