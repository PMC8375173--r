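test_that("simulated proteins are deterministic per seed", {
  a <- simulate_protein(c("Q", "M3"), gaps = 9, seed = 42)
  b <- simulate_protein(c("Q", "M3"), gaps = 9, seed = 42)
  c <- simulate_protein(c("Q", "M3"), gaps = 9, seed = 43)
  expect_identical(a$sequence, b$sequence)
  expect_false(identical(a$sequence, c$sequence))
  expect_identical(attr(a, "truth"), attr(c, "truth"))  # only filler varies
})

test_that("impossible protein specs are rejected", {
  expect_error(simulate_protein(c("Q", "Q"), gaps = -1),
               class = "zf_simulate_error")
  expect_error(simulate_protein(c("Q", "Q"), gaps = c(1, 2)),
               class = "zf_simulate_error")
  expect_error(simulate_protein("W1"), class = "zf_simulate_error")
})

test_that("planted tandem/isolated examples classify as designed", {
  tand <- assign_subsets(scan_domains(
    simulate_protein(c("Q", "Q"), gaps = 11, seed = 1)))
  expect_equal(tand$arrangement, "tandem")
  expect_equal(tand$subset, "Ta-t1-SF")

  mix <- assign_subsets(scan_domains(
    simulate_protein(c("M4", "Z1"), gaps = 40, seed = 1)))
  expect_equal(mix$arrangement, "isolated")
  expect_equal(mix$subset, "Ta-2i-Mix-SF")
  expect_equal(mix$type_string, "M4;Z1")
})

test_that("codon-pair generator hits its targets on average", {
  est <- vapply(1:50, function(s) {
    kaks(simulate_codon_pair(0.2, 0.02, 300, seed = s)$pair)$Ks
  }, numeric(1))
  expect_gt(mean(est), 0.15)
  expect_lt(mean(est), 0.25)
})

test_that("zero-divergence and pure-synonymous targets behave", {
  sim <- simulate_codon_pair(0, 0, 50, seed = 3)
  expect_identical(sim$pair$cds_a, sim$pair$cds_b)
  omegas <- vapply(1:40, function(s) {
    r <- kaks(simulate_codon_pair(0.1, 0, 200, seed = s)$pair)
    ifelse(is.na(r$omega), 0, r$omega)
  }, numeric(1))
  expect_gte(mean(omegas < 1), 0.95)
})

test_that("unattainable codon-pair targets error", {
  expect_error(simulate_codon_pair(5, 5, 10, seed = 1),
               class = "zf_simulate_error")
})

test_that("expression generator plants recoverable groups", {
  # zero noise: exact recovery
  sim0 <- simulate_expression(c(3, 4, 5), sigma = 0, seed = 2)
  cl0 <- cluster_expression(sim0$tpm, k = 3)
  expect_equal(tidy(cl0)$group, sim0$labels$group)
  # single group
  sim1 <- simulate_expression(7, sigma = 0.1, seed = 2)
  expect_equal(unique(sim1$labels$group), 1L)
})

test_that("fixture tallies are identical across seeds", {
  m1 <- survey_fixture(seed = 2)$manifest
  m2 <- survey_fixture(seed = 99)$manifest
  m1$seed <- m2$seed <- NULL
  expect_identical(m1, m2)
})

test_that("fixture composition matches its manifest", {
  fx <- survey_fixture(seed = 3)
  man <- fx$manifest
  expect_equal(nrow(fx$proteins), man$n_proteins)
  expect_equal(length(unique(fx$proteins$gene_id)), man$n_genes)
  expect_equal(sum(fx$proteins$variant >= 2), man$n_splice_variants)
  loci <- parse_gene_id(unique(fx$proteins$gene_id))
  expect_true(all(loci$valid))
  expect_equal(sum(loci$subgenome == "B"), man$genes_subgenome_b)
  expect_equal(sum(loci$arm == "L"), man$genes_long_arm)
  ic <- count_introns(fx$gene_models)
  expect_equal(sum(ic$n_introns == 0), man$intronless_genes)
  expect_equal(nrow(ic), man$n_genes)
})

test_that("fixture files round-trip through standard formats", {
  fx <- survey_fixture(seed = 4)
  dir <- withr::local_tempdir()
  write_survey_fixture(fx, dir)
  prots <- read_protein_fasta(file.path(dir, "proteome.fa"))
  expect_equal(prots$id, fx$proteins$id)
  expect_equal(prots$sequence, fx$proteins$sequence)
  gm <- read_gene_models(file.path(dir, "gene_models.gff3"))
  expect_equal(nrow(gm), nrow(fx$gene_models))
  expect_equal(sort(unique(gm$gene_id)), sort(unique(fx$gene_models$gene_id)))
  tpm <- read_tpm_matrix(file.path(dir, "tpm.tsv"))
  expect_equal(as.data.frame(tpm), as.data.frame(fx$tpm), tolerance = 1e-9)
})
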