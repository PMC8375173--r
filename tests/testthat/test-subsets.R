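make_domains <- function(spans, types = NULL, id = "p") {
  # spans: list of c(start, end); minimal domain rows for architecture tests
  n <- length(spans)
  if (is.null(types)) types <- rep("Q", n)
  tibble::tibble(
    protein_id = id,
    start = vapply(spans, `[`, 0, 1), end = vapply(spans, `[`, 0, 2),
    c1 = vapply(spans, `[`, 0, 1), c2 = vapply(spans, `[`, 0, 1) + 3L,
    h1 = vapply(spans, `[`, 0, 2) - 4L, h2 = vapply(spans, `[`, 0, 2),
    spacing = 12L, window = "QALGGH", mismatches = 0L, dtype = types
  )
}

test_that("architecture gaps are computed from inclusive spans", {
  # spans [3,23] and [35,55]: residues 24..34 strictly between -> gap 11
  arch <- build_architecture(make_domains(list(c(3, 23), c(35, 55))))
  expect_equal(arch$gap_next, c(11L, NA))
  expect_equal(build_architecture(make_domains(list(c(3, 23))))$gap_next,
               NA_integer_)
  expect_error(build_architecture(make_domains(list(c(3, 23), c(20, 40)))),
               class = "zf_architecture_error")
})

test_that("the tandem boundary sits exactly between gaps 11 and 12", {
  two <- function(gap) {
    make_domains(list(c(1, 21), c(21 + gap + 1, 21 + gap + 21)))
  }
  t11 <- assign_subsets(two(11))
  t12 <- assign_subsets(two(12))
  expect_equal(t11$arrangement, "tandem")
  expect_equal(t12$arrangement, "isolated")
  # flipping the single gap changes arrangement/subset and nothing else
  expect_equal(t11$n_domains, t12$n_domains)
  expect_equal(t11$type_string, t12$type_string)
  expect_false(t11$subset == t12$subset)
})

test_that("linked runs partition into tandem arrays", {
  # gaps 5, 40, 5 over four fingers: two arrays of two -> tandem, t2
  d <- make_domains(list(c(1, 21), c(27, 47), c(88, 108), c(114, 134)),
                    types = c("M1", "M1", "M2", "M2"))
  a <- assign_subsets(d)
  expect_equal(a$arrangement, "tandem")
  expect_equal(a$n_arrays, 2L)
  expect_equal(a$subset, "Ta-t2-SF")
  # one array covering all fingers -> t1
  d2 <- make_domains(list(c(1, 21), c(27, 47), c(53, 73)),
                     types = c("M1", "M2", "Z1"))
  expect_equal(assign_subsets(d2)$subset, "Ta-t1-SF")
  # array plus a dispersed finger -> t2
  d3 <- make_domains(list(c(1, 21), c(27, 47), c(100, 120)),
                     types = c("M1", "M2", "Z1"))
  a3 <- assign_subsets(d3)
  expect_equal(a3$arrangement, "tandem")
  expect_equal(a3$subset, "Ta-t2-SF")
})

test_that("isolated subsets follow finger count and collapsed type", {
  single <- function(ty) {
    assign_subsets(make_domains(list(c(1, 21)), types = ty))$subset
  }
  expect_equal(single("Q"), "Ta-1i-Q-SF")
  expect_equal(single("M3"), "Ta-1i-M-SF")
  expect_equal(single("Z2"), "Ta-1i-Z-SF")
  expect_equal(single("D"), "Ta-1i-D-SF")

  pair <- function(t1, t2) {
    assign_subsets(make_domains(list(c(1, 21), c(50, 70)),
                                types = c(t1, t2)))$subset
  }
  expect_equal(pair("Q", "Q"), "Ta-2i-Q-SF")
  expect_equal(pair("M1", "M4"), "Ta-2i-M-SF")  # M-subclass collapsed
  expect_equal(pair("Z1", "Z2"), "Ta-2i-Z-SF")
  expect_equal(pair("Q", "M2"), "Ta-2i-Mix-SF")
  expect_equal(pair("M4", "Z1"), "Ta-2i-Mix-SF")
  expect_equal(pair("Q", "D"), "Ta-2i-Mix-SF")

  multi <- function(n) {
    spans <- lapply(seq_len(n), function(i) c(1 + 60 * (i - 1),
                                              21 + 60 * (i - 1)))
    assign_subsets(make_domains(spans, types = rep("Q", n)))$subset
  }
  expect_equal(multi(3), "Ta-3i-SF")
  expect_equal(multi(4), "Ta-4i-SF")
  expect_equal(multi(5), "Ta-4i-SF")  # 5+ dispersed fingers binned into 4i
})

test_that("subset labels are invariant under M-subclass refinement", {
  for (k1 in 1:4) {
    for (k2 in 1:4) {
      s <- assign_subsets(make_domains(list(c(1, 21), c(50, 70)),
                                       types = paste0("M", c(k1, k2))))
      expect_equal(s$subset, "Ta-2i-M-SF")
    }
  }
})

test_that("variant dedupe picks the lowest splice index and flags drift", {
  doms <- dplyr::bind_rows(
    make_domains(list(c(1, 21), c(50, 70)), c("M4", "Z1"), id = "g1.11"),
    make_domains(list(c(1, 21), c(27, 47), c(53, 73), c(79, 99), c(105, 125)),
                 c("M3", "M4", "M4", "M4", "Z1"), id = "g1.1"),
    make_domains(list(c(1, 21)), "Q", id = "g2.1"),
    make_domains(list(c(1, 21)), "Q", id = "g2.2"),
    make_domains(list(c(1, 21)), "Z1", id = "g3")
  )
  asg <- assign_subsets(doms)
  prots <- tibble::tibble(
    id = c("g1.11", "g1.1", "g2.1", "g2.2", "g3"),
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    variant = c(11L, 1L, 1L, 2L, NA)
  )
  dd <- dedupe_variants(asg, prots)
  expect_setequal(dd$representatives$protein_id, c("g1.1", "g2.1", "g3"))
  expect_equal(dd$divergent$gene_id, "g1")   # g2's variants agree, g3 single
})

test_that("intron counts are exons minus one", {
  gm <- tibble::tibble(
    gene_id = c("g1", "g2", "g2", "g2", rep("g3", 11)),
    mrna_id = c("g1.1", "g2.1", "g2.1", "g2.1", rep("g3.1", 11)),
    start = c(1, 1, 201, 401, seq(1, by = 300, length.out = 11)),
    end = c(100, 100, 300, 500, seq(200, by = 300, length.out = 11))
  )
  ic <- count_introns(gm)
  expect_equal(ic$n_introns[ic$gene_id == "g1"], 0L)
  expect_equal(ic$n_introns[ic$gene_id == "g2"], 2L)
  expect_equal(ic$n_introns[ic$gene_id == "g3"], 10L)
})

test_that("family summary percentages use half-up rounding and the right
           denominators", {
  asg <- tibble::tibble(
    protein_id = sprintf("Traes_%dAL_H%03d.1", c(rep(5, 3), 2, 2, 1, 1),
                         1:7),
    n_domains = 1L, type_string = "Q", n_arrays = c(1L, 1L, 1L, 0L, 0L,
                                                    0L, 0L),
    arrangement = c(rep("tandem", 3), rep("isolated", 4)),
    subset = c(rep("Ta-t1-SF", 3), rep("Ta-1i-Q-SF", 4))
  )
  s <- summarize_family(asg, parse_gene_id(asg$protein_id))
  expect_equal(s$n_proteins, 7L)
  expect_equal(s$arrangement$percent[s$arrangement$arrangement == "tandem"],
               42.9)  # 3/7 = 42.857 -> half-up 42.9
  expect_equal(sum(s$subsets$n), 7L)
  expect_equal(s$n_genes, 7L)
  expect_equal(s$chromosomes$n[s$chromosomes$chromosome == 5], 3L)
})

test_that("invalid loci are skipped from locus tables with a count", {
  asg <- tibble::tibble(
    protein_id = c("Traes_1AL_AAA.1", "freeform"),
    n_domains = 1L, type_string = "Q", n_arrays = 0L,
    arrangement = "isolated", subset = "Ta-1i-Q-SF"
  )
  s <- summarize_family(asg, parse_gene_id(asg$protein_id))
  expect_equal(s$n_genes, 1L)
  expect_equal(s$n_skipped_loci, 1L)
})
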