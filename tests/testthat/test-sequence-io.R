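test_that("protein FASTA reading normalises, orders and validates records", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">p2.1 some description", "mkcaecgkafsq",
               ">p1", "MKAAAX*"), fa)
  tbl <- read_protein_fasta(fa)
  expect_equal(tbl$id, c("p2.1", "p1"))           # order preserved
  expect_equal(tbl$sequence[1], "MKCAECGKAFSQ")   # uppercased
  expect_equal(tbl$sequence[2], "MKAAAX")         # stop stripped, X kept
  expect_equal(tbl$gene_id, c("p2", "p1"))
  expect_equal(tbl$variant, c(1L, NA_integer_))
})

test_that("FASTA degenerate inputs raise format errors", {
  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(read_protein_fasta(empty), class = "zf_format_error")

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "MKL", ">a", "MKV"), dup)
  expect_error(read_protein_fasta(dup), "duplicate.*a",
               class = "zf_format_error")

  blank <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "", ">b", "MK"), blank)
  expect_error(read_protein_fasta(blank), class = "zf_format_error")

  ambig <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "MKBZ"), ambig)  # B/Z ambiguity letters rejected
  expect_error(read_protein_fasta(ambig), class = "zf_format_error")
})

test_that("FASTA round trip preserves id/sequence pairs", {
  tbl <- tibble::tibble(id = c("x.1", "y"), sequence = c("MKLV", "ACDEF"))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_protein_fasta(tbl, fa)
  back <- read_protein_fasta(fa)
  expect_equal(back$id, tbl$id)
  expect_equal(back$sequence, tbl$sequence)
})

test_that("wheat gene ids parse into chromosome, sub-genome, arm, variant", {
  got <- parse_gene_id("Traes_5BL_D53A846BE.1")
  expect_equal(got$chromosome, 5L)
  expect_equal(got$subgenome, "B")
  expect_equal(got$arm, "L")
  expect_equal(got$hash, "D53A846BE")
  expect_equal(got$variant, 1L)

  got2 <- parse_gene_id("Traes_3AS_BE15533CD.3")
  expect_equal(got2$chromosome, 3L)
  expect_equal(got2$subgenome, "A")
  expect_equal(got2$arm, "S")
  expect_equal(got2$variant, 3L)
})

test_that("foreign id dialects fall back to locus-less mode or error", {
  got <- parse_gene_id("AT1G27730.1")
  expect_false(got$valid)
  expect_true(is.na(got$chromosome))
  expect_error(parse_gene_id("AT1G27730.1", strict = TRUE),
               class = "zf_parse_error")
  # case-sensitive dialect: lowercase arm fails
  expect_false(parse_gene_id("Traes_5Bl_D53A846BE.1")$valid)
})

test_that("compose/parse are inverse over all 42 locus combinations", {
  grid <- expand.grid(chromosome = 1:7, subgenome = c("A", "B", "D"),
                      arm = c("S", "L"), stringsAsFactors = FALSE)
  ids <- compose_gene_id(grid$chromosome, grid$subgenome, grid$arm,
                         hash = sprintf("HASH%02d", seq_len(nrow(grid))),
                         variant = seq_len(nrow(grid)))
  back <- parse_gene_id(ids)
  expect_true(all(back$valid))
  expect_equal(back$chromosome, grid$chromosome)
  expect_equal(back$subgenome, grid$subgenome)
  expect_equal(back$arm, grid$arm)
  expect_equal(back$variant, seq_len(nrow(grid)))
})

test_that("gene models read from GFF3 with sorted exons per mRNA", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t300\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t1\t300\t.\t+\t.\tID=g1.1;Parent=g1",
    "chr1\ttest\texon\t201\t300\t.\t+\t.\tID=g1.1.e2;Parent=g1.1",
    "chr1\ttest\texon\t1\t100\t.\t+\t.\tID=g1.1.e1;Parent=g1.1"
  ), gff)
  gm <- read_gene_models(gff)
  expect_equal(gm$start, c(1L, 201L))
  expect_equal(gm$end, c(100L, 300L))
  expect_equal(unique(gm$gene_id), "g1")
  expect_equal(count_introns(gm)$n_introns, 1L)
})

test_that("GFF3 structural problems are rejected, empty file is empty", {
  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(nrow(read_gene_models(empty)), 0L)

  orphan <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tt\texon\t1\t100\t.\t+\t.\tID=e1;Parent=missing"),
             orphan)
  expect_error(read_gene_models(orphan), class = "zf_format_error")

  overlap <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tmRNA\t1\t300\t.\t+\t.\tID=m1",
    "chr1\tt\texon\t1\t100\t.\t+\t.\tID=e1;Parent=m1",
    "chr1\tt\texon\t50\t200\t.\t+\t.\tID=e2;Parent=m1"
  ), overlap)
  expect_error(read_gene_models(overlap), class = "zf_format_error")

  malformed <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("chr1\tonly\tthree"), malformed)
  expect_error(read_gene_models(malformed), class = "zf_format_error")
})
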