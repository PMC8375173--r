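toy_tpm <- function(values, samples = stage_organs()$stage) {
  m <- matrix(values, ncol = length(samples),
              dimnames = list(NULL, samples))
  dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%02d", seq_len(nrow(m)))),
    tibble::as_tibble(m)
  )
}

test_that("log2 transform uses a +1 pseudocount and rejects negatives", {
  tpm <- toy_tpm(rep(c(0, 1, 3), each = 15) |> matrix(nrow = 3, byrow = TRUE))
  lg <- log2_tpm(tpm)
  expect_equal(unname(unlist(lg[1, -1])), rep(0, 15))
  expect_equal(unname(unlist(lg[2, -1])), rep(1, 15))
  expect_equal(unname(unlist(lg[3, -1])), rep(2, 15))
  bad <- tpm; bad$SR[1] <- -1
  expect_error(log2_tpm(bad), class = "zf_expression_error")
})

test_that("expressed filter is boundary-inclusive and monotone in min_tpm", {
  vals <- rbind(rep(0, 15),                 # all-zero gene: removed
                c(0.5, rep(0, 14)),          # exactly at threshold: kept
                c(0.49, rep(0, 14)),         # just below: removed
                rep(2, 15))
  tpm <- toy_tpm(vals)
  kept <- filter_expressed(tpm)
  expect_equal(kept$gene_id, c("g02", "g04"))
  for (thr in c(0.1, 0.5, 1, 3)) {
    lo <- filter_expressed(tpm, min_tpm = thr)
    hi <- filter_expressed(tpm, min_tpm = thr + 0.5)
    expect_true(all(hi$gene_id %in% lo$gene_id))
  }
})

test_that("widely separated constant levels cluster into ordered singletons", {
  tpm <- toy_tpm(matrix(rep(2^c(0.5, 3, 6, 9, 12) - 1, 15), nrow = 5))
  cl <- cluster_expression(tpm, k = 5)
  expect_equal(tidy(cl)$group, 1:5)
  expect_true(all(diff(cl$group_means$mean_log2) > 0))
})

test_that("duplicate profiles land in the same group", {
  vals <- rbind(rep(1, 15), rep(1, 15), rep(100, 15), rep(1000, 15),
                rep(4000, 15), rep(16000, 15))
  cl <- cluster_expression(toy_tpm(vals), k = 5)
  g <- tidy(cl)$group
  expect_equal(g[1], g[2])
})

test_that("clustering needs at least k genes", {
  expect_error(cluster_expression(toy_tpm(matrix(1:30, nrow = 2)), k = 5),
               class = "zf_expression_error")
})

test_that("group labels are stable under gene-order permutation", {
  sim <- simulate_expression(c(4, 5, 6), sigma = 0.2, seed = 9)
  cl <- cluster_expression(sim$tpm, k = 3)
  set.seed(1)
  perm <- sample(nrow(sim$tpm))
  cl2 <- cluster_expression(sim$tpm[perm, ], k = 3)
  merged <- dplyr::inner_join(tidy(cl), tidy(cl2), by = "gene_id")
  expect_equal(merged$group.x, merged$group.y)
})

test_that("organ-level calls split low/moderate/high at the cutoffs", {
  # constant per-organ profiles at log2 0.2 / 3 / 7
  vals <- 2^rbind(rep(0.2, 15), rep(3, 15), rep(7, 15)) - 1
  lv <- categorize_levels(toy_tpm(vals))
  expect_equal(unique(lv$level[lv$gene_id == "g01"]), "low")
  expect_equal(unique(lv$level[lv$gene_id == "g02"]), "moderate")
  expect_equal(unique(lv$level[lv$gene_id == "g03"]), "high")
  expect_setequal(unique(lv$organ),
                  c("root", "stem", "leaf", "spike", "grain"))
})

test_that("unknown stage codes are rejected for organ mapping", {
  tpm <- toy_tpm(matrix(1, ncol = 2, nrow = 1), samples = c("SR", "XXX"))
  expect_error(categorize_levels(tpm), class = "zf_expression_error")
})

test_that("2^-ddCt identities hold", {
  r <- fold_change_ddct(24, 20, 26, 20)
  expect_equal(r$ddct, -2)
  expect_equal(r$fold_change, 4)
  expect_equal(fold_change_ddct(25, 20, 30, 25)$fold_change, 1)
  expect_equal(fold_change_ddct(21, 20, 20, 20)$fold_change, 0.5)
  # ddct = 0 <-> fold = 1 for any CT combination with equal deltas
  for (a in c(18, 25, 33)) {
    for (b in c(15, 22)) {
      expect_equal(fold_change_ddct(a, b, a, b)$fold_change, 1)
    }
  }
  expect_error(fold_change_ddct(-1, 20, 20, 20),
               class = "zf_expression_error")
})

test_that("TPM matrices round-trip through TSV and long format", {
  tpm <- toy_tpm(matrix(runif(30), nrow = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tpm, path)
  back <- read_tpm_matrix(path)
  expect_equal(as.data.frame(back), as.data.frame(tpm), tolerance = 1e-12)
  long <- tpm_long(tpm, log2 = FALSE)
  expect_equal(nrow(long), 30L)
  expect_equal(long$value[long$gene_id == "g01" & long$stage == "SR"],
               tpm$SR[1])
})
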