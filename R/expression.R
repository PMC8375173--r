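# Expression-side analyses: log2 TPM transform, expressed-gene filtering,
# five-group clustering, organ-level calls and 2^-ddCt quantification.

#' The 15 canonical developmental-stage codes and their organs
#'
#' Wheat expression surveys use 15 stage codes across 5 organs: roots (SR,
#' RTLS, RMS), stems (S1S, STNS, SATS), leaves (SL, LTTS, L2DAAs), spikes
#' (SPTNS, SPMS, SPAS) and grains (G2DAAs, G14DAAs, G30DAAs).
#'
#' @return Tibble with columns `stage` and `organ`.
#' @export
stage_organs <- function() {
  tibble::tibble(
    stage = c("SR", "RTLS", "RMS", "S1S", "STNS", "SATS",
              "SL", "LTTS", "L2DAAs", "SPTNS", "SPMS", "SPAS",
              "G2DAAs", "G14DAAs", "G30DAAs"),
    organ = rep(c("root", "stem", "leaf", "spike", "grain"), each = 3)
  )
}

tpm_values <- function(tpm) {
  stopifnot("gene_id" %in% names(tpm))
  m <- as.matrix(tpm[, setdiff(names(tpm), "gene_id"), drop = FALSE])
  if (any(m < 0, na.rm = TRUE)) {
    abort_zf("TPM values must be non-negative", "zf_expression_error")
  }
  rownames(m) <- tpm$gene_id
  m
}

#' Log-transform a TPM matrix
#'
#' `value -> log2(value + 1)`; the pseudocount keeps zero TPM at zero on
#' the log scale.
#'
#' @param tpm Tibble with a `gene_id` column and one numeric column per
#'   sample.
#' @return Tibble of the same shape on the log2 scale.
#' @export
log2_tpm <- function(tpm) {
  m <- log2(tpm_values(tpm) + 1)
  dplyr::bind_cols(tibble::tibble(gene_id = tpm$gene_id),
                   tibble::as_tibble(m))
}

#' Filter to expressed genes
#'
#' A gene counts as expressed when its TPM reaches `min_tpm` in at least
#' `min_samples` samples (boundary inclusive).
#'
#' @param tpm TPM tibble (`gene_id` + sample columns).
#' @param min_tpm Minimum TPM; default 0.5.
#' @param min_samples Minimum number of samples at or above it; default 1.
#' @return The expressed subset of `tpm`, original order preserved.
#' @export
filter_expressed <- function(tpm, min_tpm = 0.5, min_samples = 1) {
  m <- tpm_values(tpm)
  keep <- rowSums(m >= min_tpm) >= min_samples
  tpm[keep, , drop = FALSE]
}

#' Cluster expression profiles into ordered groups
#'
#' Agglomerative hierarchical clustering (average linkage, Euclidean
#' distance) of each gene's log2(TPM + 1) profile, cut into `k` groups.
#' Groups are relabelled 1..k by ascending mean log2 expression (ties
#' broken by the first gene id in input order), so group 1 is always the
#' lowest-expressed cluster. Deterministic given the input.
#'
#' @param tpm TPM tibble (`gene_id` + sample columns).
#' @param k Number of groups; default 5.
#' @return An `expression_clusters` object: list with `assignments`
#'   (tibble `gene_id`, `group`), `group_means` (tibble `group`,
#'   `mean_log2`, `n`), `hclust` (the dendrogram) and `k`. Use
#'   [generics::tidy()] / [generics::glance()] to extract tibbles.
#' @export
cluster_expression <- function(tpm, k = 5) {
  m <- log2(tpm_values(tpm) + 1)
  if (nrow(m) < k) {
    abort_zf(paste0("cannot form ", k, " groups from ", nrow(m), " genes"),
             "zf_expression_error")
  }
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "average")
  raw <- stats::cutree(hc, k = k)
  means <- tapply(rowMeans(m), raw, mean)
  first_seen <- tapply(seq_along(raw), raw, min)
  ord <- order(means, first_seen)
  relabel <- integer(k)
  relabel[as.integer(names(means))[ord]] <- seq_len(k)
  group <- relabel[raw]
  assignments <- tibble::tibble(gene_id = tpm$gene_id, group = group)
  group_means <- assignments |>
    dplyr::mutate(mean_log2 = rowMeans(m)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_log2 = mean(.data$mean_log2), n = dplyr::n(),
                     .groups = "drop")
  structure(list(assignments = assignments, group_means = group_means,
                 hclust = hc, k = k),
            class = "expression_clusters")
}

#' @export
print.expression_clusters <- function(x, ...) {
  cat("Expression clustering:", nrow(x$assignments), "genes in", x$k,
      "groups (ascending mean log2 TPM)\n")
  print(x$group_means)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.expression_clusters <- function(x, ...) x$assignments

#' @export
glance.expression_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, n_genes = nrow(x$assignments),
                 min_group = min(x$group_means$n),
                 max_group = max(x$group_means$n))
}

#' Call low/moderate/high expression per gene and organ
#'
#' Averages log2(TPM + 1) within each organ (stage codes mapped via
#' [stage_organs()]) and calls the level: low when the mean is at most
#' `low_max`, high when at least `high_min`, moderate in between.
#'
#' @param tpm TPM tibble whose sample columns are the 15 canonical stage
#'   codes (unknown codes are an error).
#' @param low_max,high_min Level cutoffs on the log2 scale; defaults 1 and 5.
#' @return Long tibble: `gene_id`, `organ`, `mean_log2`, `level`.
#' @export
categorize_levels <- function(tpm, low_max = 1.0, high_min = 5.0) {
  samples <- setdiff(names(tpm), "gene_id")
  map <- stage_organs()
  unknown <- setdiff(samples, map$stage)
  if (length(unknown) > 0) {
    abort_zf(paste0("unknown stage code: ", unknown[1]),
             "zf_expression_error")
  }
  log2_tpm(tpm) |>
    tidyr::pivot_longer(-"gene_id", names_to = "stage",
                        values_to = "log2_tpm") |>
    dplyr::inner_join(map, by = "stage") |>
    dplyr::group_by(.data$gene_id, .data$organ) |>
    dplyr::summarise(mean_log2 = mean(.data$log2_tpm), .groups = "drop") |>
    dplyr::mutate(level = dplyr::case_when(
      .data$mean_log2 <= low_max ~ "low",
      .data$mean_log2 >= high_min ~ "high",
      TRUE ~ "moderate"
    ))
}

#' Relative qPCR quantification by the comparative 2^-ddCt method
#'
#' `ddct = (CT_target - CT_reference)_treated - (CT_target -
#' CT_reference)_control`; the fold change of the target in treated vs
#' control samples is `2^-ddct`.
#'
#' @param ct_target_treated,ct_ref_treated CT values in the treated sample.
#' @param ct_target_control,ct_ref_control CT values in the control sample.
#' @return Tibble: `delta_ct_treated`, `delta_ct_control`, `ddct`,
#'   `fold_change`.
#' @examples
#' fold_change_ddct(24, 20, 26, 20) # fold_change = 4
#' @export
fold_change_ddct <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated,
           ct_target_control, ct_ref_control)
  if (any(!is.finite(cts)) || any(cts <= 0)) {
    abort_zf("CT values must be finite and positive", "zf_expression_error")
  }
  dt <- ct_target_treated - ct_ref_treated
  dc <- ct_target_control - ct_ref_control
  ddct <- dt - dc
  tibble::tibble(delta_ct_treated = dt, delta_ct_control = dc,
                 ddct = ddct, fold_change = 2^(-ddct))
}

#' Read a TPM matrix from TSV
#'
#' Genes in rows; the first column (`gene_id` or unnamed) holds gene ids,
#' remaining columns are samples.
#'
#' @param path TSV path with one header row.
#' @return TPM tibble.
#' @export
read_tpm_matrix <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  names(tbl)[1] <- "gene_id"
  tpm_values(tbl) # validates
  tbl
}

#' Long-format export of a TPM matrix (heatmap-ready)
#'
#' @param tpm TPM tibble.
#' @param log2 Transform values to log2(TPM + 1); default TRUE.
#' @return Long tibble `gene_id`, `stage`, `value`.
#' @export
tpm_long <- function(tpm, log2 = TRUE) {
  tbl <- if (log2) log2_tpm(tpm) else tpm
  tidyr::pivot_longer(tbl, -"gene_id", names_to = "stage",
                      values_to = "value")
}
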