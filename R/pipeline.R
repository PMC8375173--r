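#' Run the full C2H2-ZF family survey
#'
#' Orchestrates the pipeline: read proteome, scan and type fingers,
#' classify architectures and subsets, locate accessory boxes, summarise
#' the family, and — when the inputs are given — count introns, estimate
#' Ka/Ks with divergence times, and run the expression analyses
#' (expressed-gene filter, five-group clustering, organ-level calls).
#'
#' @param protein_fasta Path to the proteome FASTA (required).
#' @param gff3 Optional gene-model GFF3 for intron counting.
#' @param tpm Optional TPM matrix TSV (genes x stage codes).
#' @param cds_pairs Optional aligned CDS pairs (FASTA or TSV, see
#'   [read_codon_pairs()]).
#' @param out_dir Optional output directory; when given, every table is
#'   written as TSV and a `MANIFEST` file records completed stages.
#' @param params [scan_params()] overrides.
#' @param motif_lib Motif library tibble; default [motif_library()].
#' @param min_tpm,min_samples Expressed-gene filter thresholds.
#' @param k Number of expression groups.
#' @param low_max,high_min Level-call cutoffs (log2 scale).
#' @param neutral_band,lambda Ka/Ks selection band and clock rate.
#' @return A `zf_survey` list: `proteins`, `domains`, `assignments`,
#'   `summary` (a `family_summary`), `divergent_variants`, `motifs`, and
#'   when computed `introns`, `kaks`, `expression` (list: `expressed`,
#'   `clusters`, `levels`).
#' @export
run_survey <- function(protein_fasta, gff3 = NULL, tpm = NULL,
                       cds_pairs = NULL, out_dir = NULL,
                       params = scan_params(), motif_lib = motif_library(),
                       min_tpm = 0.5, min_samples = 1, k = 5,
                       low_max = 1.0, high_min = 5.0,
                       neutral_band = 0.05, lambda = 6.5e-9) {
  manifest_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest_path <- file.path(out_dir, "MANIFEST")
    unlink(manifest_path)
  }
  note <- function(stage) {
    if (!is.null(manifest_path)) {
      cat(stage, "\n", file = manifest_path, append = TRUE, sep = "")
    }
  }
  out <- function(name, tbl) {
    if (!is.null(out_dir)) {
      readr::write_tsv(tbl, file.path(out_dir, paste0(name, ".tsv")))
    }
  }

  proteins <- read_protein_fasta(protein_fasta)
  note("read_proteins")
  domains <- scan_domains(proteins, params)
  out("domains", domains)
  note("scan")
  assignments <- assign_subsets(domains)
  out("proteins_classified",
      dplyr::left_join(assignments,
                       proteins |> dplyr::select("id", "gene_id", "variant"),
                       by = c(protein_id = "id")))
  note("classify")
  loci <- parse_gene_id(proteins$id)
  dedup <- dedupe_variants(assignments, proteins)
  out("divergent_variants", dedup$divergent)

  introns <- NULL
  if (!is.null(gff3)) {
    introns <- count_introns(read_gene_models(gff3))
    out("introns", introns)
    note("introns")
  }
  summary <- summarize_family(assignments, loci, introns)
  out("summary_subsets", summary$subsets)
  out("summary_arrangement", summary$arrangement)
  if (!is.null(summary$chromosomes)) {
    out("summary_chromosomes", summary$chromosomes)
    out("summary_subgenomes", summary$subgenomes)
    out("summary_arms", summary$arms)
  }
  note("summarize")

  motifs <- find_boxes(proteins, domains, motif_lib)
  out("motif_hits", motifs)
  note("motifs")

  kaks_tbl <- NULL
  if (!is.null(cds_pairs)) {
    kaks_tbl <- kaks(read_codon_pairs(cds_pairs),
                     neutral_band = neutral_band, lambda = lambda)
    out("kaks", kaks_tbl)
    note("kaks")
  }

  expression <- NULL
  if (!is.null(tpm)) {
    tpm_tbl <- if (is.data.frame(tpm)) tpm else read_tpm_matrix(tpm)
    expressed <- filter_expressed(tpm_tbl, min_tpm, min_samples)
    clusters <- cluster_expression(expressed, k = k)
    levels <- categorize_levels(expressed, low_max, high_min)
    out("expression_groups", tidy(clusters))
    out("expression_levels", levels)
    expression <- list(expressed = expressed, clusters = clusters,
                       levels = levels)
    note("expression")
  }

  note("done")
  structure(
    list(proteins = proteins, domains = domains, assignments = assignments,
         summary = summary, divergent_variants = dedup$divergent,
         motifs = motifs, introns = introns, kaks = kaks_tbl,
         expression = expression),
    class = "zf_survey"
  )
}

#' @export
print.zf_survey <- function(x, ...) {
  cat("C2H2-ZF survey of", nrow(x$proteins), "proteins;",
      nrow(x$domains), "fingers detected\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.zf_survey <- function(x, ...) {
  dplyr::left_join(
    x$assignments,
    x$proteins |> dplyr::select("id", "gene_id", "variant"),
    by = c(protein_id = "id")
  )
}

#' @export
glance.zf_survey <- function(x, ...) {
  arr <- x$summary$arrangement
  tibble::tibble(
    n_proteins = nrow(x$proteins),
    n_domains = nrow(x$domains),
    n_classified = nrow(x$assignments),
    n_tandem = sum(arr$n[arr$arrangement == "tandem"]),
    n_isolated = sum(arr$n[arr$arrangement == "isolated"]),
    n_genes = x$summary$n_genes,
    n_motif_hits = nrow(x$motifs)
  )
}

#' Read a flat key-value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Values are
#' auto-typed (TRUE/FALSE, numbers, strings).
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- stringr::str_match(lines, "^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$")
  if (any(is.na(kv[, 1]))) {
    abort_zf(paste0("malformed config line: ", lines[is.na(kv[, 1])][1]),
             "zf_format_error")
  }
  vals <- lapply(trimws(kv[, 3]), function(v) {
    if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(toupper(v)))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  })
  stats::setNames(vals, kv[, 2])
}
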