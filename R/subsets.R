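#' Build per-protein domain architectures
#'
#' Orders each protein's fingers along the sequence and computes the
#' inter-finger gaps (residues strictly between one domain's end and the
#' next domain's start) that drive the tandem/isolated classification.
#'
#' @param domains Domain tibble from [scan_domains()].
#' @return Tibble with one row per finger: `protein_id`, `index`, `start`,
#'   `end`, `dtype`, `gap_next` (residues to the next finger, `NA` for the
#'   last one).
#' @export
build_architecture <- function(domains) {
  if (nrow(domains) == 0) {
    return(tibble::tibble(protein_id = character(), index = integer(),
                          start = integer(), end = integer(),
                          dtype = character(), gap_next = integer()))
  }
  arch <- domains |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(
      index = dplyr::row_number(),
      gap_next = dplyr::lead(.data$start) - .data$end - 1L
    ) |>
    dplyr::ungroup()
  if (any(arch$gap_next < 0, na.rm = TRUE)) {
    bad <- arch$protein_id[which(arch$gap_next < 0)][1]
    abort_zf(paste0("overlapping domains in protein ", bad),
             "zf_architecture_error")
  }
  arch |>
    dplyr::select("protein_id", "index", "start", "end", "dtype", "gap_next")
}

# Collapse M1..M4 -> M and Z1/Z2 -> Z (subset labels use collapsed types).
collapse_type <- function(dtype) {
  dplyr::case_when(
    stringr::str_starts(dtype, "M") ~ "M",
    stringr::str_starts(dtype, "Z") ~ "Z",
    TRUE ~ dtype
  )
}

#' Classify protein domain arrangements and assign family subsets
#'
#' Two adjacent fingers are *linked* when separated by fewer than 12
#' residues (gap <= 11); maximal runs of linked fingers form tandem arrays.
#' A protein is **tandem** when at least one array holds two or more fingers
#' and **isolated** otherwise (fingers dispersed by > 11 residues, or a
#' single finger).
#'
#' Subsets follow the naming used for plant C2H2 families (`Ta-` prefix for
#' Triticum aestivum): tandem proteins split into `Ta-t1-SF` (one tandem
#' array covering every finger) and `Ta-t2-SF` (several arrays, or an array
#' plus dispersed fingers); isolated proteins split by finger count and
#' collapsed type into `Ta-1i-{Q,M,Z,D}-SF`, `Ta-2i-{Q,M,Z}-SF` /
#' `Ta-2i-Mix-SF`, `Ta-3i-SF` and `Ta-4i-SF` (proteins with five or more
#' dispersed fingers are binned into `Ta-4i-SF`).
#'
#' @param domains Domain tibble from [scan_domains()] (only proteins with at
#'   least one finger appear in the result).
#' @param max_linker Largest gap (residues) still linking two fingers into a
#'   tandem array; default 11.
#' @param prefix Species prefix for subset labels; default `"Ta"`.
#' @return Tibble with one row per protein: `protein_id`, `n_domains`,
#'   `type_string` (semicolon-joined finger types, N- to C-terminal),
#'   `n_arrays` (tandem arrays of size >= 2), `arrangement`
#'   (`"tandem"`/`"isolated"`) and `subset`.
#' @examples
#' doms <- scan_domains(simulate_protein(c("Q", "Q"), gaps = 5, seed = 1))
#' assign_subsets(doms)
#' @export
assign_subsets <- function(domains, max_linker = 11, prefix = "Ta") {
  arch <- build_architecture(domains)
  if (nrow(arch) == 0) {
    return(tibble::tibble(protein_id = character(), n_domains = integer(),
                          type_string = character(), n_arrays = integer(),
                          arrangement = character(), subset = character()))
  }
  arch |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      n_domains = dplyr::n(),
      type_string = paste(.data$dtype, collapse = ";"),
      n_arrays = n_tandem_arrays(.data$gap_next, max_linker),
      n_in_arrays = n_domains_in_arrays(.data$gap_next, max_linker),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      arrangement = ifelse(.data$n_arrays >= 1L, "tandem", "isolated"),
      subset = subset_label(.data$arrangement, .data$n_domains,
                            .data$n_arrays, .data$n_in_arrays,
                            .data$type_string, prefix)
    ) |>
    dplyr::select(-"n_in_arrays")
}

# Number of maximal runs of linked fingers with >= 2 members.
n_tandem_arrays <- function(gap_next, max_linker) {
  linked <- !is.na(gap_next) & gap_next <= max_linker
  r <- rle(linked)
  sum(r$values)
}

# Number of fingers belonging to some tandem array.
n_domains_in_arrays <- function(gap_next, max_linker) {
  linked <- !is.na(gap_next) & gap_next <= max_linker
  r <- rle(linked)
  sum(r$lengths[r$values] + 1L)
}

subset_label <- function(arrangement, n_domains, n_arrays, n_in_arrays,
                         type_string, prefix) {
  types <- strsplit(type_string, ";", fixed = TRUE)
  collapsed <- purrr::map(types, collapse_type)
  purrr::pmap_chr(
    list(arrangement, n_domains, n_arrays, n_in_arrays, collapsed),
    function(arr, nd, na, nia, cty) {
      if (arr == "tandem") {
        if (na == 1L && nia == nd) paste0(prefix, "-t1-SF")
        else paste0(prefix, "-t2-SF")
      } else if (nd == 1L) {
        paste0(prefix, "-1i-", cty[1], "-SF")
      } else if (nd == 2L) {
        if (cty[1] == cty[2] && cty[1] %in% c("Q", "M", "Z")) {
          paste0(prefix, "-2i-", cty[1], "-SF")
        } else {
          paste0(prefix, "-2i-Mix-SF")
        }
      } else if (nd == 3L) {
        paste0(prefix, "-3i-SF")
      } else {
        paste0(prefix, "-4i-SF")
      }
    }
  )
}

#' Pick one representative per gene and flag architecture-divergent variants
#'
#' Splice variants of one gene may drop or change fingers (the
#' `Traes_6DL_F47CFC6D9` series runs from five fingers down to two). The
#' representative is the lowest splice index; genes whose variants disagree
#' in `type_string` are flagged.
#'
#' @param assignments Output of [assign_subsets()], one row per protein.
#' @param proteins Protein tibble with `id`, `gene_id`, `variant` columns.
#' @return List with `representatives` (assignments restricted to each
#'   gene's representative protein, plus `gene_id`) and `divergent` (tibble
#'   of genes whose variants differ in architecture, with the distinct type
#'   strings observed).
#' @export
dedupe_variants <- function(assignments, proteins) {
  joined <- assignments |>
    dplyr::inner_join(proteins |> dplyr::select("id", "gene_id", "variant"),
                      by = c(protein_id = "id")) |>
    dplyr::mutate(variant = dplyr::coalesce(.data$variant, 1L))
  reps <- joined |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice_min(.data$variant, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  divergent <- joined |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_variants = dplyr::n(),
      type_strings = paste(sort(unique(.data$type_string)), collapse = " | "),
      divergent = dplyr::n_distinct(.data$type_string) > 1L,
      .groups = "drop"
    ) |>
    dplyr::filter(.data$divergent) |>
    dplyr::select(-"divergent")
  list(representatives = reps, divergent = divergent)
}

#' Count introns of gene models
#'
#' @param gene_models Exon tibble from [read_gene_models()].
#' @return Tibble `gene_id`, `mrna_id`, `n_introns` (= exons - 1).
#' @export
count_introns <- function(gene_models) {
  if (nrow(gene_models) == 0) {
    return(tibble::tibble(gene_id = character(), mrna_id = character(),
                          n_introns = integer()))
  }
  gene_models |>
    dplyr::group_by(.data$gene_id, .data$mrna_id) |>
    dplyr::summarise(n_introns = dplyr::n() - 1L, .groups = "drop")
}

#' Family-level summary tables
#'
#' Tallies the classified family the way genome-wide C2H2 surveys report it:
#' per-subset protein counts, tandem/isolated counts with percentages,
#' per-chromosome / sub-genome / arm gene counts, and the intron histogram.
#' Protein-level percentages use the number of classified proteins as
#' denominator; gene-level percentages use the number of genes with a valid
#' locus. Chromosome and arrangement percentages are printed at one decimal,
#' sub-genome and arm percentages at two (the conventions of the source
#' tables); exact fractions are carried alongside.
#'
#' @param assignments Output of [assign_subsets()].
#' @param loci Optional tibble from [parse_gene_id()] on the protein ids
#'   (rows with `valid = FALSE` are skipped in locus tables).
#' @param introns Optional tibble from [count_introns()].
#' @return A `family_summary` list of tibbles: `arrangement`, `subsets`,
#'   `chromosomes`, `subgenomes`, `arms`, `introns`, plus counts
#'   `n_proteins`, `n_genes`, `n_skipped_loci`.
#' @export
summarize_family <- function(assignments, loci = NULL, introns = NULL) {
  n_prot <- nrow(assignments)
  arrangement <- assignments |>
    dplyr::count(.data$arrangement, name = "n") |>
    dplyr::mutate(fraction = .data$n / n_prot,
                  percent = pct(.data$n, n_prot, 1))
  subsets <- assignments |>
    dplyr::count(.data$subset, name = "n") |>
    dplyr::mutate(fraction = .data$n / n_prot,
                  percent = pct(.data$n, n_prot, 1))

  chromosomes <- subgenomes <- arms <- NULL
  n_genes <- NA_integer_
  n_skipped <- 0L
  if (!is.null(loci)) {
    genes <- loci |>
      dplyr::distinct(.data$gene_id, .keep_all = TRUE)
    n_skipped <- sum(!genes$valid)
    genes <- genes |> dplyr::filter(.data$valid)
    n_genes <- nrow(genes)
    chromosomes <- genes |>
      dplyr::count(.data$chromosome, name = "n") |>
      dplyr::mutate(fraction = .data$n / n_genes,
                    percent = pct(.data$n, n_genes, 1))
    subgenomes <- genes |>
      dplyr::count(.data$subgenome, name = "n") |>
      dplyr::mutate(fraction = .data$n / n_genes,
                    percent = pct(.data$n, n_genes, 2))
    arms <- genes |>
      dplyr::count(.data$arm, name = "n") |>
      dplyr::mutate(fraction = .data$n / n_genes,
                    percent = pct(.data$n, n_genes, 2))
  }

  intron_hist <- NULL
  if (!is.null(introns)) {
    intron_hist <- introns |>
      dplyr::count(.data$n_introns, name = "n") |>
      dplyr::arrange(.data$n_introns)
  }

  structure(
    list(arrangement = arrangement, subsets = subsets,
         chromosomes = chromosomes, subgenomes = subgenomes, arms = arms,
         introns = intron_hist,
         n_proteins = n_prot, n_genes = n_genes, n_skipped_loci = n_skipped),
    class = "family_summary"
  )
}

#' @export
print.family_summary <- function(x, ...) {
  cat("C2H2-ZF family summary:", x$n_proteins, "proteins",
      if (!is.na(x$n_genes)) paste0("over ", x$n_genes, " genes"), "\n")
  td <- x$arrangement$n[x$arrangement$arrangement == "tandem"] %||% 0L
  iso <- x$arrangement$n[x$arrangement$arrangement == "isolated"] %||% 0L
  tdp <- x$arrangement$percent[x$arrangement$arrangement == "tandem"] %||% 0
  isop <- x$arrangement$percent[x$arrangement$arrangement == "isolated"] %||% 0
  cat("  tandem: ", td, " (", tdp, "%), isolated: ", iso,
      " (", isop, "%)\n", sep = "")
  cat("  subsets:\n")
  print(x$subsets, n = Inf)
  invisible(x)
}
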