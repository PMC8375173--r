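#' Read a protein FASTA into a tibble
#'
#' Reads protein sequences and normalises them for downstream scanning:
#' sequences are uppercased, terminal `*` stop symbols are stripped, and the
#' splice-variant suffix (a trailing `.<n>` on the record id, as in
#' `Traes_5BL_D53A846BE.1`) is split off into `gene_id` / `variant` columns.
#'
#' Only the 20 standard amino-acid letters plus `X` are accepted. `X` is
#' tolerated as an unknown residue but can never match a zinc-ligand position
#' (C/H) or a QALGGH position during scanning, so ligand identity stays
#' certain. Other ambiguity letters (B, J, O, U, Z) are rejected at read time.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @return A tibble with columns `id`, `sequence`, `gene_id`, `variant`
#'   (integer, `NA` when the id carries no splice suffix).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">p1.1", "mkcaecgkafsqkqalgghlrshirt*"), fa)
#' read_protein_fasta(fa)
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) {
    abort_zf(paste0("FASTA file not found: ", path), "zf_io_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort_zf(paste0("not a readable FASTA file: ", path),
                                 "zf_format_error")
  )
  if (length(set) == 0) {
    abort_zf(paste0("empty FASTA file: ", path), "zf_format_error")
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- unname(toupper(as.character(set)))
  # strip terminal stop symbols, then validate the alphabet
  seqs <- sub("\\*+$", "", seqs)
  as_protein_tbl(ids, seqs)
}

# Shared constructor/validator for protein tibbles.
as_protein_tbl <- function(ids, seqs) {
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    abort_zf(paste0("duplicate sequence id: ", dup), "zf_format_error")
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort_zf(paste0("empty sequence for id: ", ids[empty][1]),
             "zf_format_error")
  }
  bad <- stringr::str_detect(seqs, "[^ACDEFGHIKLMNPQRSTVWYX]")
  if (any(bad)) {
    abort_zf(
      paste0("sequence for id ", ids[bad][1],
             " contains letters outside the 20 standard amino acids + X"),
      "zf_format_error"
    )
  }
  tibble::tibble(
    id = ids,
    sequence = seqs,
    gene_id = sub("\\.[0-9]+$", "", ids),
    variant = suppressWarnings(
      as.integer(stringr::str_match(ids, "\\.([0-9]+)$")[, 2])
    )
  )
}

#' Write a protein tibble to FASTA
#'
#' @param proteins A tibble with `id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  set <- Biostrings::BStringSet(proteins$sequence)
  names(set) <- proteins$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Parse wheat gene identifiers into genomic coordinates metadata
#'
#' Bread-wheat gene ids of the dialect `Traes_<chr><subgenome><arm>_<hash>.<n>`
#' (e.g. `Traes_5BL_D53A846BE.1`) encode the chromosome (1-7), sub-genome
#' (A/B/D of the hexaploid genome) and chromosome arm (S short / L long).
#' Ids in other dialects are kept with an unknown locus when
#' `strict = FALSE` (the default used by the survey pipeline), so the
#' classifier still works on arbitrary proteomes; chromosome summaries then
#' skip such genes.
#'
#' @param ids Character vector of protein or gene ids.
#' @param strict If `TRUE`, any id failing the dialect is an error.
#' @return Tibble with columns `id`, `gene_id`, `chromosome` (integer),
#'   `subgenome`, `arm`, `hash`, `variant`, `valid`.
#' @examples
#' parse_gene_id("Traes_5BL_D53A846BE.1")
#' @export
parse_gene_id <- function(ids, strict = FALSE) {
  m <- stringr::str_match(
    ids, "^Traes_([1-7])([ABD])([SL])_([A-Za-z0-9]+)(\\.([0-9]+))?$"
  )
  valid <- !is.na(m[, 1])
  if (strict && any(!valid)) {
    abort_zf(paste0("id does not match the Traes_<chr><sub><arm>_<hash> ",
                    "dialect: ", ids[!valid][1]),
             "zf_parse_error")
  }
  tibble::tibble(
    id = ids,
    gene_id = sub("\\.[0-9]+$", "", ids),
    chromosome = as.integer(m[, 2]),
    subgenome = m[, 3],
    arm = m[, 4],
    hash = m[, 5],
    variant = suppressWarnings(as.integer(m[, 7])),
    valid = valid
  )
}

#' Compose a wheat gene identifier from locus parts
#'
#' Inverse of [parse_gene_id()] on valid loci.
#'
#' @param chromosome Integer 1-7.
#' @param subgenome One of "A", "B", "D".
#' @param arm One of "S", "L".
#' @param hash Opaque alphanumeric gene hash.
#' @param variant Optional positive integer splice index.
#' @return Character vector of ids.
#' @export
compose_gene_id <- function(chromosome, subgenome, arm, hash, variant = NA) {
  stopifnot(all(chromosome %in% 1:7), all(subgenome %in% c("A", "B", "D")),
            all(arm %in% c("S", "L")))
  base <- paste0("Traes_", chromosome, subgenome, arm, "_", hash)
  variant <- rep(variant, length.out = length(base))
  ifelse(is.na(variant), base, paste0(base, ".", variant))
}

#' Read gene models (exon structures) from a GFF3 file
#'
#' Parses gene/mRNA/exon features and returns one row per exon, grouped by
#' mRNA and sorted by position. Coordinates are kept 1-based inclusive, the
#' GFF3 standard and the convention used throughout this package.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with columns `gene_id`, `mrna_id`, `start`, `end`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) {
    abort_zf(paste0("GFF3 file not found: ", path), "zf_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0) {
    return(tibble::tibble(gene_id = character(), mrna_id = character(),
                          start = integer(), end = integer()))
  }
  nfield <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (any(nfield != 9)) {
    abort_zf("malformed GFF3: expected 9 tab-separated columns",
             "zf_format_error")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  mrna <- gr[typ %in% c("mRNA", "transcript")]
  exons <- gr[typ == "exon"]
  mrna_parent <- vapply(mrna$Parent, function(p) p[1] %||% NA_character_, "")
  mrna_ids <- mrna$ID
  exon_parent <- vapply(exons$Parent, function(p) p[1] %||% NA_character_, "")
  if (any(is.na(exon_parent)) || !all(exon_parent %in% mrna_ids)) {
    abort_zf("exon feature without a parent mRNA", "zf_format_error")
  }
  out <- tibble::tibble(
    mrna_id = exon_parent,
    gene_id = unname(stats::setNames(mrna_parent, mrna_ids)[exon_parent]),
    start = as.integer(BiocGenerics::start(exons)),
    end = as.integer(BiocGenerics::end(exons))
  ) |>
    dplyr::arrange(.data$mrna_id, .data$start) |>
    dplyr::relocate("gene_id")
  bad <- out |>
    dplyr::group_by(.data$mrna_id) |>
    dplyr::filter(dplyr::row_number() > 1 &
                    .data$start <= dplyr::lag(.data$end)) |>
    dplyr::ungroup()
  if (nrow(bad) > 0) {
    abort_zf(paste0("overlapping exons in mRNA ", bad$mrna_id[1]),
             "zf_format_error")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
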