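# Synthetic-data generators with planted ground truth: proteins with known
# finger architectures, codon pairs with controlled divergence, expression
# matrices with planted groups, and a full family fixture whose composition
# mirrors the bread-wheat C2H2-ZF survey tallies.

# Filler alphabet: no C/H (so no spurious ligands), no F/L (so no spurious
# EAR-box matches in flanks and linkers).
FILLER <- c("A", "D", "E", "G", "I", "K", "M", "N", "P", "Q",
            "R", "S", "T", "V", "W", "Y")
# Replacement letters for degenerated QALGGH positions: disjoint from
# QALGGH itself and from the filler exclusions above.
DEGEN <- c("D", "E", "K", "N", "R", "S", "T", "V", "W", "Y")

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

filler <- function(n) {
  if (n == 0) return("")
  paste(sample(FILLER, n, replace = TRUE), collapse = "")
}

# One finger of the requested type; returns the sequence chunk plus the
# ligand offsets (1-based, relative to the chunk start).
build_domain <- function(dtype) {
  win5 <- strsplit("QALGG", "")[[1]]
  degen5 <- function(k) {
    idx <- sort(sample(5, k))
    for (i in idx) win5[i] <- sample(setdiff(DEGEN, win5[i]), 1)
    win5
  }
  if (dtype == "Q") {
    chunk <- paste0("C", filler(2), "C", filler(7), "QALGG", "H",
                    filler(3), "H")
    list(chunk = chunk, c1 = 1L, c2 = 4L, h1 = 17L, h2 = 21L)
  } else if (grepl("^M[1-5]$", dtype)) {
    k <- as.integer(substring(dtype, 2))
    w <- paste(degen5(k), collapse = "")
    chunk <- paste0("C", filler(2), "C", filler(7), w, "H", filler(3), "H")
    list(chunk = chunk, c1 = 1L, c2 = 4L, h1 = 17L, h2 = 21L)
  } else if (dtype == "Z1") {
    w <- paste(degen5(5), collapse = "")
    chunk <- paste0("C", filler(2), "C", filler(9), w, "H", filler(3), "H")
    list(chunk = chunk, c1 = 1L, c2 = 4L, h1 = 19L, h2 = 23L)
  } else if (dtype == "Z2") {
    w <- paste(degen5(5), collapse = "")
    chunk <- paste0("C", filler(2), "C", filler(4), w, "H", filler(3), "H")
    list(chunk = chunk, c1 = 1L, c2 = 4L, h1 = 14L, h2 = 18L)
  } else if (dtype == "D") {
    chunk <- paste0("C", filler(2), "C", filler(7), "QALGG", "H")
    list(chunk = chunk, c1 = 1L, c2 = 4L, h1 = 17L, h2 = NA_integer_)
  } else {
    abort_zf(paste0("unknown finger type: ", dtype), "zf_simulate_error")
  }
}

#' Simulate a protein with planted C2H2 fingers
#'
#' Builds a sequence whose scan + classify output equals the requested
#' architecture exactly: Q fingers use the canonical QALGGH template,
#' M-k fingers carry exactly k substitutions among the first five QALGGH
#' residues, Z1/Z2 fingers use fully degenerated windows at spacings 14 and
#' 9, and D fingers end at the motif histidine with no second ligand.
#' Filler residues avoid C and H (no spurious ligands) and F and L (no
#' spurious EAR-motif matches), so the scanner recovers the planted
#' architecture and nothing else.
#'
#' @param domain_types Character vector of finger types, N- to C-terminal
#'   (Q, M1-M4, Z1, Z2, D).
#' @param gaps Residue gaps between consecutive fingers (length one less
#'   than `domain_types`; recycled if scalar). Must be `>= 0`.
#' @param n_flank,c_flank Flank lengths before the first / after the last
#'   finger.
#' @param planted_boxes Optional tibble (`name`, `pattern`, `where`) of
#'   accessory boxes to embed, `where` one of `"n_flank"` / `"c_flank"`:
#'   the concrete pattern text (with `x` positions filled by `P`) replaces
#'   the center of that flank.
#' @param id Protein id for the output tibble.
#' @param seed Integer seed; fillers are deterministic given the seed.
#' @return One-row tibble (`id`, `sequence`) with attribute `truth`: a
#'   tibble of the planted fingers (`start`, `end`, ligand positions,
#'   `dtype`) and, when boxes were planted, attribute `truth_boxes`.
#' @examples
#' simulate_protein(c("Q", "M2"), gaps = 11, seed = 1)
#' @export
simulate_protein <- function(domain_types, gaps = integer(0), n_flank = 15,
                             c_flank = 15, planted_boxes = NULL,
                             id = "synthetic_protein", seed = NULL) {
  n_dom <- length(domain_types)
  stopifnot(n_dom >= 1)
  if (length(gaps) == 1 && n_dom > 2) gaps <- rep(gaps, n_dom - 1)
  if (n_dom == 1) gaps <- integer(0)
  if (length(gaps) != n_dom - 1) {
    abort_zf("gaps must have one entry per adjacent finger pair",
             "zf_simulate_error")
  }
  if (any(gaps < 0) || n_flank < 0 || c_flank < 0) {
    abort_zf("gaps and flanks must be non-negative", "zf_simulate_error")
  }
  with_local_seed(seed, {
    nf <- flank_with_boxes(n_flank, planted_boxes, "n_flank")
    cf <- flank_with_boxes(c_flank, planted_boxes, "c_flank")
    seq <- nf$text
    rows <- list()
    for (i in seq_len(n_dom)) {
      if (i > 1) seq <- paste0(seq, filler(gaps[i - 1]))
      d <- build_domain(domain_types[i])
      off <- nchar(seq)
      rows[[i]] <- tibble::tibble(
        start = off + d$c1, end = off + max(d$h2, d$h1, na.rm = TRUE),
        c1 = off + d$c1, c2 = off + d$c2, h1 = off + d$h1,
        h2 = off + d$h2, dtype = domain_types[i]
      )
      seq <- paste0(seq, d$chunk)
    }
    dom_end <- nchar(seq)
    seq <- paste0(seq, cf$text)
    truth <- dplyr::bind_rows(rows)
    out <- tibble::tibble(id = id, sequence = seq)
    attr(out, "truth") <- truth
    boxes <- dplyr::bind_rows(
      if (!is.null(nf$boxes)) nf$boxes,
      if (!is.null(cf$boxes)) {
        cf$boxes$start <- cf$boxes$start + dom_end
        cf$boxes$end <- cf$boxes$end + dom_end
        cf$boxes
      }
    )
    if (nrow(boxes %||% tibble::tibble()) > 0) attr(out, "truth_boxes") <- boxes
    out
  })
}

flank_with_boxes <- function(len, planted_boxes, where) {
  if (is.null(planted_boxes) || !any(planted_boxes$where == where)) {
    return(list(text = filler(len), boxes = NULL))
  }
  pb <- planted_boxes[planted_boxes$where == where, , drop = FALSE]
  texts <- gsub("x", "P", pb$pattern, fixed = TRUE)
  need <- sum(nchar(texts))
  pad <- max(len - need, 2 * nrow(pb))
  left <- pad %/% 2
  out <- filler(left)
  rows <- list()
  for (i in seq_len(nrow(pb))) {
    rows[[i]] <- tibble::tibble(name = pb$name[i],
                                start = nchar(out) + 1L,
                                end = nchar(out) + nchar(texts[i]))
    out <- paste0(out, texts[i], if (i < nrow(pb)) filler(2) else "")
  }
  out <- paste0(out, filler(pad - left))
  list(text = out, boxes = dplyr::bind_rows(rows))
}

#' Simulate an aligned codon pair with controlled divergence
#'
#' Draws a random stop-free coding sequence, then applies Poisson-
#' distributed synonymous and nonsynonymous single-base changes (one per
#' affected codon, never creating stops) calibrated so the Nei-Gojobori
#' estimates center on the requested `ks_target` / `ka_target`: the
#' expected change counts are the targets converted back through the
#' Jukes-Cantor correction and multiplied by the sequence's site counts.
#'
#' @param ks_target,ka_target Target synonymous / nonsynonymous rates
#'   (`>= 0`).
#' @param n_codons Number of codons (>= 10); default 300.
#' @param seed Integer seed.
#' @return List with `pair` (one-row tibble `id_a`, `id_b`, `cds_a`,
#'   `cds_b`) and `truth` (list: targets and the true applied change
#'   counts).
#' @export
simulate_codon_pair <- function(ks_target, ka_target, n_codons = 300,
                                seed = NULL) {
  stopifnot(ks_target >= 0, ka_target >= 0, n_codons >= 10)
  ps <- (3 / 4) * (1 - exp(-(4 / 3) * ks_target))
  pn <- (3 / 4) * (1 - exp(-(4 / 3) * ka_target))
  if (ps >= 3 / 4 || pn >= 3 / 4) {
    abort_zf("targets are beyond saturation", "zf_simulate_error")
  }
  code <- genetic_code()
  sense <- setdiff(names(code$aa), code$stops)
  with_local_seed(seed, {
    codons <- sample(sense, n_codons, replace = TRUE)
    cds_a <- paste(codons, collapse = "")
    sites <- count_sites(cds_a)
    n_syn <- stats::rpois(1, ps * sites[["S"]])
    n_non <- stats::rpois(1, pn * sites[["N"]])
    muts <- codon_mutations(codons, code)
    syn_ok <- which(lengths(muts$syn) > 0)
    non_ok <- which(lengths(muts$non) > 0)
    if (n_syn > length(syn_ok) || n_non + n_syn > n_codons) {
      abort_zf("targets unattainable at this length (saturation)",
               "zf_simulate_error")
    }
    target_syn <- sample(syn_ok, n_syn)
    non_pool <- setdiff(non_ok, target_syn)
    if (n_non > length(non_pool)) {
      abort_zf("targets unattainable at this length (saturation)",
               "zf_simulate_error")
    }
    target_non <- sample(non_pool, n_non)
    mutated <- codons
    for (i in target_syn) mutated[i] <- sample_one(muts$syn[[i]])
    for (i in target_non) mutated[i] <- sample_one(muts$non[[i]])
    list(
      pair = tibble::tibble(id_a = "ancestor", id_b = "derived",
                            cds_a = cds_a,
                            cds_b = paste(mutated, collapse = "")),
      truth = list(ks_target = ks_target, ka_target = ka_target,
                   n_syn_changes = n_syn, n_nonsyn_changes = n_non)
    )
  })
}

sample_one <- function(x) if (length(x) == 1) x else sample(x, 1)

# For each codon: the sense codons reachable by one base change, split into
# synonymous and nonsynonymous.
codon_mutations <- function(codons, code) {
  uniq <- unique(codons)
  syn_map <- list(); non_map <- list()
  for (cod in uniq) {
    chars <- strsplit(cod, "")[[1]]
    syn <- character(0); non <- character(0)
    for (pos in 1:3) {
      for (b in setdiff(BASES, chars[pos])) {
        m <- chars; m[pos] <- b
        mc <- paste(m, collapse = "")
        if (code$aa[[mc]] == "*") next
        if (code$aa[[mc]] == code$aa[[cod]]) syn <- c(syn, mc)
        else non <- c(non, mc)
      }
    }
    syn_map[[cod]] <- syn
    non_map[[cod]] <- non
  }
  list(syn = syn_map[codons], non = non_map[codons])
}

#' Simulate a TPM matrix with planted expression groups
#'
#' Each group's genes are its mean log2 profile plus Gaussian noise,
#' back-transformed to TPM (`2^x - 1`, clamped at zero).
#'
#' @param group_sizes Integer vector of genes per group.
#' @param group_profiles Numeric matrix, one row per group, one column per
#'   sample (log2 scale). Default: constant profiles at 0.5, 2, 3.5, ...
#'   (steps of 1.5) over the 15 canonical stages.
#' @param sigma Gaussian noise standard deviation on the log2 scale;
#'   default 0.3.
#' @param samples Sample (column) names.
#' @param seed Integer seed.
#' @return List with `tpm` (tibble) and `labels` (tibble `gene_id`,
#'   `group`).
#' @export
simulate_expression <- function(group_sizes, group_profiles = NULL,
                                sigma = 0.3,
                                samples = stage_organs()$stage,
                                seed = NULL) {
  k <- length(group_sizes)
  stopifnot(k >= 1, all(group_sizes >= 1))
  if (is.null(group_profiles)) {
    group_profiles <- matrix(0.5 + 1.5 * (seq_len(k) - 1),
                             nrow = k, ncol = length(samples))
  }
  stopifnot(nrow(group_profiles) == k,
            ncol(group_profiles) == length(samples))
  n <- sum(group_sizes)
  labels <- rep(seq_len(k), group_sizes)
  with_local_seed(seed, {
    log2m <- group_profiles[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * length(samples), sd = sigma), nrow = n)
    log2m[log2m < 0] <- 0
    tpm <- 2^log2m - 1
    colnames(tpm) <- samples
    ids <- sprintf("gene%03d", seq_len(n))
    list(
      tpm = dplyr::bind_cols(tibble::tibble(gene_id = ids),
                             tibble::as_tibble(tpm)),
      labels = tibble::tibble(gene_id = ids, group = labels)
    )
  })
}
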