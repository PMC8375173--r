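# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction, and the
# molecular-clock conversion of Ks to divergence time.

.zf_cache <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  list(aa = gc, stops = names(gc)[gc == "*"])
}

# Fractional synonymous sites of one codon: each of its 3 positions
# contributes (synonymous single-base changes at that position)/3.
# Changes producing a stop codon count as nonsynonymous.
codon_syn_sites <- function() {
  if (!is.null(.zf_cache$syn_sites)) return(.zf_cache$syn_sites)
  code <- genetic_code()
  codons <- names(code$aa)
  s <- vapply(codons, function(cod) {
    if (code$aa[[cod]] == "*") return(NA_real_)
    chars <- strsplit(cod, "")[[1]]
    tot <- 0
    for (pos in 1:3) {
      for (b in setdiff(BASES, chars[pos])) {
        mut <- chars
        mut[pos] <- b
        mutc <- paste(mut, collapse = "")
        if (code$aa[[mutc]] != "*" && code$aa[[mutc]] == code$aa[[cod]]) {
          tot <- tot + 1 / 3
        }
      }
    }
    tot
  }, numeric(1))
  .zf_cache$syn_sites <- s
  s
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n == 0 || n %% 3 != 0) {
    abort_zf("coding sequence length must be a positive multiple of 3",
             "zf_codon_error")
  }
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

#' Count synonymous and nonsynonymous sites of a coding sequence
#'
#' Nei-Gojobori site counting: each codon position contributes the fraction
#' of its three possible single-nucleotide changes that are synonymous to
#' `S`; `N = 3 x codons - S`. Changes creating a stop codon count as
#' nonsynonymous.
#'
#' @param cds Nucleotide string (A/C/G/T), length a multiple of 3, no stop
#'   codons.
#' @return Named numeric vector `c(S = ..., N = ...)`.
#' @examples
#' count_sites("TTT") # S = 1/3
#' @export
count_sites <- function(cds) {
  codons <- split_codons(toupper(cds))
  syn <- codon_syn_sites()
  vals <- syn[codons]
  if (anyNA(vals)) {
    bad <- codons[is.na(vals)][1]
    abort_zf(paste0("stop or invalid codon in coding sequence: ", bad),
             "zf_codon_error")
  }
  S <- sum(vals)
  c(S = S, N = 3 * length(codons) - S)
}

# Pathway-averaged (Sd, Nd) between two sense codons. All orderings of the
# differing positions are enumerated; pathways passing through a stop codon
# are excluded from the average. If every pathway hits a stop, the codon
# pair contributes its raw differences as nonsynonymous.
codon_diff <- function(ca, cb) {
  key <- paste0(ca, cb)
  if (!is.null(.zf_cache$diffs[[key]])) return(.zf_cache$diffs[[key]])
  code <- genetic_code()
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  d <- length(pos)
  res <- if (d == 0) {
    c(Sd = 0, Nd = 0)
  } else {
    perms <- permutations_of(pos)
    path_syn <- numeric(0)
    for (ord in perms) {
      cur <- a
      syn <- 0
      ok <- TRUE
      for (p in ord) {
        nxt <- cur
        nxt[p] <- b[p]
        aa1 <- code$aa[[paste(cur, collapse = "")]]
        aa2 <- code$aa[[paste(nxt, collapse = "")]]
        if (aa2 == "*") { ok <- FALSE; break }
        if (aa1 == aa2) syn <- syn + 1
        cur <- nxt
      }
      if (ok) path_syn <- c(path_syn, syn)
    }
    if (length(path_syn) == 0) {
      c(Sd = 0, Nd = d)
    } else {
      ms <- mean(path_syn)
      c(Sd = ms, Nd = d - ms)
    }
  }
  if (is.null(.zf_cache$diffs)) .zf_cache$diffs <- new.env(parent = emptyenv())
  .zf_cache$diffs[[key]] <- res
  res
}

permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

#' Count synonymous and nonsynonymous differences of an aligned codon pair
#'
#' @param cds_a,cds_b Aligned coding sequences of equal length (multiple
#'   of 3, gap columns already removed).
#' @return Named numeric vector `c(Sd = ..., Nd = ...)` (pathway-averaged).
#' @examples
#' count_differences("GAA", "GAG") # one synonymous difference
#' @export
count_differences <- function(cds_a, cds_b) {
  ca <- split_codons(toupper(cds_a))
  cb <- split_codons(toupper(cds_b))
  if (length(ca) != length(cb)) {
    abort_zf("aligned coding sequences differ in length", "zf_codon_error")
  }
  tot <- c(Sd = 0, Nd = 0)
  for (i in seq_along(ca)) tot <- tot + codon_diff(ca[i], cb[i])
  tot
}

# Drop aligned codon columns containing a gap in either sequence.
drop_gap_codons <- function(cds_a, cds_b) {
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  list(a = paste(ca[keep], collapse = ""), b = paste(cb[keep], collapse = ""))
}

#' Ka/Ks estimation for aligned coding-sequence pairs (Nei-Gojobori 1986)
#'
#' For each pair: synonymous/nonsynonymous site counts are averaged over the
#' two sequences, pathway-averaged difference counts give the proportions
#' `ps = Sd/S` and `pn = Nd/N`, and the Jukes-Cantor correction
#' `K = -(3/4) log(1 - (4/3) p)` yields `Ks` and `Ka`. `omega = Ka/Ks`
#' classifies selection: purifying (< 1), neutral (within `neutral_band` of
#' 1) or positive (> 1). Proportions at or beyond 3/4 are saturated and the
#' corresponding rate is undefined. `Ks` is also converted to a divergence
#' time in million years via [divergence_time()].
#'
#' Codon columns containing alignment gaps (`-`) are removed pairwise before
#' counting.
#'
#' @param pairs Tibble with columns `id_a`, `id_b`, `cds_a`, `cds_b` (see
#'   [read_codon_pairs()]), or two single sequences via `cds_a`/`cds_b`.
#' @param neutral_band Half-width of the omega band called neutral
#'   (exact omega = 1 is measure-zero); default 0.05.
#' @param lambda Clock rate for [divergence_time()].
#' @return Tibble with one row per pair: `id_a`, `id_b`, `n_codons`, `S`,
#'   `N`, `Sd`, `Nd`, `ps`, `pn`, `Ka`, `Ks`, `omega`, `saturated`,
#'   `selection`, `T_mya`.
#' @export
kaks <- function(pairs, neutral_band = 0.05, lambda = 6.5e-9) {
  if (is.character(pairs)) {
    abort_zf("pass a tibble with cds_a/cds_b columns (see read_codon_pairs)",
             "zf_codon_error")
  }
  stopifnot(all(c("cds_a", "cds_b") %in% names(pairs)))
  if (!"id_a" %in% names(pairs)) pairs$id_a <- paste0("a", seq_len(nrow(pairs)))
  if (!"id_b" %in% names(pairs)) pairs$id_b <- paste0("b", seq_len(nrow(pairs)))
  rows <- purrr::pmap(
    pairs[, c("id_a", "id_b", "cds_a", "cds_b")],
    function(id_a, id_b, cds_a, cds_b) {
      g <- drop_gap_codons(toupper(cds_a), toupper(cds_b))
      sa <- count_sites(g$a)
      sb <- count_sites(g$b)
      dd <- count_differences(g$a, g$b)
      S <- (sa[["S"]] + sb[["S"]]) / 2
      N <- (sa[["N"]] + sb[["N"]]) / 2
      ps <- dd[["Sd"]] / S
      pn <- dd[["Nd"]] / N
      Ks <- jc_correct(ps)
      Ka <- jc_correct(pn)
      omega <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
      tibble::tibble(
        id_a = id_a, id_b = id_b, n_codons = nchar(g$a) / 3,
        S = S, N = N, Sd = dd[["Sd"]], Nd = dd[["Nd"]],
        ps = ps, pn = pn, Ka = Ka, Ks = Ks, omega = omega,
        saturated = ps >= 3 / 4 | pn >= 3 / 4,
        selection = classify_selection(omega, neutral_band),
        T_mya = if (is.na(Ks)) NA_real_ else divergence_time(Ks, lambda)
      )
    }
  )
  dplyr::bind_rows(rows)
}

jc_correct <- function(p) {
  if (p >= 3 / 4) return(NA_real_)
  -(3 / 4) * log(1 - (4 / 3) * p)
}

classify_selection <- function(omega, neutral_band) {
  if (is.na(omega)) return(NA_character_)
  if (abs(omega - 1) <= neutral_band) "neutral"
  else if (omega > 1) "positive"
  else "purifying"
}

#' Divergence time from the synonymous substitution rate
#'
#' Molecular clock `T = Ks / (2 lambda x 10^6)` Mya, with
#' `lambda = 6.5e-9` synonymous substitutions per site per year (the rate
#' commonly used for grasses); `Ks = 0.013` corresponds to 1 Mya.
#'
#' @param ks Synonymous substitution rate(s), `>= 0`.
#' @param lambda Substitutions per synonymous site per year.
#' @return Divergence time(s) in million years.
#' @examples
#' divergence_time(0.26) # 20 Mya
#' @export
divergence_time <- function(ks, lambda = 6.5e-9) {
  if (any(ks < 0, na.rm = TRUE)) {
    abort_zf("Ks must be non-negative", "zf_codon_error")
  }
  ks / (2 * lambda * 1e6)
}

#' Read aligned coding-sequence pairs
#'
#' Accepts either a paired CDS FASTA (two consecutive records per pair) or
#' a 4-column TSV `id_a`, `id_b`, `cds_a`, `cds_b`.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"fasta"` or `"tsv"`.
#' @return Tibble with columns `id_a`, `id_b`, `cds_a`, `cds_b`.
#' @export
read_codon_pairs <- function(path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) {
      "fasta"
    } else {
      "tsv"
    }
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0 || length(set) %% 2 != 0) {
      abort_zf("paired CDS FASTA must hold an even, positive record count",
               "zf_format_error")
    }
    ids <- sub("\\s.*$", "", names(set))
    seqs <- toupper(as.character(set))
    odd <- seq(1, length(set), 2)
    tibble::tibble(id_a = ids[odd], id_b = ids[odd + 1],
                   cds_a = unname(seqs[odd]), cds_b = unname(seqs[odd + 1]))
  } else {
    tbl <- readr::read_tsv(path, show_col_types = FALSE)
    stopifnot(all(c("id_a", "id_b", "cds_a", "cds_b") %in% names(tbl)))
    tibble::as_tibble(tbl[, c("id_a", "id_b", "cds_a", "cds_b")])
  }
}
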