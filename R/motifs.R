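#' Default accessory-motif library
#'
#' Plant C2H2 zinc-finger proteins carry short accessory boxes outside the
#' fingers. The transcriptional-repression EAR motif family has concrete
#' consensus forms (`DLNxxP`, `LxLxL`, and EAR-like variants `LDLNL`,
#' `LDLSL`, `FDLNI`), shipped here as matchable degenerate patterns
#' (`x` = any residue). The subset-specific boxes first described from
#' sequence logos (NPL-, SFP1-, DL-, R-, PL-, L-, EK-box) have no published
#' consensus string; they ship pattern-less with their expected location
#' relative to the fingers, and accept user-supplied patterns (see
#' [read_motif_library()]).
#'
#' @return Tibble with columns `name`, `pattern` (`NA` for placeholder
#'   boxes) and `context`, one of `N-of-first-ZF`, `C-of-first-ZF`,
#'   `C-of-second-ZF`, `C-of-last-ZF`, `anywhere`.
#' @export
motif_library <- function() {
  tibble::tribble(
    ~name,          ~pattern,  ~context,
    "EAR-DLNxxP",   "DLNxxP",  "anywhere",
    "EAR-LxLxL",    "LxLxL",   "anywhere",
    "EAR-LDLNL",    "LDLNL",   "anywhere",
    "EAR-LDLSL",    "LDLSL",   "anywhere",
    "EAR-FDLNI",    "FDLNI",   "anywhere",
    "NPL-box",      NA,        "N-of-first-ZF",
    "L-box",        NA,        "N-of-first-ZF",
    "DL-box",       NA,        "C-of-first-ZF",
    "SFP1-box",     NA,        "C-of-first-ZF",
    "R-box",        NA,        "C-of-first-ZF",
    "PL-box",       NA,        "C-of-second-ZF",
    "EK-box",       NA,        "C-of-second-ZF"
  )
}

#' Read a motif library from a config table
#'
#' Two- or three-column whitespace/tab-separated table: `name`, `pattern`
#' and optionally `context` (defaults to `anywhere`). Patterns use uppercase
#' residue letters with `x` for any residue.
#'
#' @param path Path to the table (with a header row).
#' @return Tibble like [motif_library()].
#' @export
read_motif_library <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("name", "pattern") %in% names(tbl)))
  if (!"context" %in% names(tbl)) tbl$context <- "anywhere"
  validate_patterns(tbl$pattern)
  tibble::as_tibble(tbl[, c("name", "pattern", "context")])
}

validate_patterns <- function(patterns) {
  p <- patterns[!is.na(patterns)]
  bad <- nchar(p) < 3 | stringr::str_detect(p, "[^A-Zx]")
  if (any(bad)) {
    abort_zf(paste0("invalid motif pattern: ", p[bad][1]), "zf_motif_error")
  }
  invisible(patterns)
}

pattern_to_regex <- function(pattern) gsub("x", ".", pattern, fixed = TRUE)

#' Find accessory boxes and their position relative to the fingers
#'
#' Matches every concrete pattern of the library against each protein
#' (leftmost non-overlapping matches per pattern; different patterns may
#' overlap each other) and reports where each hit sits relative to the
#' protein's fingers: strictly N-terminal of the first finger, strictly
#' between the k-th and (k+1)-th finger (`C-of-<k>th-ZF`; a 0-residue gap
#' still counts as outside), or `within-ZF` when the match touches a finger.
#' `context_ok` records whether the observed location matches the library's
#' declared context (`C-of-last-ZF` accepts a hit after the final finger).
#'
#' @param proteins Protein tibble (`id`, `sequence`) or named character
#'   vector.
#' @param domains Domain tibble from [scan_domains()] for the same proteins.
#' @param library Motif library tibble; placeholder (pattern-less) entries
#'   are skipped.
#' @return Tibble: `protein_id`, `name`, `start`, `end` (1-based inclusive),
#'   `matched_text`, `context_observed`, `context_ok`.
#' @examples
#' prot <- c(p = "MADLNIPPALDLSLKK")
#' find_boxes(prot, scan_domains(prot))
#' @export
find_boxes <- function(proteins, domains, library = motif_library()) {
  if (is.character(proteins)) {
    ids <- names(proteins) %||% as.character(seq_along(proteins))
    proteins <- tibble::tibble(id = ids, sequence = unname(proteins))
  }
  validate_patterns(library$pattern)
  lib <- library[!is.na(library$pattern), , drop = FALSE]
  empty <- tibble::tibble(
    protein_id = character(), name = character(), start = integer(),
    end = integer(), matched_text = character(),
    context_observed = character(), context_ok = logical()
  )
  if (nrow(lib) == 0 || nrow(proteins) == 0) return(empty)

  hits <- purrr::map2(proteins$id, toupper(proteins$sequence), function(id, s) {
    doms <- domains[domains$protein_id == id, , drop = FALSE]
    doms <- doms[order(doms$start), , drop = FALSE]
    purrr::pmap(lib, function(name, pattern, context) {
      rx <- pattern_to_regex(pattern)
      m <- gregexpr(rx, s)[[1]]
      if (m[1] == -1) return(NULL)
      start <- as.integer(m)
      end <- start + attr(m, "match.length") - 1L
      obs <- vapply(seq_along(start), function(i) {
        observe_context(start[i], end[i], doms$start, doms$end)
      }, "")
      tibble::tibble(
        protein_id = id, name = name, start = start, end = end,
        matched_text = substring(s, start, end),
        context_observed = obs,
        context_ok = context_matches(obs, context, nrow(doms))
      )
    })
  })
  dplyr::bind_rows(empty, purrr::flatten(hits))
}

# Where does [start, end] sit relative to the ordered finger spans?
observe_context <- function(start, end, d_start, d_end) {
  k <- length(d_start)
  if (k == 0) return("no-ZF")
  if (end < d_start[1]) return("N-of-first-ZF")
  for (i in seq_len(k)) {
    after_i <- start > d_end[i]
    before_next <- i == k || end < d_start[i + 1]
    if (after_i && before_next) return(paste0("C-of-", ordinal(i), "-ZF"))
  }
  "within-ZF"
}

ordinal <- function(i) {
  if (i == 1) "first" else if (i == 2) "second" else if (i == 3) "third"
  else paste0(i, "th")
}

context_matches <- function(observed, declared, n_domains) {
  if (declared == "anywhere") return(rep(TRUE, length(observed)))
  if (declared == "C-of-last-ZF") {
    return(observed == paste0("C-of-", ordinal(max(n_domains, 1)), "-ZF"))
  }
  observed == declared
}
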