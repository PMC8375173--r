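#' Scanner parameters for C2H2 zinc-finger detection
#'
#' The canonical plant C2H2 finger is C-X(2-4)-C-X3-F-X5-L-X2-H-X(3-5)-H:
#' two zinc-ligand cysteines 2-4 residues apart, then (in Q-type fingers)
#' the plant-specific QALGGH hexapeptide whose terminal H is the first
#' zinc-ligand histidine, then a second histidine 3-5 residues further on.
#' These parameters bound the search.
#'
#' @param cc_gap_min,cc_gap_max Residues strictly between the two cysteines.
#' @param spacing_min,spacing_max Residues strictly between the second
#'   cysteine and the first histidine (the Q-type value is 12).
#' @param hh_gap_min,hh_gap_max Residues strictly between the two histidines.
#' @param require_FL Enforce the F and L of the general consensus
#'   (F three residues after Cys2, L nine residues after). Off by default:
#'   the Q-type definition X2-C-X2-C-X7-QALGGH-X3-H does not require them.
#' @param m_max_mismatch Maximum QALGGH substitutions for an M-type call;
#'   more substitutions route the finger to Z-type by spacing.
#' @param d_tail_max How far past Cys2 to look for the single motif
#'   histidine of a D-type (second-histidine-less) finger.
#' @return A `scan_params` list.
#' @export
scan_params <- function(cc_gap_min = 2, cc_gap_max = 4,
                        spacing_min = 7, spacing_max = 30,
                        hh_gap_min = 3, hh_gap_max = 5,
                        require_FL = FALSE,
                        m_max_mismatch = 4,
                        d_tail_max = 30) {
  stopifnot(cc_gap_min > 0, cc_gap_max >= cc_gap_min,
            spacing_min > 0, spacing_max >= spacing_min,
            spacing_min <= 12, spacing_max >= 12,
            hh_gap_min > 0, hh_gap_max >= hh_gap_min,
            m_max_mismatch >= 1, d_tail_max > 0)
  structure(
    list(cc_gap_min = cc_gap_min, cc_gap_max = cc_gap_max,
         spacing_min = spacing_min, spacing_max = spacing_max,
         hh_gap_min = hh_gap_min, hh_gap_max = hh_gap_max,
         require_FL = require_FL, m_max_mismatch = m_max_mismatch,
         d_tail_max = d_tail_max),
    class = "scan_params"
  )
}

QALGGH <- "QALGGH"

# Empty domain tibble (column contract for scan_domains).
empty_domains <- function() {
  tibble::tibble(
    protein_id = character(), start = integer(), end = integer(),
    c1 = integer(), c2 = integer(), h1 = integer(), h2 = integer(),
    spacing = integer(), window = character(), mismatches = integer(),
    dtype = character()
  )
}

#' Detect C2H2 zinc-finger domains in protein sequences
#'
#' Two-pass scan, all positions 1-based inclusive. Pass 1 finds complete
#' C..C..H..H units within the [scan_params()] bounds; the first zinc-ligand
#' histidine must be the first histidine after Cys2 (an earlier histidine
#' would itself be the first ligand). Overlaps are resolved
#' greedily leftmost-first (candidates ordered by Cys1, then Cys2, H1, H2;
#' accepted domains never share residues). Pass 2 revisits sequence not
#' covered by pass-1 domains and emits D-type candidates: a cysteine pair
#' whose first following histidine falls within the spacing bounds but which
#' lacks the second zinc-ligand histidine.
#'
#' `X` never matches a ligand or QALGGH position.
#'
#' @param proteins Tibble with `id` and `sequence` columns (as returned by
#'   [read_protein_fasta()]), or a named character vector of sequences.
#' @param params A [scan_params()] object.
#' @return Tibble with one row per detected finger: `protein_id`, `start`,
#'   `end` (domain span, first Cys through last His), ligand positions `c1`,
#'   `c2`, `h1`, `h2` (`h2` is `NA` for D-type), `spacing` (residues strictly
#'   between Cys2 and H1), `window` (the 6-residue QALGGH slot ending at H1),
#'   `mismatches` (Hamming distance of `window` to QALGGH) and `dtype`
#'   (Q, M1-M4, Z1, Z2, D).
#' @examples
#' scan_domains(c(p1 = "MKCAECGKAFSQKQALGGHLRSHIRT"))
#' @export
scan_domains <- function(proteins, params = scan_params()) {
  if (is.character(proteins)) {
    ids <- names(proteins) %||% as.character(seq_along(proteins))
    proteins <- tibble::tibble(id = ids, sequence = unname(proteins))
  }
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  res <- purrr::map2(proteins$id, toupper(proteins$sequence),
                     function(id, s) scan_one(id, s, params))
  out <- dplyr::bind_rows(empty_domains(), res)
  classify_domains(out, params)
}

# Scan a single sequence; returns untyped domain rows.
scan_one <- function(id, s, params) {
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  cpos <- which(ch == "C")
  hpos <- which(ch == "H")
  taken <- logical(n)
  rows <- list()

  # Pass 1: complete C..C..H..H units, greedy leftmost-first.
  cand <- full_unit_candidates(ch, cpos, hpos, params)
  if (nrow(cand) > 0) {
    cand <- cand[order(cand$c1, cand$c2, cand$h1, cand$h2), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      sp <- cand$c1[i]:cand$h2[i]
      if (!any(taken[sp])) {
        taken[sp] <- TRUE
        rows[[length(rows) + 1]] <- cand[i, ]
      }
    }
  }

  # Pass 2: D-type candidates in uncovered segments.
  seg <- uncovered_segments(taken, n)
  for (k in seq_len(nrow(seg))) {
    a <- seg$from[k]; b <- seg$to[k]
    pos <- a
    repeat {
      d <- next_d_candidate(ch, hpos, pos, a, b, params)
      if (is.null(d)) break
      rows[[length(rows) + 1]] <- d
      pos <- d$h1 + 1
    }
  }

  if (length(rows) == 0) return(NULL)
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$c1), , drop = FALSE]
  tibble::tibble(
    protein_id = id,
    start = out$c1,
    end = ifelse(is.na(out$h2), out$h1, out$h2),
    c1 = out$c1, c2 = out$c2, h1 = out$h1, h2 = out$h2,
    spacing = ifelse(is.na(out$h1), NA_integer_, out$h1 - out$c2 - 1L),
    window = ifelse(is.na(out$h1), NA_character_,
                    substring(s, out$h1 - 5L, out$h1)),
    mismatches = NA_integer_
  )
}

full_unit_candidates <- function(ch, cpos, hpos, p) {
  out <- list()
  for (c1 in cpos) {
    c2s <- cpos[cpos - c1 - 1L >= p$cc_gap_min & cpos - c1 - 1L <= p$cc_gap_max]
    for (c2 in c2s) {
      after <- hpos[hpos > c2]
      if (length(after) == 0) next
      h1s <- after[1]
      h1s <- h1s[h1s - c2 - 1L >= p$spacing_min &
                   h1s - c2 - 1L <= p$spacing_max]
      for (h1 in h1s) {
        if (p$require_FL &&
            !(isTRUE(ch[c2 + 4L] == "F") && isTRUE(ch[c2 + 10L] == "L"))) next
        h2s <- hpos[hpos - h1 - 1L >= p$hh_gap_min &
                      hpos - h1 - 1L <= p$hh_gap_max]
        for (h2 in h2s) {
          out[[length(out) + 1]] <- c(c1, c2, h1, h2)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(c1 = integer(), c2 = integer(),
                      h1 = integer(), h2 = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(c1 = m[, 1], c2 = m[, 2], h1 = m[, 3], h2 = m[, 4])
}

uncovered_segments <- function(taken, n) {
  if (n == 0) return(data.frame(from = integer(), to = integer()))
  free <- which(!taken)
  if (length(free) == 0) return(data.frame(from = integer(), to = integer()))
  brk <- c(0, which(diff(free) > 1), length(free))
  data.frame(from = free[brk[-length(brk)] + 1], to = free[brk[-1]])
}

# Leftmost D-type candidate at or after `pos` inside segment [a, b]:
# Cys pair (gap within bounds) whose first following His within the segment
# falls inside the spacing bounds (and within d_tail_max of Cys2), with no
# further His in the h-h gap window after it (that would be a broken full
# unit, not a D finger).
next_d_candidate <- function(ch, hpos, pos, a, b, p) {
  cseg <- which(ch == "C")
  cseg <- cseg[cseg >= pos & cseg <= b]
  for (c1 in cseg) {
    c2s <- cseg[cseg - c1 - 1L >= p$cc_gap_min & cseg - c1 - 1L <= p$cc_gap_max]
    for (c2 in c2s) {
      hseg <- hpos[hpos > c2 & hpos <= b]
      if (length(hseg) == 0) next
      h1 <- hseg[1]
      sp <- h1 - c2 - 1L
      if (sp < p$spacing_min || sp > min(p$spacing_max, p$d_tail_max)) next
      trailing <- hpos[hpos - h1 - 1L >= p$hh_gap_min &
                         hpos - h1 - 1L <= p$hh_gap_max & hpos <= b]
      if (length(trailing) > 0) next
      return(data.frame(c1 = c1, c2 = c2, h1 = h1, h2 = NA_integer_))
    }
  }
  NULL
}

#' Assign the type label of each detected finger
#'
#' Decision cascade: a finger lacking the second zinc-ligand histidine is
#' D-type; an intact QALGGH window at spacing exactly 12 is Q-type; 1 to
#' `m_max_mismatch` substitutions among the first five QALGGH residues give
#' M1-M4 (the index is the substitution count); anything further degenerated
#' is Z-type, split by Cys2-to-H1 spacing into Z1 (>= 12) and Z2 (< 12).
#'
#' @param domains Domain tibble from [scan_domains()].
#' @param params A [scan_params()] object.
#' @return `domains` with `mismatches` and `dtype` recomputed.
#' @export
classify_domains <- function(domains, params = scan_params()) {
  if (nrow(domains) == 0) {
    domains$dtype <- character()
    return(domains)
  }
  mm <- window_mismatches(domains$window)
  dtype <- dplyr::case_when(
    is.na(domains$h2) ~ "D",
    mm == 0L & domains$spacing == 12L ~ "Q",
    mm >= 1L & mm <= params$m_max_mismatch ~ paste0("M", mm),
    domains$spacing >= 12L ~ "Z1",
    TRUE ~ "Z2"
  )
  domains$mismatches <- mm
  domains$dtype <- dtype
  domains
}

# Hamming distance of each 6-residue window to QALGGH. The window ends at
# the first ligand histidine, so its final residue is always H; mismatches
# therefore range over the first five positions. X never matches.
window_mismatches <- function(window) {
  ref <- strsplit(QALGGH, "")[[1]]
  vapply(window, function(w) {
    if (is.na(w)) return(NA_integer_)
    sum(strsplit(w, "")[[1]] != ref)
  }, integer(1), USE.NAMES = FALSE)
}
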