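# Independent oracles used by the test suite. These re-derive expected
# results by exhaustive enumeration, deliberately sharing no code with the
# package implementation.

# --- brute-force C2H2 scanner -------------------------------------------

# Enumerate every ligand quadruple (c1, c2, h1, h2) over ALL positions,
# check the letters and the scan bounds, then keep the leftmost
# non-overlapping set (ordered by c1, c2, h1, h2). Pass 2 enumerates
# (c1, c2, h1) triples for D-type fingers over the uncovered segments.
oracle_scan <- function(seq, params = scan_params()) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  p <- params
  cand <- list()
  if (n >= 4) {
    for (c1 in seq_len(n)) {
      if (ch[c1] != "C") next
      for (c2 in seq_len(n)) {
        if (ch[c2] != "C") next
        if (c2 - c1 - 1 < p$cc_gap_min || c2 - c1 - 1 > p$cc_gap_max) next
        for (h1 in seq_len(n)) {
          if (ch[h1] != "H") next
          if (h1 - c2 - 1 < p$spacing_min || h1 - c2 - 1 > p$spacing_max) next
          if (any(ch[seq2(c2 + 1, h1 - 1)] == "H")) next  # h1 = first His
          if (p$require_FL &&
              !(isTRUE(ch[c2 + 4] == "F") && isTRUE(ch[c2 + 10] == "L"))) next
          for (h2 in seq_len(n)) {
            if (ch[h2] != "H") next
            if (h2 - h1 - 1 < p$hh_gap_min || h2 - h1 - 1 > p$hh_gap_max) next
            cand[[length(cand) + 1]] <- c(c1, c2, h1, h2)
          }
        }
      }
    }
  }
  taken <- rep(FALSE, n)
  keep <- list()
  if (length(cand) > 0) {
    m <- do.call(rbind, cand)
    m <- m[order(m[, 1], m[, 2], m[, 3], m[, 4]), , drop = FALSE]
    for (i in seq_len(nrow(m))) {
      span <- m[i, 1]:m[i, 4]
      if (!any(taken[span])) {
        taken[span] <- TRUE
        keep[[length(keep) + 1]] <- m[i, ]
      }
    }
  }
  # D-type pass over uncovered segments
  free <- which(!taken)
  segs <- split(free, cumsum(c(1, diff(free) > 1)))
  for (seg in segs) {
    a <- min(seg); b <- max(seg)
    pos <- a
    repeat {
      found <- NULL
      dc <- seg[ch[seg] == "C" & seg >= pos]
      for (c1 in dc) {
        for (c2 in dc[dc - c1 - 1 >= p$cc_gap_min &
                        dc - c1 - 1 <= p$cc_gap_max]) {
          hs <- seg[ch[seg] == "H" & seg > c2]
          if (length(hs) == 0) next
          h1 <- min(hs)
          sp <- h1 - c2 - 1
          if (sp < p$spacing_min || sp > min(p$spacing_max, p$d_tail_max)) next
          trail <- hs[hs - h1 - 1 >= p$hh_gap_min & hs - h1 - 1 <= p$hh_gap_max]
          if (length(trail) > 0) next
          found <- c(c1, c2, h1, NA)
          break
        }
        if (!is.null(found)) break
      }
      if (is.null(found)) break
      keep[[length(keep) + 1]] <- found
      pos <- found[3] + 1
    }
  }
  if (length(keep) == 0) {
    return(data.frame(c1 = integer(), c2 = integer(),
                      h1 = integer(), h2 = integer()))
  }
  m <- do.call(rbind, keep)
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(c1 = m[, 1], c2 = m[, 2], h1 = m[, 3], h2 = m[, 4])
}

seq2 <- function(from, to) if (from > to) integer(0) else from:to

# --- brute-force Nei-Gojobori -------------------------------------------

.oracle_code <- Biostrings::GENETIC_CODE

# Fractional synonymous sites of one codon (independent loop structure).
oracle_codon_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa <- .oracle_code[[codon]]
  stopifnot(aa != "*")
  s <- 0
  for (i in 1:3) {
    for (b in bases) {
      mut <- codon
      substr(mut, i, i) <- b
      if (mut == codon) next
      if (.oracle_code[[mut]] == aa) s <- s + 1
    }
  }
  s / 3
}

# DFS over all orderings of the differing positions; paths through stop
# codons are dropped. Returns pathway-averaged c(Sd, Nd), with the
# all-paths-blocked fallback counting raw differences as nonsynonymous.
oracle_codon_diff <- function(ca, cb) {
  diffs <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (length(diffs) == 0) return(c(0, 0))
  acc <- new.env()
  acc$syn <- numeric(0)
  walk <- function(cur, remaining, syn) {
    if (length(remaining) == 0) {
      acc$syn <- c(acc$syn, syn)
      return(invisible())
    }
    for (i in seq_along(remaining)) {
      p <- remaining[i]
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (.oracle_code[[nxt]] == "*") next
      walk(nxt, remaining[-i],
           syn + (.oracle_code[[nxt]] == .oracle_code[[cur]]))
    }
  }
  walk(ca, diffs, 0)
  if (length(acc$syn) == 0) return(c(0, length(diffs)))
  c(mean(acc$syn), length(diffs) - mean(acc$syn))
}

oracle_kaks <- function(cds_a, cds_b) {
  split3 <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  ca <- split3(cds_a); cb <- split3(cds_b)
  S <- (sum(vapply(ca, oracle_codon_sites, 0)) +
          sum(vapply(cb, oracle_codon_sites, 0))) / 2
  N <- 3 * length(ca) - S
  d <- rowSums(vapply(seq_along(ca),
                      function(i) oracle_codon_diff(ca[i], cb[i]),
                      numeric(2)))
  ps <- d[1] / S; pn <- d[2] / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = d[1], Nd = d[2],
       Ks = jc(ps), Ka = jc(pn))
}

# --- misc helpers --------------------------------------------------------

sense_codons <- names(.oracle_code)[.oracle_code != "*"]

random_cds <- function(n_codons) {
  paste(sample(sense_codons, n_codons, replace = TRUE), collapse = "")
}

random_restricted_seq <- function(len) {
  paste(sample(c("A", "C", "H", "Q", "L", "G", "F", "S"), len,
               replace = TRUE), collapse = "")
}

domain_cols <- c("c1", "c2", "h1", "h2")
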