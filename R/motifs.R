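#' IUPAC consensus scan
#'
#' Finds all matches of an IUPAC consensus (R, Y, N, ... ambiguity codes)
#' in a sequence with at most `max_mismatch` mismatches at non-N consensus
#' positions. Backed by Biostrings pattern matching; `U` is treated as `T`.
#'
#' @param seq Subject sequence (DNA or RNA alphabet).
#' @param consensus IUPAC consensus string.
#' @param max_mismatch Maximum mismatches.
#' @return Tibble with `start`, `end` (0-based half-open), `matched_seq`,
#'   `mismatches`, ordered by position; zero rows if no match.
#' @export
match_iupac <- function(seq, consensus, max_mismatch = 0) {
  s <- chartr("Uu", "Tt", toupper(seq))
  pat <- Biostrings::DNAString(chartr("Uu", "Tt", toupper(consensus)))
  subject <- Biostrings::DNAString(s)
  hits <- Biostrings::matchPattern(pat, subject,
                                   max.mismatch = max_mismatch,
                                   fixed = "subject")
  # drop partial matches hanging over the sequence edges
  hits <- hits[BiocGenerics::start(hits) >= 1 &
                 BiocGenerics::end(hits) <= length(subject)]
  if (!length(hits)) {
    return(tibble(start = integer(), end = integer(),
                  matched_seq = character(), mismatches = integer()))
  }
  mm <- lengths(Biostrings::mismatch(pat, hits, fixed = "subject"))
  tibble(start = BiocGenerics::start(hits) - 1L,
         end = BiocGenerics::end(hits),
         matched_seq = as.character(hits),
         mismatches = as.integer(mm)) |>
    dplyr::arrange(.data$start)
}

motif_row <- function(kind, start, end, matched_seq, mismatches) {
  tibble(motif_kind = kind, start = as.integer(start), end = as.integer(end),
         matched_seq = matched_seq, mismatches = as.integer(mismatches))
}

check_motif_length <- function(seq, min_len, error_on_short, op) {
  if (nchar(seq) >= min_len) return(TRUE)
  if (error_on_short) {
    abort(sprintf("%s: sequence shorter than %d nt", op, min_len))
  }
  FALSE
}

#' Detect RNA polymerase III promoter architecture
#'
#' Positive when the transcript carries (a) a terminator: a run of at least
#' `min_u` consecutive U (T in DNA sense) lying entirely within the last
#' `terminator_window` nt; (b) an internal A-box matching `a_box` with at
#' most `a_mm` mismatches, starting in the 5' half; and (c) a B-box
#' matching `b_box` with at most `b_mm` mismatches downstream of the
#' A-box. Consensi are the canonical type-2 Pol III internal promoter
#' elements and are configurable.
#'
#' @param seq Candidate sequence in genomic sense (DNA or RNA alphabet).
#' @param a_box,b_box IUPAC consensi (defaults `TRGCNNARYNNG`, `GTTCRANNC`).
#' @param a_mm,b_mm Mismatch budgets (defaults 2 and 1).
#' @param min_u Minimum terminator U-run (default 4).
#' @param terminator_window 3'-terminal window containing the run
#'   (default 6 nt).
#' @param error_on_short Error (default) or return `NULL` when the
#'   sequence is shorter than 60 nt.
#' @return `NULL` if negative, otherwise a tibble of motif hits (`Abox`,
#'   `Bbox`, `4U`) with 0-based offsets into `seq`.
#' @export
detect_pol3 <- function(seq, a_box = "TRGCNNARYNNG", a_mm = 2,
                        b_box = "GTTCRANNC", b_mm = 1, min_u = 4,
                        terminator_window = 6, error_on_short = TRUE) {
  if (!check_motif_length(seq, 60, error_on_short, "detect_pol3")) return(NULL)
  s <- chartr("Uu", "Tt", toupper(seq))
  n <- nchar(s)
  tail_seq <- substr(s, n - terminator_window + 1, n)
  run <- regmatches(tail_seq, gregexpr("T+", tail_seq))[[1]]
  if (!length(run) || max(nchar(run)) < min_u) return(NULL)
  u_off <- n - terminator_window + regexpr(strrep("T", min_u), tail_seq) - 1L
  a_hits <- match_iupac(s, a_box, a_mm)
  a_hits <- a_hits[a_hits$start < n / 2, , drop = FALSE]
  if (!nrow(a_hits)) return(NULL)
  a_hits <- a_hits[order(a_hits$mismatches, a_hits$start), , drop = FALSE]
  b_all <- match_iupac(s, b_box, b_mm)
  for (i in seq_len(nrow(a_hits))) {
    b_hits <- b_all[b_all$start >= a_hits$end[i], , drop = FALSE]
    if (nrow(b_hits)) {
      b_hits <- b_hits[order(b_hits$mismatches, b_hits$start), , drop = FALSE]
      return(dplyr::bind_rows(
        motif_row("Abox", a_hits$start[i], a_hits$end[i],
                  a_hits$matched_seq[i], a_hits$mismatches[i]),
        motif_row("Bbox", b_hits$start[1], b_hits$end[1],
                  b_hits$matched_seq[1], b_hits$mismatches[1]),
        motif_row("4U", u_off, u_off + min_u,
                  substr(s, u_off + 1, u_off + min_u), 0L)))
    }
  }
  NULL
}

# Longest antiparallel gapless duplex between two short terminal regions:
# left is read 5'->3', right 3'->5'; pairs are WC + G.U.
best_terminal_stem <- function(left, right) {
  pair_ok <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  l <- strsplit(left, "")[[1]]
  r <- rev(strsplit(right, "")[[1]]) # 3'->5'
  best <- 0L
  for (i in seq_along(l)) {
    for (j in seq_along(r)) {
      k <- 0L
      while (i + k <= length(l) && j + k <= length(r) &&
             pair_ok(l[i + k], r[j + k])) k <- k + 1L
      best <- max(best, k)
    }
  }
  best
}

#' Detect C/D box snoRNA architecture
#'
#' Positive when a C box (consensus `RUGAUGA`, at most `c_mm` mismatches)
#' starts within `c_offset` nt of the 5' end, a D box (`CUGA`, exact by
#' default) ends within `d_offset` nt of the 3' end, and the terminal
#' regions outside the boxes (up to `stem_region` nt each) can form a
#' gapless stem of at least `stem_min_pairs` consecutive pairs (G-U
#' allowed).
#'
#' @param seq RNA (or DNA) sequence, >= 50 nt.
#' @param c_box,d_box Consensi (RNA alphabet accepted).
#' @param c_mm,d_mm Mismatch budgets (defaults 1 and 0).
#' @param c_offset,d_offset Maximum distance of the box from its end
#'   (default 12 nt).
#' @param stem_min_pairs Minimum terminal stem pairs (default 4).
#' @param stem_region Terminal region length searched for the stem
#'   (default 10 nt).
#' @param error_on_short See [detect_pol3()].
#' @return `NULL` if negative, otherwise a tibble of motif hits (`Cbox`,
#'   `Dbox`).
#' @export
detect_cd_box <- function(seq, c_box = "RUGAUGA", c_mm = 1, c_offset = 12,
                          d_box = "CUGA", d_mm = 0, d_offset = 12,
                          stem_min_pairs = 4, stem_region = 10,
                          error_on_short = TRUE) {
  if (!check_motif_length(seq, 50, error_on_short, "detect_cd_box")) {
    return(NULL)
  }
  s <- chartr("Uu", "Tt", toupper(seq))
  n <- nchar(s)
  c_hits <- match_iupac(s, c_box, c_mm)
  c_hits <- c_hits[c_hits$start <= c_offset, , drop = FALSE]
  if (!nrow(c_hits)) return(NULL)
  c_hits <- c_hits[order(c_hits$mismatches, c_hits$start), , drop = FALSE]
  d_hits <- match_iupac(s, d_box, d_mm)
  d_hits <- d_hits[n - d_hits$end <= d_offset, , drop = FALSE]
  if (!nrow(d_hits)) return(NULL)
  d_hits <- d_hits[order(d_hits$mismatches, -d_hits$start), , drop = FALSE]
  cb <- c_hits[1, ]; db <- d_hits[1, ]
  left <- substr(s, max(1, cb$start - stem_region + 1), cb$start)
  right <- substr(s, db$end + 1, min(n, db$end + stem_region))
  if (best_terminal_stem(left, right) < stem_min_pairs) return(NULL)
  dplyr::bind_rows(
    motif_row("Cbox", cb$start, cb$end, cb$matched_seq, cb$mismatches),
    motif_row("Dbox", db$start, db$end, db$matched_seq, db$mismatches))
}

#' Detect H/ACA box snoRNA architecture
#'
#' Positive when the sequence carries a 3' ACA box followed by at most
#' `aca_max_tail` nt, an H box (consensus `ANANNA`, at most `h_mm`
#' mismatches) in its middle third, and a predicted two-hairpin fold: the
#' segments 5' and 3' of the H-box hinge (3' segment ending at the ACA box)
#' must each fold into at least `min_hairpin_pairs` base pairs under the
#' pluggable `folder`. A poly(A) pocket — a run of at least `polya_min` A
#' entirely unpaired within the 5' hairpin — is annotated when present.
#'
#' @param seq RNA (or DNA) sequence, >= 60 nt.
#' @param h_box H-box consensus (default `ANANNA`).
#' @param h_mm Mismatch budget (default 1).
#' @param aca_max_tail Maximum nt after the ACA box (default 3).
#' @param min_hairpin_pairs Minimum pairs per hairpin (default 4).
#' @param polya_min Minimum unpaired A-run for the pocket (default 6).
#' @param folder Folding function with the [fold_pairmax()] contract.
#' @param error_on_short See [detect_pol3()].
#' @return `NULL` if negative, otherwise a tibble of motif hits (`Hbox`,
#'   `ACAbox`, optionally `polyA_pocket`).
#' @export
detect_haca_box <- function(seq, h_box = "ANANNA", h_mm = 1,
                            aca_max_tail = 3, min_hairpin_pairs = 4,
                            polya_min = 6, folder = fold_pairmax,
                            error_on_short = TRUE) {
  if (!check_motif_length(seq, 60, error_on_short, "detect_haca_box")) {
    return(NULL)
  }
  s <- chartr("Uu", "Tt", toupper(seq))
  n <- nchar(s)
  aca_start <- NA_integer_
  for (k in 0:aca_max_tail) {
    if (substr(s, n - 2 - k, n - k) == "ACA") { aca_start <- n - 2 - k; break }
  }
  if (is.na(aca_start)) return(NULL)
  h_all <- match_iupac(s, h_box, h_mm)
  third <- floor(n / 3)
  h_all <- h_all[h_all$start >= third & h_all$end <= n - third, , drop = FALSE]
  if (!nrow(h_all)) return(NULL)
  mid <- n / 2
  h_all <- h_all[order(h_all$mismatches,
                       abs((h_all$start + h_all$end) / 2 - mid)), ,
                 drop = FALSE]
  for (i in seq_len(nrow(h_all))) {
    hb <- h_all[i, ]
    seg5 <- substr(s, 1, hb$start)
    seg3 <- substr(s, hb$end + 1, aca_start - 1)
    if (nchar(seg5) < 2 * min_hairpin_pairs ||
        nchar(seg3) < 2 * min_hairpin_pairs) next
    f5 <- folder(seg5)
    f3 <- folder(seg3)
    if (f5$pairs < min_hairpin_pairs || f3$pairs < min_hairpin_pairs) next
    hits <- dplyr::bind_rows(
      motif_row("Hbox", hb$start, hb$end, hb$matched_seq, hb$mismatches),
      motif_row("ACAbox", aca_start - 1L, aca_start + 2L, "ACA", 0L))
    runs <- gregexpr(sprintf("A{%d,}", polya_min), seg5)[[1]]
    if (runs[1] != -1) {
      db <- strsplit(f5$dotbracket, "")[[1]]
      lens <- attr(runs, "match.length")
      for (j in seq_along(runs)) {
        span <- runs[j]:(runs[j] + lens[j] - 1)
        if (all(db[span] == ".")) {
          hits <- dplyr::bind_rows(hits,
            motif_row("polyA_pocket", runs[j] - 1L, runs[j] - 1L + lens[j],
                      substr(s, runs[j], runs[j] + lens[j] - 1), 0L))
          break
        }
      }
    }
    return(hits)
  }
  NULL
}
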