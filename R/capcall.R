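#' Call 5'-cap sites from cap-enriched 5'-end tracks
#'
#' A candidate position is any site with at least `min_count` 5'-end reads.
#' Within each replicate a site must satisfy: (1) `upFC = endCov /
#' max(upCov, pseudocount) >= min_fc`; (2) `downFC` likewise for the
#' position one nt downstream; (3) `endCov >= min_count`; (4) a one-sided
#' binomial enrichment p-value below `alpha`, testing `endCov` successes
#' out of `N` = total 5'-end counts within `window` nt of the site, with
#' success probability `1 / (2 * window + 1)` (local-uniform null). A final
#' site must pass (1)-(4) in at least `min_replicates` replicates at the
#' same position and (5) lie within an annotated mRNA 5'UTR on the same
#' strand. Up/downstream are strand-aware.
#'
#' @param tracks List of `nap_tracks`, one per replicate, whose `start5`
#'   arrays hold the 5'-end counts of the cap-enriched library.
#' @param utr5 Interval tibble of mRNA 5'UTRs (required).
#' @param min_count Minimum 5'-end reads at the site (default 10).
#' @param min_fc Minimum up/down fold change (default 2).
#' @param alpha P-value threshold (default 0.05).
#' @param window Half-width of the binomial null window (default 100 nt).
#' @param pseudocount Denominator floor for the fold changes (default 1).
#' @param min_replicates Replicates that must support a site (default 2).
#' @return Tibble of cap sites: `chrom`, `pos` (0-based), `strand`,
#'   `endCov`, `upCov`, `downCov`, `upFC`, `downFC`, `pvalue` (all from the
#'   replicate with the highest `endCov`) and `replicates_supporting`.
#' @export
call_cap_sites <- function(tracks, utr5, min_count = 10, min_fc = 2,
                           alpha = 0.05, window = 100, pseudocount = 1,
                           min_replicates = 2) {
  if (is.null(utr5)) abort("5'UTR annotation is required to call cap sites")
  check_intervals(utr5, what = "utr5")
  if (length(tracks) < min_replicates) {
    abort(sprintf("need >= %d replicate track sets, got %d",
                  min_replicates, length(tracks)))
  }
  per_rep <- purrr::imap(tracks, function(tr, rep_id) {
    rows <- purrr::map(names(tr$start5), function(key) {
      parts <- strsplit(key, ":", fixed = TRUE)[[1]]
      strand <- parts[2]
      v <- tr$start5[[key]]
      cand <- which(v >= min_count) - 1L # 0-based positions
      if (!length(cand)) return(NULL)
      up_off <- if (strand == "+") -1L else 1L
      n <- length(v)
      at <- function(p) ifelse(p >= 0 & p < n, v[pmin(pmax(p, 0), n - 1) + 1], 0)
      endCov <- v[cand + 1]
      upCov <- at(cand + up_off)
      downCov <- at(cand - up_off)
      win_n <- vapply(cand, function(p) {
        sum(v[(max(p - window, 0) + 1):(min(p + window, n - 1) + 1)])
      }, numeric(1))
      p0 <- 1 / (2 * window + 1)
      pval <- pbinom(endCov - 1, size = win_n, prob = p0, lower.tail = FALSE)
      tibble(chrom = parts[1], pos = cand, strand = strand,
             endCov = endCov, upCov = upCov, downCov = downCov,
             upFC = endCov / pmax(upCov, pseudocount),
             downFC = endCov / pmax(downCov, pseudocount),
             pvalue = pval, replicate = rep_id)
    })
    out <- dplyr::bind_rows(rows)
    if (!nrow(out)) return(out)
    dplyr::filter(out, .data$upFC >= min_fc, .data$downFC >= min_fc,
                  .data$endCov >= min_count, .data$pvalue < alpha)
  })
  all_pass <- dplyr::bind_rows(per_rep)
  if (!nrow(all_pass)) {
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  endCov = numeric(), upCov = numeric(), downCov = numeric(),
                  upFC = numeric(), downFC = numeric(), pvalue = numeric(),
                  replicates_supporting = integer()))
  }
  sites <- all_pass |>
    dplyr::group_by(.data$chrom, .data$pos, .data$strand) |>
    dplyr::arrange(dplyr::desc(.data$endCov), .data$replicate,
                   .by_group = TRUE) |>
    dplyr::summarise(endCov = .data$endCov[1], upCov = .data$upCov[1],
                     downCov = .data$downCov[1], upFC = .data$upFC[1],
                     downFC = .data$downFC[1], pvalue = .data$pvalue[1],
                     replicates_supporting = dplyr::n_distinct(.data$replicate),
                     .groups = "drop") |>
    dplyr::filter(.data$replicates_supporting >= min_replicates)
  if (!nrow(sites)) return(dplyr::mutate(sites, pos = integer()))
  as_iv <- tibble(chrom = sites$chrom, start = sites$pos,
                  end = sites$pos + 1L, strand = sites$strand)
  hits <- overlap_features(as_iv, utr5, same_strand = TRUE)
  sites <- sites[sort(unique(hits$query_row)), , drop = FALSE]
  dplyr::arrange(sites, .data$chrom, .data$pos, .data$strand)
}

#' Overlap between napRNA 5' starts and cap sites
#'
#' Counts called napRNAs whose biological 5'-start coincides with a cap
#' site (same strand) within `tolerance` nt — the specificity check that
#' transcripts called as noncapped do not sit on capped TSSs.
#'
#' @param naprnas Interval tibble of napRNA calls.
#' @param cap_sites Tibble from [call_cap_sites()] (`chrom`, `pos`,
#'   `strand`).
#' @param tolerance Matching tolerance in nt (default 0).
#' @return One-row tibble: `n_naprnas`, `n_overlap`, `fraction`.
#' @export
compare_cap_overlap <- function(naprnas, cap_sites, tolerance = 0) {
  check_intervals(naprnas, what = "naprnas")
  n <- nrow(naprnas)
  if (!n || !nrow(cap_sites)) {
    return(tibble(n_naprnas = n, n_overlap = 0L, fraction = 0))
  }
  p5 <- bio_end5(naprnas)
  hit <- vapply(seq_len(n), function(i) {
    any(cap_sites$chrom == naprnas$chrom[i] &
          cap_sites$strand == naprnas$strand[i] &
          abs(cap_sites$pos - p5[i]) <= tolerance)
  }, logical(1))
  tibble(n_naprnas = n, n_overlap = sum(hit), fraction = sum(hit) / n)
}
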