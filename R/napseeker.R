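#' Assemble covered contigs from a signal track
#'
#' A contig is a maximal run of consecutive positions with coverage at or
#' above `cov_floor`, per chromosome and strand — the caller's unit of
#' candidate search.
#'
#' @param track A `nap_tracks` object.
#' @param cov_floor Minimum coverage depth (default 1).
#' @return Tibble `chrom`, `start`, `end`, `strand`, `mean_cov`, sorted by
#'   chrom, start, strand.
#' @export
assemble_contigs <- function(track, cov_floor = 1) {
  stopifnot(inherits(track, "nap_tracks"), cov_floor >= 1)
  rows <- purrr::map(names(track$cov), function(key) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    v <- track$cov[[key]]
    r <- rle(v >= cov_floor)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (!any(keep)) return(NULL)
    tibble(chrom = parts[1], start = starts[keep], end = ends[keep],
           strand = parts[2],
           mean_cov = purrr::map2_dbl(starts[keep], ends[keep],
                                      function(s, e) mean(v[(s + 1):e])))
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), mean_cov = numeric()))
  }
  dplyr::arrange(out, .data$chrom, .data$start, .data$strand)
}

# Strand-aware argmax helpers: ties resolve to the most-5' (resp. most-3')
# genomic position on the feature strand.
argmax_5p <- function(v, strand) {
  m <- max(v)
  idx <- which(v == m)
  if (strand == "+") idx[1] else idx[length(idx)]
}
argmax_3p <- function(v, strand) {
  m <- max(v)
  idx <- which(v == m)
  if (strand == "+") idx[length(idx)] else idx[1]
}

# Mean over the clipped window [from, to) of vector v (0-based bounds);
# returns NA if the clipped window is empty.
clipped_mean <- function(v, from, to) {
  from <- max(from, 0L); to <- min(to, length(v))
  if (to <= from) return(NA_real_)
  mean(v[(from + 1):to])
}

#' Boundary statistics for candidate napRNAs
#'
#' For each contig, the candidate 5' boundary is the position with the most
#' adapter-verified 5' ends (ties resolve to the most-5' position) and the
#' candidate 3' boundary the position with the most verified 3' ends (ties
#' most-3'). Six statistics are attached:
#' \describe{
#'   \item{startReadNum / endReadNum}{verified 5'/3' end counts at the
#'     candidate boundaries.}
#'   \item{startFC / endFC}{boundary count over the sum of like counts
#'     within `boundary_window` nt on both sides (the boundary position
#'     itself excluded), floored at 1.}
#'   \item{up20ntFC / down20ntFC}{mean candidate coverage over the mean
#'     coverage of the `flank` nt immediately upstream of the 5' boundary
#'     (resp. downstream of the 3' boundary), floored at `epsilon`.}
#' }
#' Contigs whose best 5' boundary lies downstream of the best 3' boundary
#' are degenerate and emit no candidate.
#'
#' @param contigs Tibble from [assemble_contigs()].
#' @param track The `nap_tracks` the contigs came from.
#' @param boundary_window Half-width of the boundary fold-change window
#'   (default 100 nt).
#' @param flank Width of the coverage flank (default 20 nt).
#' @param epsilon Floor for the flank coverage mean (default 0.05, i.e. one
#'   read over 20 nt).
#' @return Tibble of candidates with the six statistics, `p5`/`p3`
#'   boundary positions, `length` and `sample`.
#' @export
boundary_stats <- function(contigs, track, boundary_window = 100, flank = 20,
                           epsilon = 0.05) {
  stopifnot(inherits(track, "nap_tracks"))
  rows <- purrr::pmap(contigs[c("chrom", "start", "end", "strand")],
                      function(chrom, start, end, strand) {
    key <- track_key(chrom, strand)
    cov <- track$cov[[key]]; s5 <- track$start5[[key]]; e3 <- track$end3[[key]]
    idx <- (start + 1):end
    p5 <- start + argmax_5p(s5[idx], strand) - 1L
    p3 <- start + argmax_3p(e3[idx], strand) - 1L
    cstart <- min(p5, p3); cend <- max(p5, p3) + 1L
    upstream_of_5p <- if (strand == "+") p5 > p3 else p5 < p3
    if (upstream_of_5p) return(NULL) # degenerate: 5' boundary past 3'
    win_sum <- function(v, p) {
      from <- max(p - boundary_window, 0L)
      to <- min(p + boundary_window, length(v) - 1L)
      sum(v[(from + 1):(to + 1)]) - v[p + 1]
    }
    start_n <- s5[p5 + 1]; end_n <- e3[p3 + 1]
    inside <- mean(cov[(cstart + 1):cend])
    up_mean <- if (strand == "+") clipped_mean(cov, p5 - flank, p5)
               else clipped_mean(cov, p5 + 1L, p5 + 1L + flank)
    down_mean <- if (strand == "+") clipped_mean(cov, p3 + 1L, p3 + 1L + flank)
                 else clipped_mean(cov, p3 - flank, p3)
    if (is.na(up_mean)) up_mean <- 0
    if (is.na(down_mean)) down_mean <- 0
    tibble(chrom = chrom, start = cstart, end = cend, strand = strand,
           p5 = p5, p3 = p3,
           startReadNum = start_n, endReadNum = end_n,
           startFC = start_n / max(1, win_sum(s5, p5)),
           endFC = end_n / max(1, win_sum(e3, p3)),
           up20ntFC = inside / max(epsilon, up_mean),
           down20ntFC = inside / max(epsilon, down_mean),
           length = cend - cstart,
           sample = track$sample)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), p5 = integer(), p3 = integer(),
                  startReadNum = numeric(), endReadNum = numeric(),
                  startFC = numeric(), endFC = numeric(),
                  up20ntFC = numeric(), down20ntFC = numeric(),
                  length = integer(), sample = character())
  }
  out
}

#' Threshold filter for candidate napRNAs
#'
#' Keeps candidates with `startReadNum >= min_boundary_reads` AND
#' `endReadNum >= min_boundary_reads` AND `startFC`/`endFC >=
#' min_boundary_fc` AND `up20ntFC`/`down20ntFC >= min_flank_fc` AND
#' `length >= min_length`. All comparisons are boundary-inclusive.
#'
#' @param candidates Tibble from [boundary_stats()].
#' @param min_boundary_reads Minimum verified end reads (default 7).
#' @param min_boundary_fc Minimum boundary fold change (default 2).
#' @param min_flank_fc Minimum flank coverage fold change (default 2).
#' @param min_length Minimum length in nt (default 100).
#' @return The passing subset.
#' @export
filter_candidates <- function(candidates, min_boundary_reads = 7,
                              min_boundary_fc = 2, min_flank_fc = 2,
                              min_length = 100) {
  dplyr::filter(candidates,
                .data$startReadNum >= min_boundary_reads,
                .data$endReadNum >= min_boundary_reads,
                .data$startFC >= min_boundary_fc,
                .data$endFC >= min_boundary_fc,
                .data$up20ntFC >= min_flank_fc,
                .data$down20ntFC >= min_flank_fc,
                .data$length >= min_length)
}

#' Merge per-sample calls into a final napRNA set
#'
#' Candidates from different samples whose 5' and 3' boundaries each agree
#' within `end_tolerance` nt (same chromosome and strand; single linkage)
#' are merged. Each sample supports a merged call with
#' `min(startReadNum, endReadNum)` reads — a lower bound on fully
#' end-verified molecules — and the call is retained only when supported in
#' at least `min_samples` samples with a summed support of at least
#' `min_summary`. The representative interval is taken from the sample with
#' the highest support.
#'
#' @param candidates Filtered candidate tibble covering all samples (must
#'   have a `sample` column).
#' @param end_tolerance Boundary agreement tolerance in nt (default 5;
#'   0 = exact).
#' @param min_samples Minimum supporting samples (default 2).
#' @param min_summary Minimum summed support (default 20).
#' @return Tibble of merged calls: interval columns, `name`, the six
#'   statistics of the representative, `n_samples`, `summary_count` and a
#'   `sample_counts` list-column (named per-sample support).
#' @export
merge_across_samples <- function(candidates, end_tolerance = 5,
                                 min_samples = 2, min_summary = 20) {
  if (!nrow(candidates)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), strand = character(),
                  startReadNum = numeric(), endReadNum = numeric(),
                  startFC = numeric(), endFC = numeric(),
                  up20ntFC = numeric(), down20ntFC = numeric(),
                  length = integer(), n_samples = integer(),
                  summary_count = numeric(), sample_counts = list()))
  }
  cand <- dplyr::mutate(candidates,
                        support = pmin(.data$startReadNum, .data$endReadNum),
                        e5 = bio_end5(candidates), e3 = bio_end3(candidates))
  groups <- dplyr::group_split(dplyr::group_by(cand, .data$chrom, .data$strand))
  merged <- purrr::map(groups, function(g) {
    n <- nrow(g)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j <= i) next
        if (abs(g$e5[i] - g$e5[j]) <= end_tolerance &&
            abs(g$e3[i] - g$e3[j]) <= end_tolerance) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    purrr::map(unique(comp), function(cid) {
      m <- g[comp == cid, , drop = FALSE]
      per_sample <- tapply(m$support, m$sample, max)
      rep_row <- m[order(-m$support, m$sample, m$start)[1], , drop = FALSE]
      dplyr::mutate(
        rep_row[c("chrom", "start", "end", "strand", "startReadNum",
                  "endReadNum", "startFC", "endFC", "up20ntFC",
                  "down20ntFC", "length")],
        n_samples = length(per_sample),
        summary_count = sum(per_sample),
        sample_counts = list(c(per_sample)))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out <- dplyr::filter(merged, .data$n_samples >= min_samples,
                       .data$summary_count >= min_summary)
  out <- dplyr::arrange(out, .data$chrom, .data$start, .data$end, .data$strand)
  out$name <- sprintf("napRNA-%04d", seq_len(nrow(out)))
  dplyr::relocate(out, "name", .after = "end")
}

#' Call napRNAs from a set of per-sample track objects
#'
#' The full caller: assemble contigs, compute boundary statistics and apply
#' thresholds per sample, then merge calls across samples.
#'
#' @param tracks Named list of `nap_tracks` (one per sample) from
#'   [build_tracks()].
#' @param cov_floor,boundary_window,flank,epsilon See [assemble_contigs()]
#'   and [boundary_stats()].
#' @param min_boundary_reads,min_boundary_fc,min_flank_fc,min_length See
#'   [filter_candidates()].
#' @param end_tolerance,min_samples,min_summary See
#'   [merge_across_samples()].
#' @return Tibble of final napRNA calls (see [merge_across_samples()]),
#'   with class `"nap_calls"`.
#' @export
call_naprnas <- function(tracks, cov_floor = 1, boundary_window = 100,
                         flank = 20, epsilon = 0.05, min_boundary_reads = 7,
                         min_boundary_fc = 2, min_flank_fc = 2,
                         min_length = 100, end_tolerance = 5,
                         min_samples = 2, min_summary = 20) {
  per_sample <- purrr::map(tracks, function(tr) {
    contigs <- assemble_contigs(tr, cov_floor = cov_floor)
    cand <- boundary_stats(contigs, tr, boundary_window = boundary_window,
                           flank = flank, epsilon = epsilon)
    filter_candidates(cand, min_boundary_reads = min_boundary_reads,
                      min_boundary_fc = min_boundary_fc,
                      min_flank_fc = min_flank_fc, min_length = min_length)
  })
  out <- merge_across_samples(dplyr::bind_rows(per_sample),
                              end_tolerance = end_tolerance,
                              min_samples = min_samples,
                              min_summary = min_summary)
  class(out) <- c("nap_calls", class(out))
  out
}

#' @method glance nap_calls
#' @export
glance.nap_calls <- function(x, ...) {
  tibble(n_calls = nrow(x),
         median_length = if (nrow(x)) stats::median(x$length) else NA_real_,
         median_summary_count = if (nrow(x)) stats::median(x$summary_count)
                                else NA_real_,
         max_samples = if (nrow(x)) max(x$n_samples) else NA_integer_)
}
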