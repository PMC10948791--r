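chrT <- c(chrT = 2000L)

tracks_from <- function(aln) build_tracks(aln, chrT)[[1]]

test_that("assemble_contigs returns maximal covered runs", {
  aln <- tibble::tibble(chrom = "chrT", start = c(100L, 400L),
                        end = c(300L, 500L), strand = "+",
                        has5p = FALSE, has3p = FALSE, sample = "s1")
  ct <- assemble_contigs(tracks_from(aln))
  expect_equal(ct$start, c(100L, 400L))
  expect_equal(ct$end, c(300L, 500L))
  empty <- aln[0, ]
  expect_equal(nrow(assemble_contigs(build_tracks(
    dplyr::mutate(aln[1, ], sample = "s1"), chrT)[[1]], cov_floor = 99)), 0L)
})

test_that("contigs equal a run-length scan oracle on random tracks", {
  withr::local_seed(31)
  for (rep in 1:5) {
    aln <- random_alignments(80, 2000)
    tr <- tracks_from(aln)
    ct <- assemble_contigs(tr, cov_floor = 2)
    for (strand in c("+", "-")) {
      cov <- track_vector(tr, "cov", "chrT", strand)
      runs <- rle(cov >= 2)
      ends <- cumsum(runs$lengths); starts <- ends - runs$lengths
      want_start <- starts[runs$values]; want_end <- ends[runs$values]
      got <- ct[ct$strand == strand, ]
      expect_equal(got$start, want_start)
      expect_equal(got$end, want_end)
    }
  }
})

# Hand-built track: one clean napRNA on [1000, 1200) with controlled
# boundary and flank signal.
unit_world <- function(n5 = 10, n3 = 10, extra5 = NULL, extra3 = NULL,
                       strand = "+") {
  main <- tibble::tibble(chrom = "chrT", start = 1000L, end = 1200L,
                         strand = strand,
                         has5p = rep(c(TRUE, FALSE), c(n5, 12 - n5)),
                         has3p = rep(c(TRUE, FALSE), c(n3, 12 - n3)),
                         sample = "s1")
  dplyr::bind_rows(main, extra5, extra3)
}

test_that("boundary statistics match their printed-form definitions", {
  # startFC with an empty window denominator floors at 1
  tr <- tracks_from(unit_world(n5 = 10, n3 = 8))
  cand <- boundary_stats(assemble_contigs(tr), tr)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$startReadNum, 10)
  expect_equal(cand$endReadNum, 8)
  expect_equal(cand$startFC, 10)
  expect_equal(cand$p5, 1000L)
  expect_equal(cand$p3, 1199L)

  # competing 5' counts inside the +/-100 nt window: startFC = 10/5
  extra <- tibble::tibble(chrom = "chrT",
                          start = c(rep(960L, 2), rep(1050L, 3)),
                          end = c(rep(1160L, 2), rep(1200L, 3)),
                          strand = "+", has5p = TRUE, has3p = FALSE,
                          sample = "s1")
  tr2 <- tracks_from(unit_world(n5 = 10, n3 = 8, extra5 = extra))
  cand2 <- boundary_stats(assemble_contigs(tr2), tr2)
  expect_equal(cand2$startFC, 10 / 5)
})

test_that("flank coverage fold changes use means with the 0.05 floor", {
  # inside mean 12; upstream flank mean 2; downstream flank mean 3
  inside <- tibble::tibble(chrom = "chrT", start = 1000L, end = 1200L,
                           strand = "+", has5p = TRUE, has3p = TRUE,
                           sample = "s1")[rep(1, 12), ]
  up <- tibble::tibble(chrom = "chrT", start = 980L, end = 1000L,
                       strand = "+", has5p = FALSE, has3p = FALSE,
                       sample = "s1")[rep(1, 2), ]
  dn <- tibble::tibble(chrom = "chrT", start = 1200L, end = 1220L,
                       strand = "+", has5p = FALSE, has3p = FALSE,
                       sample = "s1")[rep(1, 3), ]
  tr <- tracks_from(dplyr::bind_rows(inside, up, dn))
  ct <- assemble_contigs(tr)
  expect_equal(nrow(ct), 1L) # 980-1220 contiguous
  cand <- boundary_stats(ct, tr)
  expect_equal(cand$up20ntFC, 12 / 2)
  expect_equal(cand$down20ntFC, 12 / 3)

  # no flanking coverage at all: denominator floors at epsilon = 0.05
  tr0 <- tracks_from(inside)
  cand0 <- boundary_stats(assemble_contigs(tr0), tr0)
  expect_equal(cand0$up20ntFC, 12 / 0.05)
})

test_that("minus-strand candidates mirror the boundary geometry", {
  tr <- tracks_from(unit_world(strand = "-"))
  cand <- boundary_stats(assemble_contigs(tr), tr)
  expect_equal(cand$p5, 1199L) # biological 5' end at the right edge
  expect_equal(cand$p3, 1000L)
  expect_equal(cand$start, 1000L)
  expect_equal(cand$end, 1200L)
})

test_that("candidate statistics match the brute-force oracle on random data", {
  withr::local_seed(37)
  checked <- 0
  while (checked < 100) {
    aln <- random_alignments(60, 2000)
    tr <- tracks_from(aln)
    cands <- boundary_stats(assemble_contigs(tr), tr)
    for (i in seq_len(nrow(cands))) {
      strand <- cands$strand[i]
      want <- oracle_boundary_stats(
        track_vector(tr, "cov", "chrT", strand),
        track_vector(tr, "start5", "chrT", strand),
        track_vector(tr, "end3", "chrT", strand),
        cands$p5[i], cands$p3[i], strand)
      expect_equal(cands$startFC[i], want$startFC)
      expect_equal(cands$endFC[i], want$endFC)
      expect_equal(cands$up20ntFC[i], want$up20ntFC)
      expect_equal(cands$down20ntFC[i], want$down20ntFC)
      checked <- checked + 1
    }
  }
})

test_that("threshold filter is boundary-inclusive on all six statistics", {
  base <- tibble::tibble(chrom = "chrT", start = 0L, end = 100L,
                         strand = "+", p5 = 0L, p3 = 99L,
                         startReadNum = 7, endReadNum = 7, startFC = 2,
                         endFC = 2, up20ntFC = 2, down20ntFC = 2,
                         length = 100L, sample = "s1")
  expect_equal(nrow(filter_candidates(base)), 1L)
  expect_equal(nrow(filter_candidates(dplyr::mutate(base, startReadNum = 6))),
               0L)
  expect_equal(nrow(filter_candidates(dplyr::mutate(base, length = 99L))), 0L)
  expect_equal(nrow(filter_candidates(dplyr::mutate(base, endFC = 1.99))), 0L)
  expect_equal(nrow(filter_candidates(dplyr::mutate(base, down20ntFC = 1.9))),
               0L)
})

test_that("cross-sample merging applies the 2-sample and summary-20 rules", {
  cand <- function(s, support, shift = 0L) {
    tibble::tibble(chrom = "chrT", start = 500L + shift, end = 700L + shift,
                   strand = "+", p5 = 500L + shift, p3 = 699L + shift,
                   startReadNum = support, endReadNum = support,
                   startFC = 5, endFC = 5, up20ntFC = 5, down20ntFC = 5,
                   length = 200L, sample = s)
  }
  # 12 + 9 = 21 >= 20 in 2 samples: retained
  m1 <- merge_across_samples(dplyr::bind_rows(cand("s1", 12), cand("s2", 9)))
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$summary_count, 21)
  expect_equal(m1$n_samples, 2L)
  # one sample only, huge count: dropped
  m2 <- merge_across_samples(cand("s1", 100))
  expect_equal(nrow(m2), 0L)
  # 9 + 9 = 18 < 20: dropped
  m3 <- merge_across_samples(dplyr::bind_rows(cand("s1", 9), cand("s2", 9)))
  expect_equal(nrow(m3), 0L)
  # ends differing by more than the tolerance never merge
  m4 <- merge_across_samples(dplyr::bind_rows(cand("s1", 12),
                                              cand("s2", 12, shift = 6L)),
                             end_tolerance = 5)
  expect_equal(nrow(m4), 0L)
  m5 <- merge_across_samples(dplyr::bind_rows(cand("s1", 12),
                                              cand("s2", 12, shift = 5L)),
                             end_tolerance = 5)
  expect_equal(nrow(m5), 1L)
  expect_equal(m5$start, 500L) # representative = highest support, first sample
})

test_that("every emitted call re-verifies all thresholds (fuzz)", {
  withr::local_seed(41)
  violations <- 0
  for (rep in 1:60) {
    aln <- dplyr::bind_rows(random_alignments(80, 2000, "s1"),
                            random_alignments(80, 2000, "s2"))
    trs <- build_tracks(aln, chrT)
    for (tr in trs) {
      passing <- filter_candidates(boundary_stats(assemble_contigs(tr), tr))
      for (i in seq_len(nrow(passing))) {
        strand <- passing$strand[i]
        want <- oracle_boundary_stats(
          track_vector(tr, "cov", "chrT", strand),
          track_vector(tr, "start5", "chrT", strand),
          track_vector(tr, "end3", "chrT", strand),
          passing$p5[i], passing$p3[i], strand)
        ok <- want$startReadNum >= 7 && want$endReadNum >= 7 &&
          want$startFC >= 2 && want$endFC >= 2 &&
          want$up20ntFC >= 2 && want$down20ntFC >= 2 &&
          passing$length[i] >= 100
        if (!ok) violations <- violations + 1
      }
    }
  }
  expect_equal(violations, 0)
})

test_that("background reads outside candidate windows never raise startFC", {
  tr <- tracks_from(unit_world(n5 = 10, n3 = 10))
  base <- boundary_stats(assemble_contigs(tr), tr)
  far <- tibble::tibble(chrom = "chrT", start = 1500L, end = 1600L,
                        strand = "+", has5p = TRUE, has3p = TRUE,
                        sample = "s1")[rep(1, 5), ]
  tr2 <- tracks_from(dplyr::bind_rows(unit_world(n5 = 10, n3 = 10), far))
  with_bg <- boundary_stats(assemble_contigs(tr2), tr2)
  main <- with_bg[with_bg$start == 1000L, ]
  expect_equal(main$startFC, base$startFC)
  expect_equal(main$endFC, base$endFC)
})
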