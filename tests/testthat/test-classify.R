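iv <- function(start, end, strand = "+", name = "x", chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), name = name, score = 0,
                 strand = strand)
}

test_that("exclusion filter drops same-strand overlaps only", {
  naps <- dplyr::bind_rows(iv(100, 300, "+", "in_rrna"),
                           iv(100, 300, "-", "antisense"),
                           iv(5000, 5200, "+", "intergenic"))
  excl <- iv(250, 400, "+", "rRNA")
  kept <- exclude_annotated(naps, excl)
  expect_setequal(kept$name, c("antisense", "intergenic"))
  withr::local_seed(61)
  naps_r <- random_alignments(200, 5000)[, c("chrom", "start", "end", "strand")]
  excl_r <- random_alignments(50, 5000)[, c("chrom", "start", "end", "strand")]
  kept_r <- exclude_annotated(naps_r, excl_r)
  want <- oracle_overlap(naps_r, excl_r, same_strand = TRUE)
  want_kept <- naps_r[setdiff(seq_len(nrow(naps_r)), unique(want[, 1])), ]
  expect_equal(as.data.frame(kept_r), as.data.frame(want_kept),
               ignore_attr = TRUE)
})

test_that("sliRNA requires both splice-site ends, with tolerance", {
  introns <- iv(1000, 1500, "+", "intronA")
  expect_true(classify_slirna(iv(1000, 1500), introns)$slirna)
  expect_false(classify_slirna(iv(1000, 1450), introns)$slirna)
  expect_false(classify_slirna(iv(1000, 1500, "-"), introns)$slirna)
  expect_true(classify_slirna(iv(997, 1503), introns,
                              end_tolerance = 3)$slirna)
  withr::local_seed(62)
  naps <- random_alignments(250, 5000)[, c("chrom", "start", "end", "strand")]
  intr <- random_alignments(250, 5000)[, c("chrom", "start", "end", "strand")]
  intr$name <- sprintf("i%d", 1:250)
  got <- classify_slirna(naps, intr, end_tolerance = 3)$slirna
  n5 <- bio_end5(naps); n3 <- bio_end3(naps)
  i5 <- bio_end5(intr); i3 <- bio_end3(intr)
  want <- vapply(seq_len(nrow(naps)), function(i) {
    any(intr$strand == naps$strand[i] & abs(i5 - n5[i]) <= 3 &
          abs(i3 - n3[i]) <= 3)
  }, logical(1))
  expect_equal(got, want)
})

test_that("snotron geometry covers both orientations and the 10-nt boundary", {
  introns <- iv(5000, 5800, "+", "host")
  sno <- iv(5100, 5180, "+", "sno1")
  lab <- function(nap) classify_snotron(nap, sno, introns)
  r <- lab(iv(5100, 5796))
  expect_true(r$snotron)
  expect_equal(r$snotron_orientation, "5p_snoRNA")
  expect_equal(r$snotron_snorna, "sno1")
  expect_true(lab(iv(5100, 5790))$snotron)    # exactly 10 nt
  expect_false(lab(iv(5100, 5789))$snotron)   # 11 nt
  # mirror configuration: 3' end = snoRNA 3' end, 5' end near the 5'SS
  sno3 <- iv(5600, 5700, "+", "sno2")
  r2 <- classify_snotron(iv(5004, 5700), sno3, introns)
  expect_true(r2$snotron)
  expect_equal(r2$snotron_orientation, "3p_snoRNA")
  # snoRNA outside any intron never yields a snotron
  orphan <- iv(9000, 9080, "+", "orphan")
  expect_false(classify_snotron(iv(9000, 9300), orphan, introns)$snotron)
})

test_that("tolerance monotonicity: growing windows never remove labels", {
  withr::local_seed(63)
  naps <- random_alignments(150, 8000)[, c("chrom", "start", "end", "strand")]
  introns <- random_alignments(60, 8000)[, c("chrom", "start", "end", "strand")]
  introns$name <- sprintf("i%d", 1:60)
  sno <- random_alignments(40, 8000)[, c("chrom", "start", "end", "strand")]
  sno$name <- sprintf("s%d", 1:40)
  prev <- rep(FALSE, nrow(naps))
  for (tol in c(0, 5, 10, 50)) {
    cur <- classify_snotron(naps, sno, introns, splice_tolerance = tol,
                            end_tolerance = tol)$snotron
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("pre-miRNA clustering is strict at the 10-kb gap", {
  two <- dplyr::bind_rows(iv(1000, 1080, "+", "p1"),
                          iv(1300, 1380, "+", "p2"))
  expect_equal(dplyr::n_distinct(cluster_premirnas(two)$cluster_id), 1L)
  apart <- dplyr::bind_rows(iv(1000, 1080, "+", "p1"),
                            iv(11080, 11160, "+", "p2"))   # gap exactly 10 kb
  expect_equal(dplyr::n_distinct(cluster_premirnas(apart)$cluster_id), 2L)
  near <- dplyr::bind_rows(iv(1000, 1080, "+", "p1"),
                           iv(11079, 11159, "+", "p2"))    # gap 9999
  expect_equal(dplyr::n_distinct(cluster_premirnas(near)$cluster_id), 1L)
  mixed <- dplyr::bind_rows(iv(1000, 1080, "+", "p1"),
                            iv(1300, 1380, "-", "p2"))     # strands split
  expect_equal(dplyr::n_distinct(cluster_premirnas(mixed)$cluster_id), 2L)

  # union-find oracle over random features
  withr::local_seed(64)
  pre <- random_alignments(60, 60000)[, c("chrom", "start", "end", "strand")]
  pre$name <- sprintf("p%d", 1:60)
  got <- cluster_premirnas(pre, max_gap = 3000)
  parent <- seq_len(nrow(pre))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(pre))) {
    for (j in seq_len(nrow(pre))) {
      if (i >= j || pre$strand[i] != pre$strand[j]) next
      gap <- max(pre$start[i], pre$start[j]) - min(pre$end[i], pre$end[j])
      if (gap < 3000) {
        ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(nrow(pre)), find, integer(1))
  got_in_input_order <- got$cluster_id[match(pre$name, got$name)]
  expect_equal(dplyr::n_distinct(paste(comp, got_in_input_order)),
               dplyr::n_distinct(comp))
  expect_equal(dplyr::n_distinct(got_in_input_order),
               dplyr::n_distinct(comp))
})

test_that("misRNA spans a spacer, never sits inside one pre-miRNA", {
  pre <- dplyr::bind_rows(iv(20000, 20080, "+", "pre1"),
                          iv(20280, 20360, "+", "pre2"))
  mature <- dplyr::bind_rows(
    dplyr::mutate(iv(20058, 20080, "+", "m1b"), parent = "pre1"),
    dplyr::mutate(iv(20280, 20302, "+", "m2a"), parent = "pre2"))
  cl <- cluster_premirnas(pre)
  spacer <- classify_misrna(iv(20058, 20302), cl, mature)
  expect_true(spacer$misrna)
  expect_true(spacer$misrna_mature_ends)
  inside <- classify_misrna(iv(20010, 20030), cl, mature)
  expect_false(inside$misrna)
  off_ends <- classify_misrna(iv(20100, 20250), cl, mature)
  expect_true(off_ends$misrna)          # soft criterion not enforced...
  expect_false(off_ends$misrna_mature_ends)
  strict <- classify_misrna(iv(20100, 20250), cl, mature,
                            require_mature_ends = TRUE)
  expect_false(strict$misrna)           # ...unless requested
})

test_that("the packaged truth-table world classifies exactly as labelled", {
  fw <- fixture_world()
  out <- classify_naprnas(fw$candidates, fw$annotations)
  kept <- exclude_annotated(fw$candidates, fw$annotations)
  out$excluded <- !(fw$candidates$name %in% kept$name)
  m <- match(fw$labels$name, out$name)
  expect_identical(out$slirna[m], fw$labels$slirna)
  expect_identical(out$snotron[m], fw$labels$snotron)
  expect_identical(out$misrna[m], fw$labels$misrna)
  expect_identical(out$excluded[m], fw$labels$excluded)
})

test_that("classification is invariant to candidate ordering", {
  fw <- fixture_world()
  out1 <- classify_naprnas(fw$candidates, fw$annotations)
  shuffled <- fw$candidates[rev(seq_len(nrow(fw$candidates))), ]
  out2 <- classify_naprnas(shuffled, fw$annotations)
  m <- match(out1$name, out2$name)
  expect_identical(out1$slirna, out2$slirna[m])
  expect_identical(out1$snotron, out2$snotron[m])
  expect_identical(out1$misrna, out2$misrna[m])
})
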