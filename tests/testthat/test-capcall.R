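chrC <- c(chrC = 3000L)
utr <- tibble::tibble(chrom = "chrC", start = 900L, end = 1200L,
                      name = "utr1", score = 0, strand = "+")

# build a replicate track with k 5'-end reads at `pos` plus given up/down
# neighbour counts and optional diffuse window noise
cap_track <- function(pos, k, up = 0, down = 0, noise_at = integer(),
                      sample = "r1") {
  mk <- function(p, m) {
    if (m == 0) return(NULL)
    tibble::tibble(chrom = "chrC", start = p, end = p + 50L, strand = "+",
                   has5p = TRUE, has3p = FALSE, sample = sample)[rep(1, m), ]
  }
  aln <- dplyr::bind_rows(mk(pos, k), mk(pos - 1L, up), mk(pos + 1L, down),
                          purrr::map(noise_at, mk, m = 1))
  build_tracks(aln, chrC)[[1]]
}

test_that("fold-change arithmetic follows the endCov/upCov definition", {
  t1 <- cap_track(1000L, 20, up = 5, down = 8)
  t2 <- cap_track(1000L, 20, up = 5, down = 8, sample = "r2")
  sites <- call_cap_sites(list(t1, t2), utr)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$endCov, 20)
  expect_equal(sites$upFC, 4)
  expect_equal(sites$downFC, 2.5)
  expect_equal(sites$replicates_supporting, 2L)
})

test_that("each printed criterion excludes a site on its own", {
  ok <- function(...) {
    t1 <- cap_track(1000L, ...)
    t2 <- cap_track(1000L, ..., sample = "r2")
    nrow(call_cap_sites(list(t1, t2), utr))
  }
  expect_equal(ok(20, up = 5, down = 5), 1L)
  expect_equal(ok(9, up = 0, down = 0), 0L)            # endCov < 10
  expect_equal(ok(20, up = 11, down = 0), 0L)          # upFC < 2
  expect_equal(ok(20, up = 0, down = 11), 0L)          # downFC < 2
  # replicate agreement: second replicate at a different position
  t1 <- cap_track(1000L, 20)
  t2 <- cap_track(1500L, 20, sample = "r2")
  expect_equal(nrow(call_cap_sites(list(t1, t2), utr)), 0L)
  # outside the 5'UTR
  t3 <- cap_track(2000L, 20)
  t4 <- cap_track(2000L, 20, sample = "r2")
  expect_equal(nrow(call_cap_sites(list(t3, t4), utr)), 0L)
  expect_error(call_cap_sites(list(t1, t2), NULL), "5'UTR")
})

test_that("binomial p-values equal the exhaustive tail sum", {
  # 15 site reads among 30 window reads under p0 = 1/201
  t1 <- cap_track(1000L, 15, noise_at = as.integer(seq(950, 1098, length.out = 15)))
  t2 <- cap_track(1000L, 15, noise_at = as.integer(seq(950, 1098, length.out = 15)),
                  sample = "r2")
  sites <- call_cap_sites(list(t1, t2), utr)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$pvalue, oracle_binom_tail(15, 30, 1 / 201),
               tolerance = 1e-12)
})

test_that("the enrichment p-value is anti-monotone in endCov at fixed N", {
  p <- vapply(5:25, function(k) {
    pbinom(k - 1, 30, 1 / 201, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("emitted cap sites re-verify all criteria independently", {
  withr::local_seed(55)
  mk_rep <- function(s) {
    aln <- random_alignments(400, 3000, s, max_len = 60)
    aln$chrom <- "chrC"; aln$strand <- "+"; aln$has5p <- TRUE
    # spike three strong sites
    spike <- tibble::tibble(chrom = "chrC", start = c(1000L, 1100L, 2500L),
                            end = c(1050L, 1150L, 2550L), strand = "+",
                            has5p = TRUE, has3p = FALSE,
                            sample = s)[rep(1:3, each = 25), ]
    build_tracks(dplyr::bind_rows(aln, spike), chrC)[[1]]
  }
  reps <- list(mk_rep("r1"), mk_rep("r2"))
  sites <- call_cap_sites(reps, utr)
  expect_gt(nrow(sites), 0L)
  for (i in seq_len(nrow(sites))) {
    pos <- sites$pos[i]
    n_support <- 0L
    for (tr in reps) {
      v <- track_vector(tr, "start5", "chrC", "+")
      endCov <- v[pos + 1]
      upCov <- if (pos >= 1) v[pos] else 0
      downCov <- if (pos + 2 <= length(v)) v[pos + 2] else 0
      N <- sum(v[max(1, pos + 1 - 100):min(length(v), pos + 1 + 100)])
      pv <- oracle_binom_tail(endCov, N, 1 / 201)
      if (endCov >= 10 && endCov / max(upCov, 1) >= 2 &&
          endCov / max(downCov, 1) >= 2 && pv < 0.05) {
        n_support <- n_support + 1L
      }
    }
    expect_gte(n_support, 2)
    expect_true(any(utr$start <= pos & pos < utr$end))
  }
})

test_that("cap/napRNA overlap comparison counts 5'-start coincidences", {
  naps <- tibble::tibble(chrom = "chrC", start = c(100L, 500L),
                         end = c(300L, 700L), strand = c("+", "-"))
  none <- tibble::tibble(chrom = "chrC", pos = 2900L, strand = "+")
  expect_equal(compare_cap_overlap(naps, none)$n_overlap, 0L)
  hit_plus <- tibble::tibble(chrom = "chrC", pos = 100L, strand = "+")
  expect_equal(compare_cap_overlap(naps, hit_plus)$fraction, 0.5)
  # minus-strand 5' start is end - 1
  hit_minus <- tibble::tibble(chrom = "chrC", pos = 699L, strand = "-")
  expect_equal(compare_cap_overlap(naps, hit_minus)$n_overlap, 1L)
  withr::local_seed(56)
  naps_r <- random_alignments(60, 3000)[, c("chrom", "start", "end", "strand")]
  naps_r$chrom <- "chrC"
  sites_r <- tibble::tibble(chrom = "chrC", pos = sample.int(3000, 40) - 1L,
                            strand = sample(c("+", "-"), 40, replace = TRUE))
  got <- compare_cap_overlap(naps_r, sites_r, tolerance = 2)
  p5 <- bio_end5(naps_r)
  want <- sum(vapply(seq_len(nrow(naps_r)), function(i) {
    any(sites_r$strand == naps_r$strand[i] & abs(sites_r$pos - p5[i]) <= 2)
  }, logical(1)))
  expect_equal(got$n_overlap, want)
})
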