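small_cfg <- function(...) {
  args <- list(genome_length = 60000, n_slirna = 2, n_snotron = 2,
               n_misrna = 1, n_pol3 = 1, n_cd = 1, n_haca = 1, n_plain = 1)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

test_that("the same seed reproduces world and library exactly", {
  w1 <- simulate_world(small_cfg(seed = 4))
  w2 <- simulate_world(small_cfg(seed = 4))
  expect_identical(w1$genome, w2$genome)
  expect_identical(w1$truth, w2$truth)
  l1 <- simulate_library(w1)
  l2 <- simulate_library(w2)
  expect_identical(l1$alignments, l2$alignments)
  expect_identical(l1$reads, l2$reads)
  w3 <- simulate_world(small_cfg(seed = 5))
  expect_false(identical(w1$genome, w3$genome))
})

test_that("truth geometry satisfies each class rule by construction", {
  w <- simulate_world(small_cfg(seed = 8))
  ann <- w$annotations
  truth <- w$truth
  sli <- truth[truth$class == "sliRNA", ]
  out <- classify_slirna(sli, ann$introns)
  expect_true(all(out$slirna))
  sno <- truth[truth$class == "snotron", ]
  expect_true(all(classify_snotron(sno, ann$snornas, ann$introns)$snotron))
  mis <- truth[truth$class == "misRNA", ]
  expect_true(all(classify_misrna(mis, cluster_premirnas(ann$pre_mirnas),
                                  ann$mature_mirnas)$misrna))
  seqs <- feature_seq(truth, w$genome)
  expect_true(all(vapply(seqs[truth$class == "pol3"], function(s)
    !is.null(detect_pol3(s)), logical(1))))
  expect_true(all(vapply(seqs[truth$class == "cd_box"], function(s)
    !is.null(detect_cd_box(s)), logical(1))))
  for (s in seqs[truth$class == "haca_box"]) {
    hits <- detect_haca_box(s)
    expect_false(is.null(hits))
    expect_true("polyA_pocket" %in% hits$motif_kind)
  }
})

test_that("every implanted annotation and truth interval is well-formed", {
  w <- simulate_world(small_cfg(seed = 12))
  expect_silent(napkit:::check_intervals(w$truth))
  for (nm in names(w$annotations)) {
    ann <- w$annotations[[nm]]
    if (!is.null(ann)) expect_silent(napkit:::check_intervals(ann))
  }
  expect_true(all(w$truth$end <= nchar(w$genome[[1]])))
  expect_true(all(w$truth$end - w$truth$start >= 100))
})

test_that("a genome too small for the requested features errors usefully", {
  expect_error(simulate_world(small_cfg(genome_length = 5000)),
               "need >= ")
})

test_that("full retention without background gives exact boundary counts", {
  cfg <- small_cfg(seed = 21, adapter_retention_prob = 1,
                   background_read_rate = 0, reads_per_end = 10,
                   n_samples = 1)
  w <- simulate_world(cfg)
  lib <- simulate_library(w)
  tr <- build_tracks(lib$alignments,
                     setNames(nchar(w$genome), names(w$genome)))[[1]]
  p5 <- bio_end5(w$truth)
  for (i in seq_len(nrow(w$truth))) {
    v <- track_vector(tr, "start5", w$truth$chrom[i], w$truth$strand[i])
    expect_equal(v[p5[i] + 1], 10)
  }
})

test_that("adapter retention matches its binomial expectation", {
  cfg <- small_cfg(seed = 22, reads_per_end = 100, n_samples = 2,
                   background_read_rate = 0)
  lib <- simulate_library(simulate_world(cfg))
  n <- nrow(lib$alignments)
  ends <- c(lib$alignments$has5p, lib$alignments$has3p)
  # exact binomial 99% interval around 0.5 for 2n Bernoulli draws
  bounds <- qbinom(c(0.005, 0.995), 2 * n, 0.5)
  expect_gte(sum(ends), bounds[1])
  expect_lte(sum(ends), bounds[2])
})

test_that("FASTQ read anatomy carries adapters and barcodes per flags", {
  cfg <- small_cfg(seed = 23, n_samples = 1, background_read_rate = 0)
  w <- simulate_world(cfg)
  lib <- simulate_library(w)
  reads <- lib$reads
  aln <- lib$alignments
  with5 <- which(aln$has5p)[1]
  expect_true(startsWith(reads$seq[with5], NAP_ADAPTER_5P))
  without5 <- which(!aln$has5p & !aln$has3p)[1]
  if (!is.na(without5)) {
    expect_false(startsWith(reads$seq[without5], NAP_ADAPTER_5P))
  }
  # trimming a flagged read recovers the genomic insert
  tr <- trim_reads(reads[with5, c("id", "seq")])
  insert <- feature_seq(aln[with5, ], w$genome)
  expect_equal(tr$insert_seq, unname(insert))
  expect_true(tr$has5p)
})

test_that("written worlds round-trip through the standard file formats", {
  out <- withr::local_tempdir()
  cfg <- small_cfg(seed = 24, n_samples = 2)
  w <- simulate_world(cfg)
  lib <- simulate_library(w, out_dir = out)
  expect_true(file.exists(file.path(out, "genome.fa")))
  expect_identical(read_genome(file.path(out, "genome.fa")), w$genome)
  truth_back <- read_bed(file.path(out, "truth.bed"))
  expect_equal(truth_back$start, w$truth$start)
  aln_back <- read_alignments(file.path(out, "sample1.alignments.tsv"))
  s1 <- lib$alignments[lib$alignments$sample == "sample1", ]
  expect_equal(aln_back$start, s1$start)
  expect_equal(aln_back$has5p, s1$has5p)
  fq <- read_fastq(file.path(out, "sample1.fastq"))
  expect_equal(nrow(fq), nrow(s1))
})

test_that("end jitter perturbs boundaries only when enabled", {
  cfg0 <- small_cfg(seed = 25, background_read_rate = 0, n_samples = 1)
  lib0 <- simulate_library(simulate_world(cfg0))
  truth <- simulate_world(cfg0)$truth
  starts <- unique(lib0$alignments$start[lib0$alignments$origin != "background"])
  expect_true(all(starts %in% truth$start))
  cfgj <- small_cfg(seed = 25, background_read_rate = 0, n_samples = 1,
                    end_jitter_prob = 0.6)
  libj <- simulate_library(simulate_world(cfgj))
  expect_false(all(libj$alignments$start %in% truth$start))
})
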