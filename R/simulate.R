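#' Simulation configuration
#'
#' Parameters of the synthetic test world: a random genome carrying
#' implanted truth napRNAs of every class (with their class-defining
#' geometry and motifs written into the genome), nested annotations
#' (snoRNAs inside introns, clustered pre-miRNAs with their mature
#' miRNAs, 5'UTRs, exclusion features), and per-sample read libraries in
#' which fragment ends at the true boundaries carry the specific adapters
#' with probability `adapter_retention_prob` (default 0.5, matching the
#' >50% per-end adapter retention of well-made boundary-tagged
#' libraries).
#'
#' @param seed Integer seed; the same seed reproduces the world and
#'   libraries byte-identically.
#' @param genome_length Genome size in nt (single contig `chr1`).
#' @param gc_fraction GC content of the random background.
#' @param n_samples Number of libraries to simulate.
#' @param n_slirna,n_snotron,n_misrna,n_pol3,n_cd,n_haca,n_plain Implant
#'   counts per class (`plain` = unclassified napRNAs).
#' @param n_utr5,n_exclusion Numbers of 5'UTR and exclusion (rRNA-like)
#'   annotation features.
#' @param length_range Length range (nt) for sliRNA/plain/Pol III inserts.
#' @param reads_per_end Full-length reads emitted per truth napRNA per
#'   sample.
#' @param adapter_retention_prob Probability that a read end carries its
#'   specific adapter.
#' @param background_read_rate Expected background reads per kb per
#'   sample.
#' @param end_jitter_prob Geometric parameter for boundary jitter
#'   (0 = exact boundaries, the default).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1, genome_length = 100000, gc_fraction = 0.5,
                       n_samples = 2, n_slirna = 3, n_snotron = 2,
                       n_misrna = 1, n_pol3 = 2, n_cd = 2, n_haca = 1,
                       n_plain = 3, n_utr5 = 2, n_exclusion = 2,
                       length_range = c(100, 600), reads_per_end = 30,
                       adapter_retention_prob = 0.5,
                       background_read_rate = 0.2, end_jitter_prob = 0) {
  stopifnot(gc_fraction >= 0, gc_fraction <= 1,
            adapter_retention_prob >= 0, adapter_retention_prob <= 1,
            end_jitter_prob >= 0, end_jitter_prob < 1,
            length_range[1] >= 100, length_range[2] >= length_range[1],
            n_samples >= 1, reads_per_end >= 0, background_read_rate >= 0)
  structure(as.list(environment()), class = "sim_config")
}

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Designed class sequences (genomic '+' sense). Motif instances follow the
# canonical consensi so the corresponding detector is positive by
# construction.
design_pol3_seq <- function(len, gc) {
  stopifnot(len >= 140)
  s <- rand_dna(len, gc)
  substr(s, 11, 22) <- "TAGCCTAACTTG"      # A box (TRGCNNARYNNG)
  substr(s, 121, 129) <- "GTTCGAATC"       # B box (GTTCRANNC)
  substr(s, len - 5, len) <- "ATTTTT"      # >= 4U terminator in last 6 nt
  s
}

design_cd_seq <- function(gc) {
  len <- 120
  s <- rand_dna(len, gc)
  substr(s, 1, 6) <- "GGCACG"              # 5' stem arm
  substr(s, 7, 13) <- "ATGATGA"            # C box (RUGAUGA)
  substr(s, 109, 112) <- "CTGA"            # D box, exact
  substr(s, 113, 114) <- "AA"
  substr(s, 115, 120) <- revcomp("GGCACG") # 3' stem arm
  s
}

design_haca_seq <- function() {
  # 140 nt: C-padding keeps the designed poly(A) loops unpairable (no U
  # outside the stems), so the pocket is unpaired in any pair-max fold.
  paste0(strrep("C", 26),
         "GGAGGCGC", "AAAAAAAA", revcomp("GGAGGCGC"), # 5' hairpin, 8-A pocket
         "AGATTA",                                     # H box (ANANNA)
         strrep("C", 57),
         "GGAGGCGG", "AACAAA", revcomp("GGAGGCGG"),    # 3' hairpin
         "ACA", "TT")                                  # ACA box + 2-nt tail
}

#' Simulate a complete napRNA test world
#'
#' Generates a random genome and implants, per class, truth napRNAs whose
#' geometry satisfies the corresponding classifier rule by construction:
#' sliRNAs coincide exactly with an implanted intron; snotrons run from an
#' intronic snoRNA end to within 4 nt of the host intron's opposite splice
#' site; misRNAs span the spacer between two clustered pre-miRNAs with
#' ends flush to the flanking mature miRNAs; Pol III / C-D / H-ACA
#' napRNAs have their promoter elements, boxes and stems written into the
#' genome. Interval-class implants alternate between strands; motif-class
#' implants sit on `+`.
#'
#' @param config A [sim_config()].
#' @return A list of class `"nap_world"`: `genome` (named character),
#'   `truth` (interval tibble with `class` column), `annotations` (an
#'   [annotation_set()]), `config`.
#' @export
simulate_world <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_world_impl(config))
}

simulate_world_impl <- function(cfg) {
  rlen <- function() sample(cfg$length_range[1]:cfg$length_range[2], 1)
  truth <- list(); introns <- list(); snornas <- list(); pre <- list()
  mature <- list(); utr5 <- list(); excl <- list(); segments <- list()
  cursor <- 1000L
  gap <- function() sample(500:1500, 1)
  place <- function(width) {
    at <- cursor
    cursor <<- cursor + as.integer(width) + gap()
    at
  }
  k <- 0L
  nm <- function(class, i) sprintf("%s_%d", class, i)

  for (i in seq_len(cfg$n_slirna)) {
    L <- rlen(); at <- place(L)
    strand <- if (i %% 2 == 1) "+" else "-"
    introns[[length(introns) + 1]] <- tibble(
      chrom = "chr1", start = at, end = at + L,
      name = paste0("intron_", nm("sli", i)), score = 0, strand = strand)
    truth[[length(truth) + 1]] <- tibble(
      chrom = "chr1", start = at, end = at + L, name = nm("sli", i),
      score = 0, strand = strand, class = "sliRNA")
  }
  for (i in seq_len(cfg$n_snotron)) {
    L <- max(150L, rlen()); at <- place(L)
    strand <- if (i %% 2 == 1) "+" else "-"
    iname <- paste0("intron_", nm("snotron", i))
    sname <- paste0("snoRNA_", nm("snotron", i))
    introns[[length(introns) + 1]] <- tibble(
      chrom = "chr1", start = at, end = at + L, name = iname, score = 0,
      strand = strand)
    if (strand == "+") {
      sno <- c(at + 30L, at + 110L)
      napv <- c(at + 30L, at + L - 4L) # 3' end 4 nt inside the 3'SS
    } else {
      sno <- c(at + L - 110L, at + L - 30L)
      napv <- c(at + 4L, at + L - 30L)
    }
    snornas[[length(snornas) + 1]] <- tibble(
      chrom = "chr1", start = sno[1], end = sno[2], name = sname, score = 0,
      strand = strand, subtype = "CD")
    truth[[length(truth) + 1]] <- tibble(
      chrom = "chr1", start = napv[1], end = napv[2], name = nm("snotron", i),
      score = 0, strand = strand, class = "snotron")
  }
  for (i in seq_len(cfg$n_misrna)) {
    spacer <- 200L
    at <- place(160L + spacer)
    strand <- if (i %% 2 == 1) "+" else "-"
    p1 <- c(at, at + 80L); p2 <- c(at + 80L + spacer, at + 160L + spacer)
    pn1 <- paste0("pre_", nm("mis", i), "a"); pn2 <- paste0("pre_", nm("mis", i), "b")
    pre[[length(pre) + 1]] <- tibble(
      chrom = "chr1", start = c(p1[1], p2[1]), end = c(p1[2], p2[2]),
      name = c(pn1, pn2), score = 0, strand = strand)
    mature[[length(mature) + 1]] <- tibble(
      chrom = "chr1",
      start = c(p1[1] + 10L, p1[2] - 22L, p2[1], p2[2] - 32L),
      end = c(p1[1] + 32L, p1[2], p2[1] + 22L, p2[2] - 10L),
      name = paste0("mat_", nm("mis", i), c("_1a", "_1b", "_2a", "_2b")),
      score = 0, strand = strand,
      parent = c(pn1, pn1, pn2, pn2))
    truth[[length(truth) + 1]] <- tibble(
      chrom = "chr1", start = p1[2] - 22L, end = p2[1] + 22L,
      name = nm("mis", i), score = 0, strand = strand, class = "misRNA")
  }
  for (i in seq_len(cfg$n_pol3)) {
    L <- max(150L, rlen()); at <- place(L)
    segments[[length(segments) + 1]] <- list(at = at,
                                             seq = design_pol3_seq(L, cfg$gc_fraction))
    truth[[length(truth) + 1]] <- tibble(
      chrom = "chr1", start = at, end = at + L, name = nm("pol3", i),
      score = 0, strand = "+", class = "pol3")
  }
  for (i in seq_len(cfg$n_cd)) {
    at <- place(120L)
    segments[[length(segments) + 1]] <- list(at = at,
                                             seq = design_cd_seq(cfg$gc_fraction))
    truth[[length(truth) + 1]] <- tibble(
      chrom = "chr1", start = at, end = at + 120L, name = nm("cd", i),
      score = 0, strand = "+", class = "cd_box")
  }
  for (i in seq_len(cfg$n_haca)) {
    sq <- design_haca_seq(); at <- place(nchar(sq))
    segments[[length(segments) + 1]] <- list(at = at, seq = sq)
    truth[[length(truth) + 1]] <- tibble(
      chrom = "chr1", start = at, end = at + nchar(sq), name = nm("haca", i),
      score = 0, strand = "+", class = "haca_box")
  }
  for (i in seq_len(cfg$n_plain)) {
    L <- rlen(); at <- place(L)
    strand <- if (i %% 2 == 1) "+" else "-"
    truth[[length(truth) + 1]] <- tibble(
      chrom = "chr1", start = at, end = at + L, name = nm("plain", i),
      score = 0, strand = strand, class = "plain")
  }
  for (i in seq_len(cfg$n_utr5)) {
    at <- place(300L)
    utr5[[length(utr5) + 1]] <- tibble(
      chrom = "chr1", start = at, end = at + 300L,
      name = paste0("utr5_", i), score = 0, strand = if (i %% 2 == 1) "+" else "-")
  }
  for (i in seq_len(cfg$n_exclusion)) {
    at <- place(150L)
    excl[[length(excl) + 1]] <- tibble(
      chrom = "chr1", start = at, end = at + 150L,
      name = paste0("rRNA_", i), score = 0, strand = if (i %% 2 == 1) "+" else "-")
  }

  needed <- cursor + 1000L
  if (needed > cfg$genome_length) {
    abort(sprintf("genome_length %d too small for requested features; need >= %d",
                  cfg$genome_length, needed))
  }
  genome <- rand_dna(cfg$genome_length, cfg$gc_fraction)
  for (seg in segments) {
    substr(genome, seg$at + 1L, seg$at + nchar(seg$seq)) <- seg$seq
  }
  bind0 <- function(x) if (length(x)) dplyr::bind_rows(x) else NULL
  structure(list(
    genome = c(chr1 = genome),
    truth = dplyr::bind_rows(truth),
    annotations = annotation_set(
      introns = bind0(introns), snornas = bind0(snornas),
      pre_mirnas = bind0(pre), mature_mirnas = bind0(mature),
      utr5 = bind0(utr5), exclusion = bind0(excl)),
    config = cfg), class = "nap_world")
}

#' @export
print.nap_world <- function(x, ...) {
  cat(sprintf("<nap_world> %d-nt genome, %d truth napRNAs (%s)\n",
              nchar(x$genome[[1]]), nrow(x$truth),
              paste(names(table(x$truth$class)), table(x$truth$class),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

random_barcode <- function(n) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = ""),
    character(1))
}

#' Simulate adapter-flagged read libraries from a world
#'
#' For every truth napRNA and sample, emits `reads_per_end` full-length
#' reads whose ends carry the specific adapters independently with
#' probability `adapter_retention_prob`; background reads are scattered at
#' `background_read_rate` per kb. Because the simulator knows the genomic
#' origin of every read, it emits the alignment table directly (exact
#' coordinates; read mapping is outside napkit's scope) alongside FASTQ
#' records with the full read anatomy
#' `[5' adapter][N6][insert][N6][3' adapter]` for exercising the trimmer.
#'
#' @param world A [simulate_world()] result.
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `truth.bed`, `annotations/*.bed`, `sample<k>.fastq`,
#'   `sample<k>.alignments.tsv` and a `config.txt` echo.
#' @return A list of class `"nap_library"`: `alignments` (all samples),
#'   `reads` (FASTQ-level tibble), `world`, and `files` when written.
#' @export
simulate_library <- function(world, out_dir = NULL) {
  stopifnot(inherits(world, "nap_world"))
  cfg <- world$config
  lib <- withr::with_seed(cfg$seed + 1L, simulate_library_impl(world, cfg))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "annotations"), showWarnings = FALSE)
    files <- c(genome = file.path(out_dir, "genome.fa"),
               truth = file.path(out_dir, "truth.bed"))
    write_genome(world$genome, files[["genome"]])
    tr <- world$truth
    tr$name <- paste(tr$name, tr$class, sep = "|")
    write_bed(tr, files[["truth"]])
    for (nmn in names(world$annotations)) {
      ann <- world$annotations[[nmn]]
      if (is.null(ann) || !nrow(ann)) next
      f <- file.path(out_dir, "annotations", paste0(nmn, ".bed"))
      write_bed(ann, f)
      files[[nmn]] <- f
    }
    for (s in unique(lib$alignments$sample)) {
      fq <- file.path(out_dir, paste0(s, ".fastq"))
      tsv <- file.path(out_dir, paste0(s, ".alignments.tsv"))
      write_fastq(lib$reads[lib$reads$sample == s, ], fq)
      write_alignments(lib$alignments[lib$alignments$sample == s, ], tsv)
      files[[paste0(s, "_fastq")]] <- fq
      files[[paste0(s, "_alignments")]] <- tsv
    }
    cfg_path <- file.path(out_dir, "config.txt")
    writeLines(c(napkit_stamp(),
                 paste0(names(unclass(cfg)), " = ",
                        vapply(unclass(cfg), function(v)
                          paste(v, collapse = ","), character(1)))),
               cfg_path)
    files[["config"]] <- cfg_path
    lib$files <- files
  }
  lib
}

simulate_library_impl <- function(world, cfg) {
  glen <- nchar(world$genome[[1]])
  all_aln <- list()
  for (si in seq_len(cfg$n_samples)) {
    sname <- paste0("sample", si)
    tr <- world$truth
    n_tr <- nrow(tr) * cfg$reads_per_end
    idx <- rep(seq_len(nrow(tr)), each = cfg$reads_per_end)
    start <- tr$start[idx]; end <- tr$end[idx]
    if (cfg$end_jitter_prob > 0) {
      j1 <- stats::rgeom(n_tr, 1 - cfg$end_jitter_prob) *
        sample(c(-1L, 1L), n_tr, replace = TRUE)
      j2 <- stats::rgeom(n_tr, 1 - cfg$end_jitter_prob) *
        sample(c(-1L, 1L), n_tr, replace = TRUE)
      start <- pmax(0L, pmin(start + j1, end - 20L))
      end <- pmax(start + 20L, pmin(end + j2, glen))
    }
    sig <- tibble(chrom = "chr1", start = start, end = end,
                  strand = tr$strand[idx],
                  has5p = rbinom(n_tr, 1, cfg$adapter_retention_prob) == 1,
                  has3p = rbinom(n_tr, 1, cfg$adapter_retention_prob) == 1,
                  sample = sname, origin = tr$name[idx])
    n_bg <- rpois(1, cfg$background_read_rate * glen / 1000)
    if (n_bg > 0) {
      blen <- sample(50:200, n_bg, replace = TRUE)
      bstart <- vapply(blen, function(L) sample.int(glen - L, 1) - 1L,
                       integer(1))
      bg <- tibble(chrom = "chr1", start = bstart, end = bstart + blen,
                   strand = sample(c("+", "-"), n_bg, replace = TRUE),
                   has5p = rbinom(n_bg, 1, cfg$adapter_retention_prob) == 1,
                   has3p = rbinom(n_bg, 1, cfg$adapter_retention_prob) == 1,
                   sample = sname, origin = "background")
      sig <- dplyr::bind_rows(sig, bg)
    }
    sig$id <- sprintf("%s_r%06d", sname, seq_len(nrow(sig)))
    all_aln[[si]] <- sig
  }
  aln <- dplyr::bind_rows(all_aln)
  insert <- feature_seq(aln, world$genome, as = "dna")
  bc5 <- random_barcode(nrow(aln)); bc3 <- random_barcode(nrow(aln))
  seqs <- paste0(ifelse(aln$has5p, paste0(NAP_ADAPTER_5P, bc5), ""),
                 insert,
                 ifelse(aln$has3p, paste0(bc3, NAP_ADAPTER_3P), ""))
  reads <- tibble(id = paste0(aln$id, " np:5p=", as.integer(aln$has5p),
                              ";3p=", as.integer(aln$has3p)),
                  seq = seqs, qual = strrep("I", nchar(seqs)),
                  sample = aln$sample)
  structure(list(alignments = aln[c("id", "chrom", "start", "end", "strand",
                                    "has5p", "has3p", "sample", "origin")],
                 reads = reads, world = world),
            class = "nap_library")
}

#' @export
print.nap_library <- function(x, ...) {
  cat(sprintf("<nap_library> %d reads across %d sample(s)\n",
              nrow(x$alignments), length(unique(x$alignments$sample))))
  invisible(x)
}
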