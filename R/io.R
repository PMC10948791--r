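#' Read a genome FASTA with per-contig access
#'
#' @param path FASTA path.
#' @return A named character vector of uppercase contig sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write contig sequences as FASTA
#'
#' @param genome Named character vector (or DNAStringSet) of contigs.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(unlist(genome))
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Extract strand-aware feature sequences from a genome
#'
#' Returns the sense-strand (transcribed) sequence of each interval:
#' reverse-complemented for `-` features.
#'
#' @param x Interval tibble.
#' @param genome Named character vector from [read_genome()].
#' @param as Either `"dna"` (default, T alphabet) or `"rna"` (U alphabet).
#' @return Character vector of sequences, named by `x$name` when present.
#' @export
feature_seq <- function(x, genome, as = c("dna", "rna")) {
  as <- match.arg(as)
  check_intervals(x)
  missing <- setdiff(unique(x$chrom), names(genome))
  if (length(missing)) {
    abort(paste0("chromosome(s) absent from genome: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(x$end > nchar(genome)[match(x$chrom, names(genome))])) {
    abort("interval extends beyond its contig")
  }
  seqs <- substr(genome[x$chrom], x$start + 1L, x$end)
  minus <- x$strand == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[minus])))
  }
  if (as == "rna") seqs <- chartr("Tt", "Uu", seqs)
  if ("name" %in% names(x)) names(seqs) <- x$name else names(seqs) <- NULL
  seqs
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ path (uncompressed or gzip).
#' @return A tibble with columns `id` (full description line), `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # the metadata-column note from the FASTQ parser is irrelevant here
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tibble(id = names(x),
         seq = as.character(x),
         qual = as.character(Biostrings::quality(x)))
}

#' Write a read tibble as FASTQ
#'
#' @param reads Tibble with `id`, `seq` and optionally `qual` (defaults to
#'   a constant high quality).
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else
    strrep("I", nchar(reads$seq))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(qual))
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read aligned, adapter-flagged reads
#'
#' Accepts either the 7-column napkit alignment TSV
#' (`chrom start end strand has5p has3p sample`, with optional `id`) or a
#' SAM text file in which the footprint is taken from POS + CIGAR reference
#' width and the adapter flags from `np:Z:5p=<0|1>;3p=<0|1>` tags.
#'
#' @param path Input path.
#' @param format `"tsv"` (default) or `"sam"`.
#' @param sample Sample label used for SAM input (TSV carries its own).
#' @return Tibble of aligned read records with 0-based half-open footprints.
#' @export
read_alignments <- function(path, format = c("tsv", "sam"), sample = "sample1") {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
    need <- c("chrom", "start", "end", "strand", "has5p", "has3p", "sample")
    missing <- setdiff(need, names(out))
    if (length(missing)) {
      abort(paste0("alignment TSV missing column(s): ",
                   paste(missing, collapse = ", ")))
    }
    out$has5p <- as.logical(out$has5p)
    out$has3p <- as.logical(out$has3p)
    check_intervals(out, what = "alignments")
    return(as_tibble(out))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines)) {
    return(tibble(id = character(), chrom = character(), start = integer(),
                  end = integer(), strand = character(), has5p = logical(),
                  has3p = logical(), sample = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- as.integer(vapply(f, `[[`, "", 2))
  pos1 <- as.integer(vapply(f, `[[`, "", 4))
  cigar <- vapply(f, `[[`, "", 6)
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  np <- vapply(f, function(x) {
    hit <- grep("^np:Z:", x[-(1:11)], value = TRUE)
    if (length(hit)) sub("^np:Z:", "", hit[1]) else ""
  }, "")
  out <- tibble(
    id = vapply(f, `[[`, "", 1),
    chrom = vapply(f, `[[`, "", 3),
    start = pos1 - 1L,
    end = pos1 - 1L + width,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    has5p = grepl("5p=1", np),
    has3p = grepl("3p=1", np),
    sample = sample
  )
  mapped <- bitwAnd(flag, 4L) == 0L
  out <- out[mapped & out$chrom != "*", , drop = FALSE]
  check_intervals(out, what = "SAM alignments")
  out
}

#' Write per-sample alignment records as the napkit TSV
#'
#' @param alignments Tibble from [read_alignments()] or [simulate_library()].
#' @param path Output path.
#' @export
write_alignments <- function(alignments, path) {
  check_intervals(alignments, what = "alignments")
  readr::write_tsv(alignments, path, progress = FALSE)
  invisible(path)
}
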