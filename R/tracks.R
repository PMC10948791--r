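#' Build strand-specific signal tracks from aligned reads
#'
#' Converts aligned, adapter-flagged read records into per-(chromosome,
#' strand) arrays of read coverage (`cov`), adapter-verified 5'-start
#' counts (`start5`) and 3'-end counts (`end3`). Coverage is incremented
#' over the full footprint `[start, end)` of every read; `start5` is
#' incremented at the biological 5'-end position only for reads with
#' `has5p`, and `end3` at the biological 3'-end position only for reads
#' with `has3p`. One track set is built per `sample`.
#'
#' @param alignments Tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `has5p`, `has3p`, `sample` (see [read_alignments()]).
#' @param chrom_sizes Named integer vector of contig lengths.
#' @return A named list (one element per sample) of `nap_tracks` objects.
#' @export
build_tracks <- function(alignments, chrom_sizes) {
  check_intervals(alignments, what = "alignments")
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)))
  missing <- setdiff(unique(alignments$chrom), names(chrom_sizes))
  if (length(missing)) {
    abort(paste0("alignments on unknown contig(s): ",
                 paste(missing, collapse = ", ")))
  }
  over <- alignments$end > chrom_sizes[alignments$chrom]
  if (any(over)) {
    id <- if ("id" %in% names(alignments)) alignments$id[which(over)[1]]
          else paste0("row ", which(over)[1])
    abort(paste0("read beyond contig bounds: ", id))
  }
  samples <- sort(unique(alignments$sample))
  out <- lapply(samples, function(s) {
    rd <- alignments[alignments$sample == s, , drop = FALSE]
    keys <- unique(paste(rd$chrom, rd$strand, sep = ":"))
    tr <- list(cov = list(), start5 = list(), end3 = list())
    for (key in sort(keys)) {
      parts <- strsplit(key, ":", fixed = TRUE)[[1]]
      chrom <- parts[1]; strand <- parts[2]
      n <- as.integer(chrom_sizes[[chrom]])
      g <- rd[rd$chrom == chrom & rd$strand == strand, , drop = FALSE]
      d1 <- tabulate(g$start + 1L, nbins = n + 1L)
      d2 <- tabulate(g$end + 1L, nbins = n + 1L)
      cov <- cumsum(d1 - d2)[seq_len(n)]
      p5 <- bio_end5(g); p3 <- bio_end3(g)
      s5 <- tabulate(p5[g$has5p] + 1L, nbins = n)
      e3 <- tabulate(p3[g$has3p] + 1L, nbins = n)
      tr$cov[[key]] <- cov
      tr$start5[[key]] <- s5
      tr$end3[[key]] <- e3
    }
    structure(list(cov = tr$cov, start5 = tr$start5, end3 = tr$end3,
                   library_size = nrow(rd), chrom_sizes = chrom_sizes,
                   sample = s, rpm = FALSE),
              class = "nap_tracks")
  })
  names(out) <- samples
  out
}

track_key <- function(chrom, strand) paste(chrom, strand, sep = ":")

#' Extract one signal vector from a track set
#'
#' @param track A `nap_tracks` object.
#' @param what One of `"cov"`, `"start5"`, `"end3"` (append `"_rpm"` after
#'   [rpm_normalize()]).
#' @param chrom,strand Which track.
#' @return Numeric vector of per-position values (length = contig length);
#'   all zero if no reads mapped there.
#' @export
track_vector <- function(track, what, chrom, strand) {
  stopifnot(inherits(track, "nap_tracks"))
  key <- track_key(chrom, strand)
  v <- track[[what]][[key]]
  if (is.null(v)) {
    if (!chrom %in% names(track$chrom_sizes)) {
      abort(paste0("unknown contig: ", chrom))
    }
    v <- numeric(track$chrom_sizes[[chrom]])
  }
  v
}

#' @export
print.nap_tracks <- function(x, ...) {
  cat(sprintf("<nap_tracks> sample '%s': %d mapped reads, %d contig-strand track(s)%s\n",
              x$sample, x$library_size, length(x$cov),
              if (x$rpm) ", RPM-normalized" else ""))
  invisible(x)
}

#' Reads-per-million normalization of a track set
#'
#' Multiplies every signal by `1e6 / library_size`, storing the normalized
#' arrays alongside the raw integer counts (as `cov_rpm`, `start5_rpm`,
#' `end3_rpm`).
#'
#' @param track A `nap_tracks` object with `library_size > 0`.
#' @return The track object with RPM arrays added and `rpm = TRUE`.
#' @export
rpm_normalize <- function(track) {
  stopifnot(inherits(track, "nap_tracks"))
  if (track$library_size <= 0) abort("library_size is zero: cannot normalize")
  f <- 1e6 / track$library_size
  track$cov_rpm <- lapply(track$cov, function(v) v * f)
  track$start5_rpm <- lapply(track$start5, function(v) v * f)
  track$end3_rpm <- lapply(track$end3, function(v) v * f)
  track$rpm <- TRUE
  track
}

#' Tidy a track set into a long tibble
#'
#' @param x A `nap_tracks` object.
#' @param ... Unused.
#' @return Tibble with one row per position where any signal is nonzero:
#'   `sample`, `chrom`, `strand`, `pos` (0-based), `cov`, `start5`, `end3`.
#' @method tidy nap_tracks
#' @export
tidy.nap_tracks <- function(x, ...) {
  rows <- purrr::map(names(x$cov), function(key) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    cov <- x$cov[[key]]; s5 <- x$start5[[key]]; e3 <- x$end3[[key]]
    nz <- which(cov != 0 | s5 != 0 | e3 != 0)
    tibble(sample = x$sample, chrom = parts[1], strand = parts[2],
           pos = nz - 1L, cov = cov[nz], start5 = s5[nz], end3 = e3[nz])
  })
  dplyr::bind_rows(rows)
}

#' Write a track set as bedGraph files
#'
#' One file per signal per strand
#' (`<prefix>.<cov|start5|end3>.<plus|minus>.bedGraph`), each with a napkit
#' header comment; RPM values are written when the track is normalized.
#'
#' @param track A `nap_tracks` object.
#' @param prefix Output path prefix.
#' @return Character vector of files written (invisibly).
#' @export
write_bedgraph <- function(track, prefix) {
  stopifnot(inherits(track, "nap_tracks"))
  signals <- c("cov", "start5", "end3")
  use <- if (track$rpm) paste0(signals, "_rpm") else signals
  files <- character(0)
  for (i in seq_along(signals)) {
    for (strand in c("+", "-")) {
      sname <- if (strand == "+") "plus" else "minus"
      path <- sprintf("%s.%s.%s.bedGraph", prefix, signals[i], sname)
      con <- file(path, "w")
      writeLines(napkit_stamp(list(sample = track$sample, signal = signals[i],
                                   strand = strand, rpm = track$rpm)), con)
      for (key in names(track[[use[i]]])) {
        parts <- strsplit(key, ":", fixed = TRUE)[[1]]
        if (parts[2] != strand) next
        v <- track[[use[i]]][[key]]
        r <- rle(v)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths
        keep <- r$values != 0
        if (any(keep)) {
          writeLines(sprintf("%s\t%d\t%d\t%s", parts[1], starts[keep],
                             ends[keep],
                             format(r$values[keep], trim = TRUE,
                                    scientific = FALSE)), con)
        }
      }
      close(con)
      files <- c(files, path)
    }
  }
  invisible(files)
}
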