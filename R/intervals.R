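#' Genomic intervals as tibbles
#'
#' All coordinates in napkit are 0-based half-open (BED convention) and
#' stranded. An interval table is any tibble with at least the columns
#' `chrom` (character), `start` (integer, 0-based inclusive), `end`
#' (integer, 0-based exclusive) and `strand` (`"+"` or `"-"`); `name` and
#' `score` columns are carried along when present. 1-based coordinates
#' appear only at serialization boundaries, never internally.
#'
#' @name intervals
NULL

check_intervals <- function(x, strict_strand = TRUE, what = "interval table") {
  need <- c("chrom", "start", "end", "strand")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(paste0(what, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$start < 0)) abort(paste0(what, ": negative start coordinate"))
  if (any(x$end <= x$start)) {
    bad <- which(x$end <= x$start)[1]
    abort(sprintf("%s: zero- or negative-length interval at row %d (start=%d end=%d)",
                  what, bad, x$start[bad], x$end[bad]))
  }
  ok <- x$strand %in% c("+", "-") | (!strict_strand & x$strand == ".")
  if (!all(ok)) {
    abort(sprintf("%s: invalid strand '%s' at row %d", what,
                  x$strand[which(!ok)[1]], which(!ok)[1]))
  }
  invisible(x)
}

#' Read a BED6 file into an interval tibble
#'
#' @param path Path to a BED file with at least 6 tab-separated columns.
#'   Lines starting with `#`, `track` or `browser` are skipped.
#' @param feature_kind Optional label stored in a `feature_kind` column
#'   (e.g. `"intron"`, `"snoRNA"`).
#' @param strand_required If `TRUE` (default), a `.` strand is rejected:
#'   every napkit analysis is strand-specific.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (and `feature_kind` if given), coordinates exactly as in the
#'   file (0-based half-open).
#' @export
read_bed <- function(path, feature_kind = NULL, strand_required = TRUE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (!length(lines)) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character())
    if (!is.null(feature_kind)) out$feature_kind <- character()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    bad <- which(nf < 6)[1]
    abort(sprintf("malformed BED line %d in %s: %d field(s), need >= 6",
                  line_no[bad], path, nf[bad]))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    abort(sprintf("malformed BED line %d in %s: non-numeric coordinates",
                  line_no[bad], path))
  }
  out <- tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = start,
    end = end,
    name = vapply(fields, `[[`, "", 4),
    score = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5))),
    strand = vapply(fields, `[[`, "", 6)
  )
  bad_strand <- !out$strand %in% c("+", "-", ".")
  if (any(bad_strand)) {
    abort(sprintf("malformed BED line %d in %s: strand '%s'",
                  line_no[which(bad_strand)[1]], path,
                  out$strand[which(bad_strand)[1]]))
  }
  if (strand_required && any(out$strand == ".")) {
    abort(sprintf("BED line %d in %s: '.' strand not allowed for strand-specific features",
                  line_no[which(out$strand == ".")[1]], path))
  }
  check_intervals(out, strict_strand = strand_required,
                  what = paste0("BED file ", path))
  if (!is.null(feature_kind)) out$feature_kind <- feature_kind
  out
}

#' Write an interval tibble as BED6
#'
#' @param x Interval tibble (`name`/`score` filled with `"."`/`0` if absent).
#' @param path Output path.
#' @param header If `TRUE`, prepend a `#` comment with the napkit version.
#'   Off by default so that `read_bed()` / `write_bed()` round-trips are
#'   byte-identical.
#' @export
write_bed <- function(x, path, header = FALSE) {
  check_intervals(x, strict_strand = FALSE, what = "BED output")
  name <- if ("name" %in% names(x)) x$name else rep(".", nrow(x))
  score <- if ("score" %in% names(x)) x$score else rep(0, nrow(x))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, x$start, x$end,
                   name, format(score, trim = TRUE, scientific = FALSE),
                   x$strand)
  if (header) lines <- c(napkit_stamp(list(n = nrow(x))), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Overlap queries against an interval table
#'
#' Finds all features sharing at least one nucleotide with each query,
#' BEDtools `intersect -s`-style when `same_strand = TRUE`. Backed by
#' IRanges; results are ordered deterministically by query row, then
#' feature start, end and name.
#'
#' @param query,features Interval tibbles.
#' @param same_strand Require matching strand (default `TRUE`).
#' @return A tibble with one row per (query, feature) overlap: `query_row`
#'   plus all feature columns.
#' @export
overlap_features <- function(query, features, same_strand = TRUE) {
  check_intervals(query, what = "query")
  check_intervals(features, what = "features")
  empty <- dplyr::bind_cols(tibble(query_row = integer()),
                            features[0, , drop = FALSE])
  if (nrow(query) == 0 || nrow(features) == 0) return(empty)
  # IRanges is 1-based closed; [start, end) maps to [start + 1, end]
  q <- IRanges::IRanges(query$start + 1L, query$end)
  f <- IRanges::IRanges(features$start + 1L, features$end)
  hits <- IRanges::findOverlaps(q, f)
  qi <- S4Vectors::queryHits(hits)
  fi <- S4Vectors::subjectHits(hits)
  keep <- query$chrom[qi] == features$chrom[fi]
  if (same_strand) keep <- keep & query$strand[qi] == features$strand[fi]
  qi <- qi[keep]; fi <- fi[keep]
  if (!length(qi)) return(empty)
  out <- dplyr::bind_cols(tibble(query_row = qi), features[fi, , drop = FALSE])
  ord <- if ("name" %in% names(out)) {
    order(out$query_row, out$start, out$end, out$name)
  } else {
    order(out$query_row, out$start, out$end)
  }
  out[ord, , drop = FALSE]
}

#' Biological end positions of stranded intervals
#'
#' The biological 5' end of `[start, end)` is `start` on `+` and `end - 1`
#' on `-`; the biological 3' end is `end - 1` on `+` and `start` on `-`.
#' Classifier distance rules all operate on these per-strand ends.
#'
#' @param x Interval tibble.
#' @return Integer vector of 0-based positions.
#' @export
bio_end5 <- function(x) {
  check_intervals(x)
  ifelse(x$strand == "+", x$start, x$end - 1L)
}

#' @rdname bio_end5
#' @export
bio_end3 <- function(x) {
  check_intervals(x)
  ifelse(x$strand == "+", x$end - 1L, x$start)
}

#' Signed 5'-to-3' distance between two positions
#'
#' Distance from reference position `b` to position `a`, oriented along the
#' feature strand: positive means `a` lies downstream (3') of `b`, negative
#' upstream. On `+` this is `a - b`; on `-` it is `b - a`.
#'
#' @param a,b 0-based positions (vectorized).
#' @param strand `"+"` or `"-"` (recycled).
#' @param chrom_a,chrom_b Optional chromosome names; mixing chromosomes is
#'   an error.
#' @return Signed integer distance(s) in nt.
#' @export
end_distance <- function(a, b, strand = "+", chrom_a = NULL, chrom_b = NULL) {
  if (!is.null(chrom_a) && !is.null(chrom_b) && any(chrom_a != chrom_b)) {
    abort("end_distance: positions on different chromosomes")
  }
  if (!all(strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  ifelse(strand == "+", a - b, b - a)
}

#' Bundle annotation tables for classification
#'
#' @param introns,snornas,pre_mirnas,mature_mirnas,utr5,exclusion Interval
#'   tibbles (any may be `NULL`). `snornas` may carry a `subtype` column
#'   (`"CD"` or `"HACA"`); `mature_mirnas` may carry a `parent` column naming
#'   the host pre-miRNA, in which case containment is checked.
#' @return A list with class `"annotation_set"`.
#' @export
annotation_set <- function(introns = NULL, snornas = NULL, pre_mirnas = NULL,
                           mature_mirnas = NULL, utr5 = NULL,
                           exclusion = NULL) {
  sets <- list(introns = introns, snornas = snornas, pre_mirnas = pre_mirnas,
               mature_mirnas = mature_mirnas, utr5 = utr5,
               exclusion = exclusion)
  for (nm in names(sets)) {
    if (!is.null(sets[[nm]])) check_intervals(sets[[nm]], what = nm)
  }
  if (!is.null(mature_mirnas) && !is.null(pre_mirnas) &&
      "parent" %in% names(mature_mirnas) && nrow(mature_mirnas)) {
    idx <- match(mature_mirnas$parent, pre_mirnas$name)
    if (anyNA(idx)) {
      abort(sprintf("mature miRNA '%s' names unknown parent '%s'",
                    mature_mirnas$name[which(is.na(idx))[1]],
                    mature_mirnas$parent[which(is.na(idx))[1]]))
    }
    contained <- mature_mirnas$start >= pre_mirnas$start[idx] &
      mature_mirnas$end <= pre_mirnas$end[idx] &
      mature_mirnas$chrom == pre_mirnas$chrom[idx] &
      mature_mirnas$strand == pre_mirnas$strand[idx]
    if (!all(contained)) {
      abort(sprintf("mature miRNA '%s' is not contained in its parent pre-miRNA",
                    mature_mirnas$name[which(!contained)[1]]))
    }
  }
  structure(sets, class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set>\n")
  for (nm in names(x)) {
    n <- if (is.null(x[[nm]])) "absent" else paste0(nrow(x[[nm]]), " features")
    cat(sprintf("  %-14s %s\n", nm, n))
  }
  invisible(x)
}
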