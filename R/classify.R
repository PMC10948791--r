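#' Remove napRNAs overlapping known annotations
#'
#' Novelty filter: drops calls sharing at least one nucleotide, on the same
#' strand, with any exclusion feature (rRNA, tRNA, known snoRNA, CDS, ...).
#'
#' @param naprnas Interval tibble of calls.
#' @param exclusion Interval tibble of features to exclude against (or an
#'   [annotation_set()], whose `exclusion` element is used).
#' @return The novel subset of `naprnas`.
#' @export
exclude_annotated <- function(naprnas, exclusion) {
  if (inherits(exclusion, "annotation_set")) exclusion <- exclusion$exclusion
  if (is.null(exclusion) || !nrow(exclusion)) return(naprnas)
  hits <- overlap_features(naprnas, exclusion, same_strand = TRUE)
  if (!nrow(hits)) return(naprnas)
  naprnas[-unique(hits$query_row), , drop = FALSE]
}

#' Classify napRNAs as stable linear intron RNAs (sliRNAs)
#'
#' A call is an sliRNA when a same-strand known intron shares both its
#' biological 5'-start and 3'-end with the call, each within
#' `end_tolerance` nt.
#'
#' @param naprnas Interval tibble of calls.
#' @param introns Interval tibble of known introns.
#' @param end_tolerance Per-end tolerance in nt (default 0 = exact).
#' @return `naprnas` with logical `slirna` and evidence column
#'   `slirna_intron` (matched intron name or `NA`).
#' @export
classify_slirna <- function(naprnas, introns, end_tolerance = 0) {
  check_intervals(naprnas, what = "naprnas")
  check_intervals(introns, what = "introns")
  n5 <- bio_end5(naprnas); n3 <- bio_end3(naprnas)
  i5 <- bio_end5(introns); i3 <- bio_end3(introns)
  lab <- logical(nrow(naprnas)); ev <- rep(NA_character_, nrow(naprnas))
  for (i in seq_len(nrow(naprnas))) {
    ok <- introns$chrom == naprnas$chrom[i] &
      introns$strand == naprnas$strand[i] &
      abs(i5 - n5[i]) <= end_tolerance &
      abs(i3 - n3[i]) <= end_tolerance
    if (any(ok)) {
      lab[i] <- TRUE
      ev[i] <- introns$name[which(ok)[1]]
    }
  }
  dplyr::mutate(naprnas, slirna = lab, slirna_intron = ev)
}

#' Classify napRNAs as snotrons
#'
#' A snotron pairs an intronic snoRNA end with the host intron's opposite
#' splice site: either the call's 5' end coincides (within
#' `end_tolerance`) with a snoRNA 5' end while its 3' end lies within
#' `splice_tolerance` nt of the 3' splice site of an intron containing
#' that snoRNA, or the mirror configuration (3' end = snoRNA 3' end,
#' 5' end near the intron's 5' splice site).
#'
#' @param naprnas Interval tibble of calls.
#' @param snornas Interval tibble of known snoRNAs.
#' @param introns Interval tibble of known introns.
#' @param splice_tolerance Distance allowed between the free call end and
#'   the splice site (default 10 nt, boundary-inclusive).
#' @param end_tolerance Tolerance for the snoRNA-end match (default 0).
#' @return `naprnas` with logical `snotron` plus evidence columns
#'   `snotron_orientation` (`"5p_snoRNA"` or `"3p_snoRNA"`),
#'   `snotron_snorna`, `snotron_intron`.
#' @export
classify_snotron <- function(naprnas, snornas, introns,
                             splice_tolerance = 10, end_tolerance = 0) {
  check_intervals(naprnas, what = "naprnas")
  check_intervals(snornas, what = "snornas")
  check_intervals(introns, what = "introns")
  n5 <- bio_end5(naprnas); n3 <- bio_end3(naprnas)
  s5 <- bio_end5(snornas); s3 <- bio_end3(snornas)
  i5 <- bio_end5(introns); i3 <- bio_end3(introns)
  lab <- logical(nrow(naprnas))
  orient <- rep(NA_character_, nrow(naprnas))
  ev_sno <- rep(NA_character_, nrow(naprnas))
  ev_int <- rep(NA_character_, nrow(naprnas))
  for (i in seq_len(nrow(naprnas))) {
    same <- which(snornas$chrom == naprnas$chrom[i] &
                    snornas$strand == naprnas$strand[i])
    for (s in same) {
      # introns containing this snoRNA, same strand
      host <- which(introns$chrom == snornas$chrom[s] &
                      introns$strand == snornas$strand[s] &
                      introns$start <= snornas$start[s] &
                      introns$end >= snornas$end[s])
      if (!length(host)) next
      if (abs(n5[i] - s5[s]) <= end_tolerance) {
        near <- host[abs(n3[i] - i3[host]) <= splice_tolerance]
        if (length(near)) {
          lab[i] <- TRUE; orient[i] <- "5p_snoRNA"
          ev_sno[i] <- snornas$name[s]; ev_int[i] <- introns$name[near[1]]
          break
        }
      }
      if (abs(n3[i] - s3[s]) <= end_tolerance) {
        near <- host[abs(n5[i] - i5[host]) <= splice_tolerance]
        if (length(near)) {
          lab[i] <- TRUE; orient[i] <- "3p_snoRNA"
          ev_sno[i] <- snornas$name[s]; ev_int[i] <- introns$name[near[1]]
          break
        }
      }
    }
  }
  dplyr::mutate(naprnas, snotron = lab, snotron_orientation = orient,
                snotron_snorna = ev_sno, snotron_intron = ev_int)
}

#' Cluster pre-miRNAs by genomic proximity
#'
#' Single-linkage clustering of same-strand pre-miRNAs whose inter-feature
#' gap is strictly less than `max_gap` (default 10 kb; a gap of exactly
#' `max_gap` separates clusters).
#'
#' @param pre_mirnas Interval tibble of pre-miRNAs.
#' @param max_gap Gap threshold in nt (default 10000, strict `<`).
#' @return `pre_mirnas` with an integer `cluster_id` column; clusters are
#'   numbered in (chrom, start) order.
#' @export
cluster_premirnas <- function(pre_mirnas, max_gap = 10000) {
  check_intervals(pre_mirnas, what = "pre_mirnas")
  if (!nrow(pre_mirnas)) return(dplyr::mutate(pre_mirnas, cluster_id = integer()))
  ord <- order(pre_mirnas$chrom, pre_mirnas$strand, pre_mirnas$start,
               pre_mirnas$end)
  x <- pre_mirnas[ord, , drop = FALSE]
  cid <- integer(nrow(x))
  cur <- 0L; reach <- -Inf; last_key <- ""
  for (i in seq_len(nrow(x))) {
    key <- paste(x$chrom[i], x$strand[i])
    if (key != last_key || x$start[i] - reach >= max_gap) {
      cur <- cur + 1L
      reach <- x$end[i]
    } else {
      reach <- max(reach, x$end[i])
    }
    cid[i] <- cur
    last_key <- key
  }
  out <- dplyr::mutate(x, cluster_id = cid)
  # renumber clusters by (chrom, start) of their first member
  out$cluster_id <- match(out$cluster_id, unique(out$cluster_id))
  out
}

#' Classify napRNAs as miRNA-spacer RNAs (misRNAs)
#'
#' A misRNA intersects a pre-miRNA cluster on the same strand and is NOT
#' located entirely within any single pre-miRNA (such calls are the known
#' pre-/mature miRNAs themselves). A soft criterion — each call end lying
#' within `end_tolerance` nt of a mature-miRNA end from the cluster — is
#' recorded as evidence and enforced only when
#' `require_mature_ends = TRUE`.
#'
#' @param naprnas Interval tibble of calls.
#' @param clustered_premirnas Output of [cluster_premirnas()].
#' @param mature_mirnas Interval tibble of mature miRNAs (with `parent`
#'   naming the host pre-miRNA when available).
#' @param end_tolerance Tolerance for the mature-end coincidence
#'   (default 3 nt).
#' @param require_mature_ends Enforce the soft criterion (default `FALSE`).
#' @return `naprnas` with logical `misrna`, integer `misrna_cluster` and
#'   logical `misrna_mature_ends` evidence columns.
#' @export
classify_misrna <- function(naprnas, clustered_premirnas, mature_mirnas,
                            end_tolerance = 3, require_mature_ends = FALSE) {
  check_intervals(naprnas, what = "naprnas")
  check_intervals(clustered_premirnas, what = "clustered_premirnas")
  if (!"cluster_id" %in% names(clustered_premirnas)) {
    abort("clustered_premirnas must come from cluster_premirnas()")
  }
  n5 <- bio_end5(naprnas); n3 <- bio_end3(naprnas)
  lab <- logical(nrow(naprnas))
  cl <- rep(NA_integer_, nrow(naprnas))
  mat_ok <- rep(NA, nrow(naprnas))
  # a spacer needs two flanking genes: singleton clusters are not eligible
  spans <- clustered_premirnas |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(chrom = .data$chrom[1], start = min(.data$start),
                     end = max(.data$end), strand = .data$strand[1],
                     n_members = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_members >= 2)
  for (i in seq_len(nrow(naprnas))) {
    hit <- which(spans$chrom == naprnas$chrom[i] &
                   spans$strand == naprnas$strand[i] &
                   spans$start < naprnas$end[i] &
                   spans$end > naprnas$start[i])
    if (!length(hit)) next
    cid <- spans$cluster_id[hit[1]]
    inside_pre <- any(clustered_premirnas$chrom == naprnas$chrom[i] &
                        clustered_premirnas$strand == naprnas$strand[i] &
                        clustered_premirnas$start <= naprnas$start[i] &
                        clustered_premirnas$end >= naprnas$end[i])
    if (inside_pre) next
    members <- clustered_premirnas$name[clustered_premirnas$cluster_id == cid]
    mm <- mature_mirnas[mature_mirnas$chrom == naprnas$chrom[i] &
                          mature_mirnas$strand == naprnas$strand[i], ,
                        drop = FALSE]
    if ("parent" %in% names(mm)) mm <- mm[mm$parent %in% members, , drop = FALSE]
    ends <- unique(c(bio_end5(mm), bio_end3(mm)))
    m_ok <- length(ends) > 0 &&
      any(abs(ends - n5[i]) <= end_tolerance) &&
      any(abs(ends - n3[i]) <= end_tolerance)
    if (require_mature_ends && !m_ok) next
    lab[i] <- TRUE; cl[i] <- cid; mat_ok[i] <- m_ok
  }
  dplyr::mutate(naprnas, misrna = lab, misrna_cluster = cl,
                misrna_mature_ends = mat_ok)
}

#' Run the full interval + motif classifier suite
#'
#' Applies the novelty exclusion filter (optional), the three interval
#' classifiers (sliRNA, snotron, misRNA) and — when a genome is supplied —
#' the three motif detectors (Pol III, C/D box, H/ACA box) to a set of
#' napRNA calls. Labels are independent flags: one call may carry several.
#'
#' @param naprnas Interval tibble of calls.
#' @param annotations An [annotation_set()].
#' @param genome Named character vector from [read_genome()], required for
#'   the motif classes; `NULL` skips them.
#' @param exclude Apply [exclude_annotated()] first (default `FALSE`;
#'   exclusion drops rows).
#' @param end_tolerance_slirna,splice_tolerance,end_tolerance_misrna,max_gap
#'   Tolerances passed to the respective classifiers.
#' @param require_mature_ends Passed to [classify_misrna()].
#' @return The (possibly filtered) call tibble with one logical label
#'   column per class plus evidence columns.
#' @export
classify_naprnas <- function(naprnas, annotations, genome = NULL,
                             exclude = FALSE, end_tolerance_slirna = 0,
                             splice_tolerance = 10, end_tolerance_misrna = 3,
                             max_gap = 10000, require_mature_ends = FALSE) {
  stopifnot(inherits(annotations, "annotation_set"))
  out <- naprnas
  if (exclude) out <- exclude_annotated(out, annotations)
  empty <- function() tibble(chrom = character(), start = integer(),
                             end = integer(), name = character(),
                             score = numeric(), strand = character())
  introns <- annotations$introns %||% empty()
  snornas <- annotations$snornas %||% empty()
  pre <- annotations$pre_mirnas %||% empty()
  mature <- annotations$mature_mirnas %||% empty()
  out <- classify_slirna(out, introns, end_tolerance = end_tolerance_slirna)
  out <- classify_snotron(out, snornas, introns,
                          splice_tolerance = splice_tolerance)
  out <- classify_misrna(out, cluster_premirnas(pre, max_gap = max_gap),
                         mature, end_tolerance = end_tolerance_misrna,
                         require_mature_ends = require_mature_ends)
  if (!is.null(genome)) {
    seqs <- feature_seq(out, genome, as = "dna")
    out$pol3 <- vapply(seqs, function(s)
      !is.null(detect_pol3(s, error_on_short = FALSE)), logical(1),
      USE.NAMES = FALSE)
    out$cd_box <- vapply(seqs, function(s)
      !is.null(detect_cd_box(s, error_on_short = FALSE)), logical(1),
      USE.NAMES = FALSE)
    out$haca_box <- vapply(seqs, function(s)
      !is.null(detect_haca_box(s, error_on_short = FALSE)), logical(1),
      USE.NAMES = FALSE)
  }
  out
}

#' Load the packaged classifier example world
#'
#' A small hand-constructed annotation world (12 introns, 6 snoRNAs, 2
#' pre-miRNA cluster groups, exclusion features) with 30 candidate calls
#' and their expected class labels, including the boundary geometries
#' (snotron distance exactly 10 nt; pre-miRNA gap exactly 10 kb). Useful
#' as a worked example and as a regression anchor for the interval
#' classifiers.
#'
#' @return A list: `candidates` (interval tibble), `annotations` (an
#'   [annotation_set()]), `labels` (expected `slirna`/`snotron`/`misrna`/
#'   `excluded` flags per candidate).
#' @export
fixture_world <- function() {
  d <- system.file("extdata", "fixture_world", package = "napkit")
  mat <- read_bed(file.path(d, "mature_mirnas.bed"))
  parts <- strsplit(mat$name, "|", fixed = TRUE)
  mat$name <- vapply(parts, `[[`, "", 1)
  mat$parent <- vapply(parts, `[[`, "", 2)
  list(
    candidates = read_bed(file.path(d, "candidates.bed")),
    annotations = annotation_set(
      introns = read_bed(file.path(d, "introns.bed")),
      snornas = read_bed(file.path(d, "snornas.bed")),
      pre_mirnas = read_bed(file.path(d, "pre_mirnas.bed")),
      mature_mirnas = mat,
      exclusion = read_bed(file.path(d, "exclusion.bed"))),
    labels = readr::read_tsv(file.path(d, "labels.tsv"),
                             show_col_types = FALSE, progress = FALSE))
}
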