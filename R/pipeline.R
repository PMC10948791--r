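#' Pipeline run configuration
#'
#' Flat key-value configuration covering every tunable threshold in the
#' workflow, with the established defaults (boundary read minimum 7, fold
#' changes 2, minimum length 100 nt, 2 samples, summary count 20, splice
#' window 10 nt, cluster gap 10 kb, cap-site count 10 and alpha 0.05).
#'
#' @param ... Key = value overrides of the defaults; unknown keys are
#'   rejected.
#' @return A named list of class `"run_config"`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1, genome_length = 100000, gc_fraction = 0.5, n_samples = 2,
    n_slirna = 3, n_snotron = 2, n_misrna = 1, n_pol3 = 2, n_cd = 2,
    n_haca = 1, n_plain = 3, reads_per_end = 30,
    adapter_retention_prob = 0.5, background_read_rate = 0.2,
    trim_error_rate = 0.1, trim_min_length = 15, trim_min_overlap = 10,
    barcode_len = 6,
    cov_floor = 1, boundary_window = 100, flank = 20,
    min_boundary_reads = 7, min_boundary_fc = 2, min_flank_fc = 2,
    min_length = 100, end_tolerance = 5, min_samples = 2, min_summary = 20,
    splice_tolerance = 10, end_tolerance_slirna = 0, end_tolerance_misrna = 3,
    max_gap = 10000,
    cap_min_count = 10, cap_min_fc = 2, cap_alpha = 0.05, cap_window = 100,
    zscore_n_shuffles = 50, zscore_order = 2
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` comments and blank lines are
#' skipped. Values are coerced to the type of the corresponding
#' [run_config()] default; unknown keys abort before any stage runs.
#'
#' @param path Config file path.
#' @return A `"run_config"` list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(run_config())
  parts <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(parts) != 3)
  if (length(bad)) abort(paste0("malformed config line: ", lines[bad[1]]))
  keys <- vapply(parts, `[[`, "", 2)
  vals <- vapply(parts, `[[`, "", 3)
  args <- as.list(suppressWarnings(as.numeric(vals)))
  if (anyNA(unlist(args))) {
    abort(paste0("non-numeric config value for key: ",
                 keys[which(is.na(unlist(args)))[1]]))
  }
  names(args) <- keys
  do.call(run_config, args)
}

#' Write a configuration echo
#'
#' @param config A `"run_config"`.
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  writeLines(c(napkit_stamp(),
               paste(names(config), unlist(config), sep = " = ")), path)
  invisible(path)
}

#' Run the napkit workflow
#'
#' Wires the modules into the standard order `simulate -> trim -> tracks
#' -> call -> classify` (optional extra stages: `capcall`, `zscore`).
#' Every stage reads only files produced by earlier stages (or present in
#' `out_dir`), writes its outputs under `out_dir`, and logs a parameter
#' line to stderr. Stochastic stages are seeded from `config$seed`, so a
#' rerun with identical config and inputs is byte-identical.
#'
#' @param config A [run_config()].
#' @param stages Character vector of stages, in order.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of per-stage outputs.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "trim", "tracks", "call",
                                    "classify"),
                         out_dir = tempfile("napkit_run_")) {
  stopifnot(inherits(config, "run_config"))
  known <- c("simulate", "trim", "tracks", "call", "classify", "capcall",
             "zscore")
  bad <- setdiff(stages, known)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "run_config.txt"))
  log_stage <- function(stage, ...) {
    message(sprintf("[napkit %s] %s", stage, paste0(...)))
  }
  results <- list()
  sim_dir <- file.path(out_dir, "sim")
  world <- NULL
  tracks <- NULL
  calls <- NULL

  get_world <- function() {
    if (is.null(world)) {
      world <<- simulate_world(sim_config(
        seed = config$seed, genome_length = config$genome_length,
        gc_fraction = config$gc_fraction, n_samples = config$n_samples,
        n_slirna = config$n_slirna, n_snotron = config$n_snotron,
        n_misrna = config$n_misrna, n_pol3 = config$n_pol3,
        n_cd = config$n_cd, n_haca = config$n_haca,
        n_plain = config$n_plain, reads_per_end = config$reads_per_end,
        adapter_retention_prob = config$adapter_retention_prob,
        background_read_rate = config$background_read_rate))
    }
    world
  }
  get_tracks <- function() {
    if (is.null(tracks)) {
      tsvs <- list.files(sim_dir, pattern = "\\.alignments\\.tsv$",
                         full.names = TRUE)
      if (!length(tsvs)) abort("tracks stage: no alignment TSVs found; run 'simulate' first")
      aln <- dplyr::bind_rows(lapply(tsvs, read_alignments))
      genome <- read_genome(file.path(sim_dir, "genome.fa"))
      tracks <<- build_tracks(aln, setNames(nchar(genome), names(genome)))
    }
    tracks
  }

  for (stage in stages) {
    if (stage == "simulate") {
      lib <- simulate_library(get_world(), out_dir = sim_dir)
      log_stage(stage, sprintf("%d truth napRNAs, %d reads, seed %d",
                               nrow(world$truth), nrow(lib$alignments),
                               config$seed))
      results$simulate <- lib$files
    } else if (stage == "trim") {
      fqs <- list.files(sim_dir, pattern = "\\.fastq$", full.names = TRUE)
      fqs <- fqs[!grepl("trimmed", fqs)]
      if (!length(fqs)) abort("trim stage: no FASTQ inputs found")
      tcfg <- trim_config(max_error_rate = config$trim_error_rate,
                          min_length = config$trim_min_length,
                          min_overlap = config$trim_min_overlap,
                          barcode_len = config$barcode_len)
      summaries <- purrr::map(fqs, function(fq) {
        trimmed <- trim_reads(read_fastq(fq), tcfg)
        out_fq <- sub("\\.fastq$", ".trimmed.fastq", fq)
        kept <- trimmed[!trimmed$rejected, ]
        write_fastq(tibble(
          id = paste0(kept$id, " np:5p=", as.integer(kept$has5p),
                      ";3p=", as.integer(kept$has3p),
                      ";bc5=", kept$barcode5, ";bc3=", kept$barcode3),
          seq = kept$insert_seq), out_fq)
        dplyr::mutate(trim_summary(trimmed), fastq = basename(fq))
      })
      out <- dplyr::bind_rows(summaries)
      readr::write_tsv(out, file.path(out_dir, "trim_summary.tsv"),
                       progress = FALSE)
      log_stage(stage, sprintf("%d librarie(s), mean adapter retention %.2f",
                               nrow(out), mean(out$frac_any_adapter)))
      results$trim <- out
    } else if (stage == "tracks") {
      trs <- get_tracks()
      files <- purrr::imap(trs, function(tr, s) {
        write_bedgraph(rpm_normalize(tr), file.path(out_dir, s))
      })
      log_stage(stage, sprintf("%d sample track set(s) written", length(trs)))
      results$tracks <- files
    } else if (stage == "call") {
      calls <- call_naprnas(
        get_tracks(), cov_floor = config$cov_floor,
        boundary_window = config$boundary_window, flank = config$flank,
        min_boundary_reads = config$min_boundary_reads,
        min_boundary_fc = config$min_boundary_fc,
        min_flank_fc = config$min_flank_fc, min_length = config$min_length,
        end_tolerance = config$end_tolerance,
        min_samples = config$min_samples, min_summary = config$min_summary)
      write_bed(dplyr::mutate(calls[c("chrom", "start", "end", "name",
                                      "strand")], score = calls$summary_count),
                file.path(out_dir, "naprnas.bed"), header = TRUE)
      readr::write_tsv(dplyr::select(calls, -"sample_counts"),
                       file.path(out_dir, "naprnas.tsv"), progress = FALSE)
      log_stage(stage, sprintf("%d napRNAs called", nrow(calls)))
      results$call <- calls
    } else if (stage == "classify") {
      if (is.null(calls)) abort("classify stage requires the call stage")
      genome <- read_genome(file.path(sim_dir, "genome.fa"))
      ann_dir <- file.path(sim_dir, "annotations")
      rb <- function(f, extra = NULL) {
        p <- file.path(ann_dir, f)
        if (!file.exists(p)) return(NULL)
        read_bed(p)
      }
      anns <- annotation_set(introns = rb("introns.bed"),
                             snornas = rb("snornas.bed"),
                             pre_mirnas = rb("pre_mirnas.bed"),
                             mature_mirnas = rb("mature_mirnas.bed"),
                             utr5 = rb("utr5.bed"),
                             exclusion = rb("exclusion.bed"))
      classified <- classify_naprnas(
        calls, anns, genome = genome,
        end_tolerance_slirna = config$end_tolerance_slirna,
        splice_tolerance = config$splice_tolerance,
        end_tolerance_misrna = config$end_tolerance_misrna,
        max_gap = config$max_gap)
      readr::write_tsv(dplyr::select(classified, -dplyr::any_of("sample_counts")),
                       file.path(out_dir, "naprnas.classified.tsv"),
                       progress = FALSE)
      log_stage(stage, sprintf(
        "labels: sliRNA %d, snotron %d, misRNA %d, pol3 %d, cd %d, haca %d",
        sum(classified$slirna), sum(classified$snotron),
        sum(classified$misrna), sum(classified$pol3 %||% FALSE),
        sum(classified$cd_box %||% FALSE),
        sum(classified$haca_box %||% FALSE)))
      results$classify <- classified
    } else if (stage == "capcall") {
      trs <- get_tracks()
      utr5 <- read_bed(file.path(sim_dir, "annotations", "utr5.bed"))
      sites <- call_cap_sites(trs, utr5, min_count = config$cap_min_count,
                              min_fc = config$cap_min_fc,
                              alpha = config$cap_alpha,
                              window = config$cap_window)
      readr::write_tsv(sites, file.path(out_dir, "cap_sites.tsv"),
                       progress = FALSE)
      log_stage(stage, sprintf("%d cap sites", nrow(sites)))
      results$capcall <- sites
    } else if (stage == "zscore") {
      if (is.null(calls)) abort("zscore stage requires the call stage")
      genome <- read_genome(file.path(sim_dir, "genome.fa"))
      seqs <- feature_seq(calls, genome, as = "rna")
      scores <- purrr::imap(setNames(seqs, calls$name), function(s, nm) {
        tidy(z_score(s, n_shuffles = config$zscore_n_shuffles,
                     order = config$zscore_order,
                     seed = config$seed + nchar(s)))
      })
      out <- dplyr::bind_rows(scores, .id = "name")
      readr::write_tsv(out, file.path(out_dir, "zscores.tsv"),
                       progress = FALSE)
      log_stage(stage, sprintf("%d z-scores", nrow(out)))
      results$zscore <- out
    }
  }
  invisible(results)
}
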