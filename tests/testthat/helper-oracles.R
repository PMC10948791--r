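# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own algorithms: plain nested loops, naive recursion,
# direct arithmetic.

# Nested-loop interval overlap (the reference for overlap_features)
oracle_overlap <- function(query, features, same_strand = TRUE) {
  hits <- list()
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(features))) {
      if (query$chrom[i] != features$chrom[j]) next
      if (same_strand && query$strand[i] != features$strand[j]) next
      if (query$start[i] < features$end[j] &&
          features$start[j] < query$end[i]) {
        hits[[length(hits) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(hits)) return(matrix(integer(), ncol = 2))
  do.call(rbind, hits)
}

# Position-by-position recount of coverage / start5 / end3 for one sample
oracle_tracks <- function(alignments, chrom, strand, n) {
  g <- alignments[alignments$chrom == chrom & alignments$strand == strand, ]
  cov <- integer(n); s5 <- integer(n); e3 <- integer(n)
  for (i in seq_len(nrow(g))) {
    for (p in g$start[i]:(g$end[i] - 1)) cov[p + 1] <- cov[p + 1] + 1L
    p5 <- if (strand == "+") g$start[i] else g$end[i] - 1L
    p3 <- if (strand == "+") g$end[i] - 1L else g$start[i]
    if (g$has5p[i]) s5[p5 + 1] <- s5[p5 + 1] + 1L
    if (g$has3p[i]) e3[p3 + 1] <- e3[p3 + 1] + 1L
  }
  list(cov = cov, start5 = s5, end3 = e3)
}

# Direct recomputation of the six boundary statistics for one candidate
oracle_boundary_stats <- function(cov, s5, e3, p5, p3, strand,
                                  window = 100, flank = 20, eps = 0.05) {
  n <- length(cov)
  win_sum <- function(v, p) {
    total <- 0
    for (q in max(0, p - window):min(n - 1, p + window)) {
      if (q != p) total <- total + v[q + 1]
    }
    total
  }
  cstart <- min(p5, p3); cend <- max(p5, p3) + 1
  inside <- mean(cov[(cstart + 1):cend])
  up_rng <- if (strand == "+") (p5 - flank):(p5 - 1) else (p5 + 1):(p5 + flank)
  dn_rng <- if (strand == "+") (p3 + 1):(p3 + flank) else (p3 - flank):(p3 - 1)
  clip <- function(r) r[r >= 0 & r < n]
  up_mean <- if (length(clip(up_rng))) mean(cov[clip(up_rng) + 1]) else 0
  dn_mean <- if (length(clip(dn_rng))) mean(cov[clip(dn_rng) + 1]) else 0
  list(startReadNum = s5[p5 + 1], endReadNum = e3[p3 + 1],
       startFC = s5[p5 + 1] / max(1, win_sum(s5, p5)),
       endFC = e3[p3 + 1] / max(1, win_sum(e3, p3)),
       up20ntFC = inside / max(eps, up_mean),
       down20ntFC = inside / max(eps, dn_mean))
}

# Exhaustive enumeration of all nested structures over WC + G.U pairs with
# a minimum hairpin loop; returns the maximum pair count. Exponential -
# for n <= 14 only.
oracle_max_pairs <- function(seq, min_loop = 3) {
  ch <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  ok <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1L, j) # i unpaired
    for (k in (i + min_loop + 1L):j) {
      if (ok(ch[i], ch[k])) {
        inner <- if (k - 1L >= i + 1L) rec(i + 1L, k - 1L) else 0L
        outer <- if (k + 1L <= j) rec(k + 1L, j) else 0L
        best <- max(best, 1L + inner + outer)
      }
    }
    best
  }
  if (length(ch) < 2) return(0L)
  rec(1L, length(ch))
}

# k-mer count table of a sequence
kmer_counts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(table(character()))
  table(substring(seq, 1:(n - k + 1), k:n))
}

# Exact upper-tail binomial probability via direct summation
oracle_binom_tail <- function(x, size, prob) {
  if (x > size) return(0)
  sum(vapply(x:size, function(k) {
    exp(lchoose(size, k) + k * log(prob) + (size - k) * log1p(-prob))
  }, numeric(1)))
}

# Random alignment table for fuzzing (single chromosome "chrT")
random_alignments <- function(n_reads, chrom_len, sample = "s1",
                              max_len = 150) {
  len <- sample(20:max_len, n_reads, replace = TRUE)
  start <- vapply(len, function(L) sample.int(chrom_len - L, 1) - 1L,
                  integer(1))
  tibble::tibble(chrom = "chrT", start = start, end = start + len,
                 strand = sample(c("+", "-"), n_reads, replace = TRUE),
                 has5p = sample(c(TRUE, FALSE), n_reads, replace = TRUE),
                 has3p = sample(c(TRUE, FALSE), n_reads, replace = TRUE),
                 sample = sample)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
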