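#' Per-position mutation rates from mutational-profiling reads
#'
#' Chemical adducts are read out as reverse-transcription mutations; this
#' pile-up turns aligned reads with per-read mutation positions into
#' per-position mutation rates and depths on one target RNA.
#'
#' @param reads Tibble with `start`, `end` (0-based half-open span on the
#'   target) and a `mutations` list-column of 0-based mutated positions
#'   (empty integer vector when none); an optional `id` column names reads
#'   in errors.
#' @param target_length Target RNA length in nt.
#' @return Tibble `pos` (0-based), `rate` (`NA` where depth is 0),
#'   `depth`.
#' @export
mutation_rates <- function(reads, target_length) {
  stopifnot(all(c("start", "end", "mutations") %in% names(reads)))
  depth <- integer(target_length)
  mut <- integer(target_length)
  for (i in seq_len(nrow(reads))) {
    s <- reads$start[i]; e <- reads$end[i]
    if (s < 0 || e > target_length || e <= s) {
      abort(sprintf("read %s: span [%d,%d) outside target of length %d",
                    if ("id" %in% names(reads)) reads$id[i] else i,
                    s, e, target_length))
    }
    depth[(s + 1):e] <- depth[(s + 1):e] + 1L
    m <- reads$mutations[[i]]
    if (length(m)) {
      if (any(m < s | m >= e)) {
        abort(sprintf("read %s: mutation outside aligned span",
                      if ("id" %in% names(reads)) reads$id[i] else i))
      }
      mut[m + 1] <- mut[m + 1] + 1L
    }
  }
  tibble(pos = seq_len(target_length) - 1L,
         rate = ifelse(depth > 0, mut / depth, NA_real_),
         depth = depth)
}

#' Background-subtracted, normalized reactivity profile
#'
#' Raw reactivity is the treated minus untreated mutation rate, clipped at
#' zero. Positions with depth below `min_depth` in either channel are
#' masked (`NA`), not zero. Normalization follows the 2-8% rule: the top
#' 2% of unmasked raw values are excluded and every value is divided by
#' the mean of the next 8%.
#'
#' @param treated,untreated Tibbles from [mutation_rates()] of equal
#'   length.
#' @param min_depth Minimum per-channel depth (default 100).
#' @return A tibble of class `"reactivity_profile"`: `pos`,
#'   `treated_rate`, `untreated_rate`, `treated_depth`,
#'   `untreated_depth`, `raw`, `norm`.
#' @export
reactivity_profile <- function(treated, untreated, min_depth = 100) {
  if (nrow(treated) != nrow(untreated)) {
    abort("treated and untreated profiles differ in length")
  }
  masked <- treated$depth < min_depth | untreated$depth < min_depth
  raw <- pmax(treated$rate - untreated$rate, 0)
  raw[masked] <- NA_real_
  if (all(is.na(raw))) abort("all positions are masked: nothing to normalize")
  vals <- sort(raw[!is.na(raw)], decreasing = TRUE)
  n <- length(vals)
  n_excl <- ceiling(0.02 * n)
  n_band <- ceiling(0.08 * n)
  band <- vals[(n_excl + 1):min(n, n_excl + n_band)]
  divisor <- mean(band)
  if (!is.finite(divisor) || divisor <= 0) {
    abort("2-8% normalization band has non-positive mean; profile is flat")
  }
  out <- tibble(pos = treated$pos,
                treated_rate = treated$rate,
                untreated_rate = untreated$rate,
                treated_depth = treated$depth,
                untreated_depth = untreated$depth,
                raw = raw,
                norm = raw / divisor)
  attr(out, "min_depth") <- min_depth
  attr(out, "norm_divisor") <- divisor
  class(out) <- c("reactivity_profile", class(out))
  out
}

#' Folding constraints from a reactivity profile
#'
#' Positions with normalized reactivity at or above `ss_threshold` are
#' highly reactive, hence single-stranded, and are forced unpaired (`x`);
#' masked and low-reactivity positions are unconstrained (`.`). The
#' string is consumable by [fold_pairmax()] or exportable to an external
#' folder.
#'
#' @param profile A [reactivity_profile()].
#' @param ss_threshold Reactivity threshold (default 0.7).
#' @return A constraint string of `.`/`x`.
#' @export
reactivity_constraints <- function(profile, ss_threshold = 0.7) {
  marks <- ifelse(!is.na(profile$norm) & profile$norm >= ss_threshold,
                  "x", ".")
  paste(marks, collapse = "")
}

#' Write a profile in SHAPE two-column format
#'
#' Position (1-based, the convention of external folding tools) and
#' normalized reactivity; masked positions are written as `-999`.
#'
#' @param profile A [reactivity_profile()].
#' @param path Output path.
#' @export
write_shape <- function(profile, path) {
  val <- ifelse(is.na(profile$norm), -999, profile$norm)
  writeLines(sprintf("%d\t%.6g", profile$pos + 1L, val), path)
  invisible(path)
}

#' @method autoplot reactivity_profile
#' @export
autoplot.reactivity_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$state <- ifelse(is.na(df$norm), "masked", "measured")
  ggplot2::ggplot(df[df$state == "measured", ],
                  ggplot2::aes(x = .data$pos + 1, y = .data$norm)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::labs(x = "position (nt)", y = "normalized reactivity") +
    ggplot2::theme_minimal()
}
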