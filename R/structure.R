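#' Base-pair maximization folding
#'
#' The package's built-in, exactly testable folding oracle: a Nussinov-style
#' dynamic program maximising the number of Watson-Crick plus G-U pairs
#' with hairpin loops of at least `min_loop` nt, with a deterministic
#' traceback. The energy is the negative pair count (more negative = more
#' stable). Positions marked `x` in `constraint` are forced unpaired —
#' the hook by which chemical-probing reactivities constrain the fold. Any
#' function with this signature and return shape (e.g. a wrapper around an
#' external thermodynamic folder) can replace it wherever napkit takes a
#' `folder` argument.
#'
#' @param seq RNA sequence (`T` accepted as `U`), <= 2000 nt.
#' @param min_loop Minimum hairpin loop length (default 3).
#' @param constraint Optional string of `.`/`x` the same length as `seq`.
#' @return A list of class `"fold_result"`: `dotbracket`, `pairs`,
#'   `energy` (`-pairs`).
#' @export
fold_pairmax <- function(seq, min_loop = 3, constraint = NULL) {
  s <- chartr("Tt", "Uu", toupper(seq))
  res <- cpp_fold_pairmax(s, as.integer(min_loop),
                          if (is.null(constraint)) "" else constraint)
  structure(list(dotbracket = res$dotbracket, pairs = res$pairs,
                 energy = -res$pairs, seq = s),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$seq, "\n", x$dotbracket, "\n", sep = "")
  cat(sprintf("pairs: %d  energy: %d\n", x$pairs, x$energy))
  invisible(x)
}

#' Composition-preserving sequence shuffles
#'
#' Order 1 permutes the bases (exact mononucleotide conservation). Order 2
#' performs an Euler-path (Altschul-Erickson) shuffle that preserves every
#' dinucleotide count exactly, hence also the base composition and the
#' first and last base.
#'
#' @param seq Sequence of length >= 3.
#' @param order 1 or 2.
#' @param seed Optional integer seed for reproducibility (the global RNG
#'   state is restored afterwards).
#' @return A shuffled sequence (same alphabet case as the uppercased
#'   input).
#' @export
shuffle_seq <- function(seq, order = 2, seed = NULL) {
  s <- toupper(seq)
  if (nchar(s) < 3) abort("sequence too short to shuffle (need >= 3 nt)")
  if (!order %in% c(1, 2)) abort("order must be 1 or 2")
  run <- function() {
    if (order == 1) {
      return(paste(sample(strsplit(s, "")[[1]]), collapse = ""))
    }
    euler_shuffle(s)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Altschul-Erickson dinucleotide shuffle: sample a uniform-ish Eulerian
# path with the original start/end vertices by drawing per-vertex "last
# edges" until they form an arborescence toward the end vertex, then
# permuting the remaining edges.
euler_shuffle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  verts <- unique(ch)
  edges <- split(ch[-1], ch[-n]) # outgoing edge targets per vertex
  last <- ch[n]
  repeat {
    last_edge <- vapply(verts, function(v) {
      out <- edges[[v]]
      if (v == last || is.null(out) || !length(out)) NA_character_
      else out[sample.int(length(out), 1)]
    }, character(1))
    # check the chosen last edges lead every vertex (with out-edges) to `last`
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.na(last_edge[[v]])) next
      seen <- character(0); cur <- v
      while (cur != last) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  arranged <- lapply(setNames(verts, verts), function(v) {
    out <- edges[[v]]
    if (is.null(out) || !length(out)) return(character(0))
    if (!is.na(last_edge[[v]])) {
      idx <- which(out == last_edge[[v]])[1]
      rest <- out[-idx]
      c(if (length(rest)) rest[sample.int(length(rest))] else character(0),
        last_edge[[v]])
    } else {
      out[sample.int(length(out))]
    }
  })
  used <- setNames(integer(length(verts)), verts)
  res <- character(n)
  res[1] <- ch[1]
  cur <- ch[1]
  for (i in 2:n) {
    used[[cur]] <- used[[cur]] + 1L
    nxt <- arranged[[cur]][used[[cur]]]
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

#' Shuffle-based structure z-score
#'
#' Standardized difference between the folding energy of the native
#' sequence and the energy distribution of `n_shuffles`
#' composition-preserving shuffles: `z = (E_native - mean) / sd`. A
#' negative z means the sequence is more stably structured than expected
#' from its (di)nucleotide composition alone. When the shuffle energies
#' are all identical the score is degenerate and reported as 0 with a
#' flag.
#'
#' @param seq RNA sequence.
#' @param n_shuffles Number of shuffles (default 100, >= 2).
#' @param order Shuffle order (default 2 = dinucleotide-preserving).
#' @param folder Folding function (default [fold_pairmax()]).
#' @param seed Optional seed.
#' @return A list of class `"structure_score"`: `mfe_native`,
#'   `shuffle_mean`, `shuffle_sd`, `z`, `n_shuffles`, `shuffle_order`,
#'   `degenerate`.
#' @export
z_score <- function(seq, n_shuffles = 100, order = 2, folder = fold_pairmax,
                    seed = NULL) {
  if (n_shuffles < 2) abort("n_shuffles must be >= 2")
  run <- function() {
    native <- folder(seq)$energy
    energies <- vapply(seq_len(n_shuffles), function(i) {
      folder(shuffle_seq(seq, order = order))$energy
    }, numeric(1))
    m <- mean(energies); sdev <- sd(energies)
    degenerate <- !is.finite(sdev) || sdev == 0
    structure(list(mfe_native = native, shuffle_mean = m,
                   shuffle_sd = sdev,
                   z = if (degenerate) 0 else (native - m) / sdev,
                   n_shuffles = n_shuffles, shuffle_order = order,
                   degenerate = degenerate),
              class = "structure_score")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.structure_score <- function(x, ...) {
  cat(sprintf("<structure_score> z = %.3f (native %g vs shuffles %.3f +/- %.3f, n = %d, order %d)%s\n",
              x$z, x$mfe_native, x$shuffle_mean, x$shuffle_sd, x$n_shuffles,
              x$shuffle_order, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @method tidy structure_score
#' @export
tidy.structure_score <- function(x, ...) {
  tibble(mfe_native = x$mfe_native, shuffle_mean = x$shuffle_mean,
         shuffle_sd = x$shuffle_sd, z = x$z, n_shuffles = x$n_shuffles,
         shuffle_order = x$shuffle_order, degenerate = x$degenerate)
}

#' @method glance structure_score
#' @export
glance.structure_score <- function(x, ...) tidy(x)
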