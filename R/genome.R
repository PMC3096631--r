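#' Reference genomes and planted truth sets
#'
#' A reference genome is a named single-sequence DNA record over \{A,C,G,T\}
#' together with the coordinates (0-based, half-open) of any repeat units that
#' were stamped into it. Substitution truth sets are tibbles with one row per
#' planted single-base substitution.
#'
#' @name genome
NULL

new_reference_genome <- function(name, sequence, repeats = NULL) {
  if (is.null(repeats)) {
    repeats <- tibble(unit = integer(), start = integer(), end = integer())
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence),
         repeats = repeats),
    class = "reference_genome"
  )
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("<reference_genome> %s: %s bp, GC %.1f%%",
              x$name, format(x$length, big.mark = ","),
              100 * gc_content(x)))
  if (nrow(x$repeats) > 0) {
    cat(sprintf(", %d repeat unit(s) of %d bp", nrow(x$repeats),
                x$repeats$end[1] - x$repeats$start[1]))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.reference_genome <- function(x) x$length

#' GC content of a genome
#'
#' @param genome a [reference_genome][generate_reference()].
#' @return Fraction of G+C bases, in `[0, 1]`.
#' @export
gc_content <- function(genome) {
  codes <- dna_to_codes(genome$sequence)
  mean(codes == 2L | codes == 3L)
}

#' Generate a random reference genome
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc_content/2` and
#' `P(A) = P(T) = (1 - gc_content)/2`. The default GC fraction matches a
#' typical *E. coli* genome (50.8%).
#'
#' @param length genome length in bases (positive integer).
#' @param gc_content target GC fraction, in `(0, 1)`; `1` and `0` are allowed
#'   as degenerate compositions.
#' @param seed optional integer seed; identical inputs and seed reproduce the
#'   same genome.
#' @param name sequence name.
#' @return A `reference_genome`.
#' @examples
#' g <- generate_reference(1e4, gc_content = 0.508, seed = 1)
#' gc_content(g)
#' @export
generate_reference <- function(length, gc_content = 0.508, seed = NULL,
                               name = "synthetic") {
  if (!is.numeric(length) || length(length) != 1 || is.na(length) || length < 1) {
    abort("`length` must be a positive integer number of bases")
  }
  check_fraction(gc_content, "gc_content")
  length <- as.integer(length)
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  with_seed_if(seed, {
    codes <- sample.int(4L, length, replace = TRUE, prob = p)
    new_reference_genome(name, codes_to_dna(codes))
  })
}

#' Stamp near-identical repeat units into a genome
#'
#' Emulates multi-copy near-identical repeats such as bacterial rRNA operons:
#' `n_copies` copies of one randomly generated unit are written over the
#' existing sequence at non-overlapping positions (genome length is
#' unchanged). Each copy receives exactly `floor(unit_length * divergence / 2)`
#' private substitutions, which guarantees every pair of copies has identity
#' at least `1 - divergence`.
#'
#' @param genome a `reference_genome`.
#' @param n_copies number of copies (>= 2).
#' @param unit_length length of each unit in bases.
#' @param divergence maximum pairwise divergence between copies, in `[0, 1]`;
#'   `0` yields identical copies.
#' @param seed optional integer seed.
#' @return A `reference_genome` whose `$repeats` tibble records the stamped
#'   units (0-based half-open `start`/`end`).
#' @export
insert_repeats <- function(genome, n_copies = 7, unit_length, divergence = 0,
                           seed = NULL) {
  stopifnot(inherits(genome, "reference_genome"))
  if (n_copies < 2) abort("`n_copies` must be >= 2")
  if (unit_length < 1) abort("`unit_length` must be >= 1")
  check_fraction(divergence, "divergence")
  G <- genome$length
  if (n_copies * unit_length >= G) {
    abort("repeat copies do not fit: n_copies * unit_length must be < genome length")
  }
  with_seed_if(seed, {
    gc <- gc_content(genome)
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    unit <- sample.int(4L, unit_length, replace = TRUE, prob = p)
    # rejection-sample non-overlapping placements
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < n_copies) {
      tries <- tries + 1L
      if (tries > 10000L) {
        abort("could not place repeat copies without overlap; reduce n_copies or unit_length")
      }
      cand <- sample.int(G - unit_length + 1L, 1L) - 1L
      if (!any(cand < starts + unit_length & starts < cand + unit_length)) {
        starts <- c(starts, cand)
      }
    }
    starts <- sort(starts)
    codes <- dna_to_codes(genome$sequence)
    n_mut <- floor(unit_length * divergence / 2)
    for (i in seq_len(n_copies)) {
      copy <- unit
      if (n_mut > 0) {
        pos <- sample.int(unit_length, n_mut)
        copy[pos] <- ((copy[pos] - 1L + sample.int(3L, n_mut, replace = TRUE)) %% 4L) + 1L
      }
      codes[(starts[i] + 1L):(starts[i] + unit_length)] <- copy
    }
    new_reference_genome(
      genome$name, codes_to_dna(codes),
      repeats = tibble(unit = seq_len(n_copies), start = starts,
                       end = starts + as.integer(unit_length))
    )
  })
}

#' Plant single-base substitutions into a genome
#'
#' Returns a sample genome differing from `genome` at exactly `n_subs`
#' positions, plus the truth set. A share `in_repeats_fraction` of the
#' substitutions is directed into recorded repeat units; those are placed at
#' least `repeat_margin` bases inside unit boundaries so that, for typical
#' short reads, every read covering them lies wholly within the repeat.
#'
#' @param genome a `reference_genome` (with `$repeats` recorded if
#'   `in_repeats_fraction > 0`).
#' @param n_subs number of substitutions to plant.
#' @param seed optional integer seed.
#' @param in_repeats_fraction fraction of substitutions placed inside repeat
#'   units, in `[0, 1]`.
#' @param repeat_margin minimum distance (bases) of in-repeat substitutions
#'   from the unit boundaries.
#' @return A list with `genome` (the mutated sample genome) and `truth`, a
#'   tibble with columns `position` (0-based), `ref`, `alt`, `in_repeat`.
#' @export
plant_substitutions <- function(genome, n_subs, seed = NULL,
                                in_repeats_fraction = 0, repeat_margin = 100) {
  stopifnot(inherits(genome, "reference_genome"))
  check_fraction(in_repeats_fraction, "in_repeats_fraction")
  if (n_subs < 0 || n_subs > genome$length) {
    abort("`n_subs` must be between 0 and the genome length")
  }
  n_subs <- as.integer(n_subs)
  codes <- dna_to_codes(genome$sequence)
  G <- genome$length
  rep_pos <- integer(0)
  if (nrow(genome$repeats) > 0) {
    rep_pos <- unlist(purrr::map2(genome$repeats$start, genome$repeats$end,
                                  function(s, e) {
      lo <- s + repeat_margin
      hi <- e - repeat_margin - 1L
      if (hi < lo) integer(0) else lo:hi
    }))
  }
  n_in <- as.integer(round(in_repeats_fraction * n_subs))
  if (n_in > length(rep_pos)) {
    abort("not enough interior repeat positions for the requested in-repeat substitutions")
  }
  all_rep <- if (nrow(genome$repeats) > 0) {
    unlist(purrr::map2(genome$repeats$start, genome$repeats$end,
                       function(s, e) s:(e - 1L)))
  } else integer(0)
  out_pool <- setdiff(0:(G - 1L), all_rep)
  if (n_subs - n_in > length(out_pool)) {
    abort("not enough non-repeat positions for the requested substitutions")
  }
  with_seed_if(seed, {
    pos_in <- if (n_in > 0) sample(rep_pos, n_in) else integer(0)
    pos_out <- if (n_subs - n_in > 0) sample(out_pool, n_subs - n_in) else integer(0)
    pos <- c(pos_in, pos_out)
    in_repeat <- c(rep(TRUE, n_in), rep(FALSE, n_subs - n_in))
    o <- order(pos)
    pos <- pos[o]; in_repeat <- in_repeat[o]
    ref_codes <- codes[pos + 1L]
    alt_codes <- ((ref_codes - 1L + sample.int(3L, n_subs, replace = TRUE)) %% 4L) + 1L
    codes[pos + 1L] <- alt_codes
    list(
      genome = new_reference_genome(paste0(genome$name, "_sample"),
                                    codes_to_dna(codes), genome$repeats),
      truth = tibble(position = as.integer(pos),
                     ref = DNA_BASES[ref_codes], alt = DNA_BASES[alt_codes],
                     in_repeat = in_repeat)
    )
  })
}

#' Rebuild a truth set by diffing two genomes
#'
#' Position-by-position comparison of two equal-length genomes; the result has
#' the same columns as [plant_substitutions()]'s truth (minus `in_repeat`).
#'
#' @param genome,sample_genome two `reference_genome`s of equal length.
#' @return A tibble with `position` (0-based), `ref`, `alt`.
#' @export
truth_from_diff <- function(genome, sample_genome) {
  a <- dna_to_codes(genome$sequence)
  b <- dna_to_codes(sample_genome$sequence)
  if (length(a) != length(b)) abort("genomes differ in length")
  d <- which(a != b)
  tibble(position = d - 1L, ref = DNA_BASES[a[d]], alt = DNA_BASES[b[d]])
}
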