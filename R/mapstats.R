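#' Mapping summary statistics
#'
#' These functions reproduce the read-quality comparison metrics: the ratio
#' of mapped reads, per-base accuracy of mapped bases, the mismatch-by-cycle
#' profile, per-position coverage depth with uncovered bases, and the GC
#' content of position sets.
#'
#' @name mapstats
NULL

#' Ratio of mapped reads
#'
#' Distinct mapped reads divided by total reads, in percent. With the
#' `best_all` policy a multiply-placed read still counts once.
#'
#' @param alnset an `alignment_set` produced from `reads`.
#' @param reads the read tibble that was mapped.
#' @return Percentage in `[0, 100]`.
#' @export
mapped_ratio <- function(alnset, reads) {
  check_read_set(reads)
  if (nrow(reads) == 0) abort("`reads` is empty")
  100 * length(unique(alnset$read_id)) / nrow(reads)
}

#' Per-base accuracy of mapped reads
#'
#' Aligned bases consistent with the reference divided by total aligned
#' bases, in percent. The denominator is aligned *bases*: a per-base ratio
#' needs base units in both numerator and denominator.
#'
#' @param alnset an `alignment_set`.
#' @param genome the reference the alignments are on.
#' @return Percentage in `[0, 100]`.
#' @export
per_base_accuracy <- function(alnset, genome) {
  if (nrow(alnset) == 0) abort("alignment set is empty")
  total <- sum(nchar(alnset$seq))
  mism <- sum(alnset$mismatches)
  100 * (total - mism) / total
}

#' Mismatch ratio by read position (sequencing cycle)
#'
#' Tallies mismatches in read coordinates: position 1 is the sequencing
#' start, so minus-strand alignments are reversed before tallying (the
#' mechanism behind position-dependent error, signal decay, is cycle-indexed).
#'
#' @param alnset an `alignment_set`.
#' @param genome the reference genome.
#' @return A `mismatch_profile` tibble with `position` (1-based cycle),
#'   `mapped_bases`, `mismatches`, `mismatch_ratio`.
#' @export
mismatch_by_position <- function(alnset, genome) {
  lens <- nchar(alnset$seq)
  max_len <- if (nrow(alnset) == 0) 0L else max(lens)
  denom <- rev(cumsum(rev(tabulate(lens, nbins = max_len))))
  minus <- alnset$strand == "-"
  cyc <- purrr::pmap(list(alnset$mm_offsets, lens, minus), function(off, L, m) {
    if (length(off) == 0) return(integer(0))
    if (m) L - off else off + 1L
  })
  mm <- tabulate(unlist(cyc), nbins = max_len)
  structure(
    tibble(position = seq_len(max_len), mapped_bases = denom, mismatches = mm,
           mismatch_ratio = ifelse(denom > 0, mm / denom, 0)),
    class = c("mismatch_profile", class(tibble())))
}

#' Coverage depth and uncovered positions
#'
#' Depth counts every aligned base (under `best_all`, tied placements each
#' contribute). Uncovered positions are those with zero depth; mean coverage
#' is `sum(depth) / genome length`.
#'
#' @param alnset an `alignment_set`.
#' @param genome the reference genome.
#' @return A `depth_track`: list with `depth` (integer vector over the
#'   reference), `uncovered` (0-based positions), `mean_coverage`.
#' @export
depth_and_uncovered <- function(alnset, genome) {
  G <- genome$length
  delta <- integer(G + 1L)
  if (nrow(alnset) > 0) {
    s <- alnset$start + 1L
    e <- alnset$start + nchar(alnset$seq) + 1L
    add_s <- tabulate(s, nbins = G + 1L)
    add_e <- tabulate(e, nbins = G + 1L)
    delta <- add_s - add_e
  }
  depth <- cumsum(delta)[seq_len(G)]
  structure(
    list(depth = as.integer(depth),
         uncovered = which(depth == 0L) - 1L,
         mean_coverage = sum(as.numeric(depth)) / G),
    class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("<depth_track> mean coverage %.2f, %d uncovered position(s) of %d\n",
              x$mean_coverage, length(x$uncovered), length(x$depth)))
  invisible(x)
}

#' Remove the common uncovered core from per-method uncovered sets
#'
#' Each output set is the input set minus the intersection of all inputs,
#' isolating platform-specific coverage failures from positions no method can
#' cover (e.g. long near-identical repeats).
#'
#' @param sets named list (>= 2) of 0-based position vectors.
#' @return A list of the same shape with the common intersection removed.
#' @export
uncommon_uncovered <- function(sets) {
  if (length(sets) < 2) abort("need at least 2 position sets")
  common <- Reduce(intersect, sets)
  lapply(sets, function(s) setdiff(s, common))
}

#' GC content of a set of reference positions
#'
#' @param positions 0-based positions.
#' @param genome the reference genome.
#' @return Percentage of G+C among the given positions.
#' @export
gc_of_positions <- function(positions, genome) {
  if (length(positions) == 0) abort("`positions` is empty")
  if (any(positions < 0 | positions >= genome$length)) {
    abort("positions out of range")
  }
  codes <- dna_to_codes(genome$sequence)[positions + 1L]
  100 * mean(codes == 2L | codes == 3L)
}

#' Write uncovered intervals as BED
#'
#' Consecutive uncovered positions are merged into 0-based half-open
#' intervals.
#'
#' @param positions 0-based uncovered positions.
#' @param chrom sequence name.
#' @param path output path.
#' @export
write_uncovered_bed <- function(positions, path, chrom = "ref") {
  if (length(positions) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  positions <- sort(unique(as.integer(positions)))
  brk <- c(0L, which(diff(positions) > 1L), length(positions))
  starts <- positions[brk[-length(brk)] + 1L]
  ends <- positions[brk[-1]] + 1L
  write.table(data.frame(chrom = chrom, start = starts, end = ends), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
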