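#' Ungapped read mapping with a mismatch budget
#'
#' Aligns every read to both strands of the reference at every ungapped,
#' fully-contained offset with Hamming distance at most `max_mismatch`
#' (default 3). Among a read's candidate placements the minimum-mismatch
#' stratum is selected; ties are then resolved by the multi-mapping policy:
#'
#' * `"best_all"` — the read is placed at every tied position, as if it were
#'   multiplied (used for the mapping-quality comparison).
#' * `"unique_only"` — reads whose best stratum contains more than one
#'   placement are excluded entirely (used for substitution calling).
#'
#' Quality values are ignored during mapping; `N` bases never match. Reads
#' longer than the reference are counted unmapped with a warning.
#'
#' @param reads a read tibble.
#' @param genome a `reference_genome`.
#' @param max_mismatch maximum Hamming distance (whole read).
#' @param policy multi-mapping policy.
#' @return An `alignment_set`: a tibble with columns `read_id`, `start`
#'   (0-based), `strand`, `mismatches`, `mm_offsets` (list of 0-based offsets
#'   within the reference-oriented sequence) and `seq` (the read in reference
#'   orientation). Attributes: `policy`, `unmapped_count` (reads with no
#'   placement within budget), `multi_count` (reads excluded as multi-mapping
#'   under `unique_only`), `n_reads`, `ref_name`, `ref_length`.
#' @export
map_reads <- function(reads, genome, max_mismatch = 3L,
                      policy = c("best_all", "unique_only")) {
  check_read_set(reads)
  policy <- match.arg(policy)
  stopifnot(inherits(genome, "reference_genome"))
  if (max_mismatch < 0) abort("`max_mismatch` must be >= 0")
  if (nrow(reads) == 0) abort("`reads` is empty")
  too_long <- nchar(reads$sequence) > genome$length
  if (any(too_long)) {
    warn(sprintf("%d read(s) longer than the reference counted as unmapped",
                 sum(too_long)))
  }
  res <- cpp_map_reads(toupper(reads$sequence), genome$sequence,
                       as.integer(max_mismatch))
  aln <- tibble(
    read_id = reads$id[res$read],
    start = res$start,
    strand = ifelse(res$minus, "-", "+"),
    mismatches = res$mismatches,
    mm_offsets = res$mm_offsets,
    seq = res$seq
  )
  n_hits <- res$n_hits
  unmapped <- sum(n_hits == 0L)
  multi <- 0L
  if (policy == "unique_only") {
    multi <- sum(n_hits > 1L)
    aln <- aln[n_hits[res$read] == 1L, , drop = FALSE]
  }
  new_alignment_set(aln, policy, unmapped, multi, nrow(reads), genome)
}

new_alignment_set <- function(aln, policy, unmapped, multi, n_reads, genome) {
  structure(
    aln,
    policy = policy,
    unmapped_count = as.integer(unmapped),
    multi_count = as.integer(multi),
    n_reads = as.integer(n_reads),
    ref_name = genome$name,
    ref_length = genome$length,
    class = c("alignment_set", class(tibble())))
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("<alignment_set> %d alignment(s) of %d read(s) on %s (%s policy, %d unmapped%s)\n",
              nrow(x), attr(x, "n_reads"), attr(x, "ref_name"),
              attr(x, "policy"), attr(x, "unmapped_count"),
              if (attr(x, "policy") == "unique_only")
                sprintf(", %d multi-mapping excluded", attr(x, "multi_count"))
              else ""))
  NextMethod()
}

#' Write alignments as SAM
#'
#' Minimal single-reference SAM: FLAG carries only the strand bit, POS is
#' 1-based, CIGAR is always fully-matched (`<L>M`), SEQ is in reference
#' orientation, QUAL is `*`, and an `NM` tag carries the mismatch count.
#'
#' @param alnset an `alignment_set`.
#' @param path output path.
#' @export
write_sam <- function(alnset, path) {
  stopifnot(inherits(alnset, "alignment_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", attr(alnset, "ref_name"),
                       attr(alnset, "ref_length"))), con)
  if (nrow(alnset) > 0) {
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                       alnset$read_id, ifelse(alnset$strand == "-", 16L, 0L),
                       attr(alnset, "ref_name"), alnset$start + 1L,
                       nchar(alnset$seq), alnset$seq, alnset$mismatches), con)
  }
  invisible(path)
}

#' Import alignments from SAM
#'
#' Lets an external aligner substitute for [map_reads()]. Records are
#' converted to ungapped alignments with mismatches recomputed against the
#' reference (tags are not trusted). Records whose CIGAR contains indels or
#' clipping, or whose recomputed mismatch count exceeds `max_mismatch`, are
#' dropped and counted; the minimum-mismatch stratum and multi-mapping policy
#' are then applied exactly as in [map_reads()].
#'
#' @param path SAM file path.
#' @param genome the `reference_genome` the records were aligned to.
#' @param max_mismatch mismatch budget.
#' @param policy multi-mapping policy.
#' @return An `alignment_set`; attribute `dropped_count` reports records
#'   removed for indels/clipping or budget excess.
#' @export
import_sam <- function(path, genome, max_mismatch = 3L,
                       policy = c("best_all", "unique_only")) {
  policy <- match.arg(policy)
  stopifnot(inherits(genome, "reference_genome"))
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "cigar", "strand", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !is.na(x$pos)
  qname <- x$qname[mapped]
  pos <- x$pos[mapped]
  cigar <- x$cigar[mapped]
  strand <- as.character(x$strand)[mapped]
  seqs <- as.character(x$seq)[mapped]
  ref_ok <- as.character(x$rname)[mapped] == genome$name
  if (any(!ref_ok)) {
    abort(sprintf("SAM references sequences absent from the reference genome: %s",
                  paste(unique(as.character(x$rname)[mapped][!ref_ok]), collapse = ", ")))
  }
  ungapped <- grepl("^[0-9]+M$", cigar)
  dropped <- sum(!ungapped)
  qname <- qname[ungapped]; pos <- pos[ungapped]
  strand <- strand[ungapped]; seqs <- toupper(seqs[ungapped])
  in_range <- pos - 1L + nchar(seqs) <= genome$length & pos >= 1L
  dropped <- dropped + sum(!in_range)
  qname <- qname[in_range]; pos <- pos[in_range]
  strand <- strand[in_range]; seqs <- seqs[in_range]
  rc <- cpp_recompute_mismatches(pos - 1L, seqs, genome$sequence)
  keep <- rc$mismatches <= max_mismatch
  dropped <- dropped + sum(!keep)
  aln <- tibble(read_id = qname[keep], start = pos[keep] - 1L,
                strand = strand[keep], mismatches = rc$mismatches[keep],
                mm_offsets = rc$mm_offsets[keep], seq = seqs[keep])
  # best-stratum selection + policy, mirroring map_reads()
  aln <- aln |>
    dplyr::group_by(.data$read_id) |>
    dplyr::filter(.data$mismatches == min(.data$mismatches)) |>
    dplyr::mutate(.n_best = dplyr::n()) |>
    dplyr::ungroup()
  multi <- 0L
  if (policy == "unique_only") {
    multi <- length(unique(aln$read_id[aln$.n_best > 1L]))
    aln <- aln[aln$.n_best == 1L, , drop = FALSE]
  }
  aln$.n_best <- NULL
  out <- new_alignment_set(aln, policy, NA_integer_, multi,
                           length(unique(qname)), genome)
  attr(out, "dropped_count") <- as.integer(dropped)
  out
}
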