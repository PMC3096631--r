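#' Quality trimming policy
#'
#' The defaults are the literal filtering rule applied to GA-style reads
#' before mapping comparison: trim bases whose quality value is below 0 and
#' drop trimmed reads shorter than 32 bases.
#'
#' Two trim modes are provided. `"three_prime_run"` (default) removes the
#' maximal 3'-terminal run of sub-threshold bases, reflecting that low
#' quality accumulates at the 3' end as fluorescent signal decays; literal
#' per-base removal would create chimeric reads. `"per_base_mask"` is the
#' literal reading: every sub-threshold base is replaced by `N` and therefore
#' excluded from downstream pileup and error-matrix counting.
#'
#' @param qv_threshold integer QV threshold; bases with QV strictly below it
#'   are trimmed/masked.
#' @param min_length minimum post-trim read length (bases).
#' @param trim_mode `"three_prime_run"` or `"per_base_mask"`.
#' @return A `trim_policy` object.
#' @export
trim_policy <- function(qv_threshold = 0L, min_length = 32L,
                        trim_mode = c("three_prime_run", "per_base_mask")) {
  trim_mode <- match.arg(trim_mode)
  if (min_length < 1) abort("`min_length` must be >= 1")
  structure(list(qv_threshold = as.integer(qv_threshold),
                 min_length = as.integer(min_length), trim_mode = trim_mode),
            class = "trim_policy")
}

#' Trim reads by quality value
#'
#' @param reads a read tibble with a `quality` list-column.
#' @param policy a [trim_policy()].
#' @return The read tibble with sequences (and qualities) trimmed or masked.
#'   Reads trimmed to length 0 are kept as empty reads (use [filter_short()]
#'   to drop them).
#' @export
trim_by_quality <- function(reads, policy = trim_policy()) {
  check_read_set(reads)
  if (is.null(reads$quality)) abort("reads lack quality values")
  missing_q <- vapply(reads$quality, is.null, logical(1))
  if (any(missing_q)) {
    abort(sprintf("reads lack quality values (first offender: %s)",
                  reads$id[which(missing_q)[1]]))
  }
  thr <- policy$qv_threshold
  if (policy$trim_mode == "three_prime_run") {
    keep_len <- vapply(reads$quality, function(q) {
      low_rev <- rev(q) < thr
      k <- which(!low_rev)
      if (length(k) == 0) 0L else length(q) - (k[1] - 1L)
    }, integer(1))
    reads$sequence <- substr(reads$sequence, 1L, keep_len)
    reads$quality <- purrr::map2(reads$quality, keep_len, ~ .x[seq_len(.y)])
  } else {
    masked <- purrr::map2(reads$sequence, reads$quality, function(s, q) {
      low <- q < thr
      if (!any(low)) return(s)
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      ch[low] <- "N"
      paste(ch, collapse = "")
    })
    reads$sequence <- unlist(masked)
  }
  reads
}

#' Drop reads shorter than a minimum length
#'
#' Boundary is inclusive: reads of exactly `min_length` bases survive.
#' Relative order is preserved.
#'
#' @param reads a read tibble.
#' @param min_length minimum length in bases.
#' @export
filter_short <- function(reads, min_length = 32L) {
  check_read_set(reads)
  reads[nchar(reads$sequence) >= min_length, , drop = FALSE]
}

#' Strip adapter sequences from read ends
#'
#' Exact, end-anchored matching only: each adapter is removed where it is a
#' literal prefix or suffix of the read. Internal occurrences are untouched.
#'
#' @param reads a read tibble.
#' @param adapters non-empty character vector of adapter sequences.
#' @export
strip_adapters <- function(reads, adapters) {
  check_read_set(reads)
  if (length(adapters) == 0) abort("`adapters` must be non-empty")
  has_q <- !is.null(reads$quality)
  seqs <- reads$sequence
  cut5 <- integer(length(seqs)); cut3 <- integer(length(seqs))
  for (a in adapters) {
    na <- nchar(a)
    pre <- startsWith(substring(seqs, cut5 + 1L), a)
    cut5[pre] <- cut5[pre] + na
    body <- substring(seqs, cut5 + 1L, nchar(seqs) - cut3)
    suf <- endsWith(body, a) & nchar(body) >= na
    cut3[suf] <- cut3[suf] + na
  }
  reads$sequence <- substring(seqs, cut5 + 1L, nchar(seqs) - cut3)
  if (has_q) {
    reads$quality <- purrr::pmap(list(reads$quality, cut5, cut3), function(q, c5, c3) {
      if (is.null(q)) NULL else q[seq.int(c5 + 1L, length.out = length(q) - c5 - c3)]
    })
  }
  reads
}
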