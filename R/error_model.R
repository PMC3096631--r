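#' Empirical read-probability (error) matrix
#'
#' Tallies every aligned (reference base `b`, read base `b'`) pair over an
#' alignment set and row-normalises with additive smoothing:
#' `p(b'|b) = (m(b'|b) + pseudocount) / sum_b'(m(b'|b) + pseudocount)`.
#' Read bases from minus-strand alignments are complemented into reference
#' orientation before tallying; `N` bases contribute no count. The matrix is
#' pooled genome-wide over all positions.
#'
#' The default pseudocount of 1 (add-one smoothing) prevents structural zeros:
#' the calling likelihood raises these probabilities to per-position depth
#' powers, so a zero entry would let a single stray read veto a base.
#'
#' @param alnset an `alignment_set` (use the same `unique_only` alignments as
#'   for calling).
#' @param genome the reference genome.
#' @param pseudocount non-negative additive smoothing count.
#' @return An `error_matrix`: list with `counts` and `prob` (4x4, rows = ref
#'   base `b`, cols = read base `b'`) and `pseudocount`.
#' @export
estimate_read_probability <- function(alnset, genome, pseudocount = 1) {
  if (nrow(alnset) == 0) abort("alignment set is empty")
  if (pseudocount < 0) abort("`pseudocount` must be >= 0")
  counts <- cpp_error_counts(alnset$start, alnset$seq, genome$sequence)
  dimnames(counts) <- list(ref = DNA_BASES, read = DNA_BASES)
  new_error_matrix(counts, pseudocount)
}

new_error_matrix <- function(counts, pseudocount) {
  rs <- rowSums(counts + pseudocount)
  if (any(rs == 0)) {
    abort(sprintf(
      "reference base(s) %s have zero aligned counts; use a positive pseudocount",
      paste(DNA_BASES[rs == 0], collapse = ", ")))
  }
  prob <- (counts + pseudocount) / rs
  structure(list(counts = counts, prob = prob, pseudocount = pseudocount),
            class = "error_matrix")
}

#' Build an error matrix from a probability matrix
#'
#' Convenience constructor for analyses that start from a known error model
#' (e.g. a uniform per-base error rate) rather than from alignments.
#'
#' @param prob 4x4 row-stochastic matrix (rows = reference base, cols = read
#'   base), or a single uniform per-base error rate `e` from which the matrix
#'   `diag = 1 - e`, `off-diag = e/3` is built.
#' @return An `error_matrix` with zero counts.
#' @export
make_error_matrix <- function(prob) {
  if (length(prob) == 1) {
    e <- prob
    check_fraction(e, "error rate")
    prob <- matrix(e / 3, 4, 4)
    diag(prob) <- 1 - e
  }
  stopifnot(is.matrix(prob), all(dim(prob) == c(4, 4)))
  if (any(prob < 0) || any(abs(rowSums(prob) - 1) > 1e-8)) {
    abort("`prob` must be row-stochastic (rows sum to 1)")
  }
  dimnames(prob) <- list(ref = DNA_BASES, read = DNA_BASES)
  counts <- matrix(0L, 4, 4, dimnames = dimnames(prob))
  structure(list(counts = counts, prob = prob, pseudocount = 0),
            class = "error_matrix")
}

#' @export
print.error_matrix <- function(x, ...) {
  cat(sprintf("<error_matrix> p(read base | reference base), pseudocount %g\n",
              x$pseudocount))
  print(round(x$prob, 5))
  invisible(x)
}

#' @export
tidy.error_matrix <- function(x, ...) {
  tibble(
    ref_base = rep(DNA_BASES, times = 4),
    read_base = rep(DNA_BASES, each = 4),
    count = as.vector(x$counts),
    prob = as.vector(x$prob)
  )
}

#' Read and write error matrices
#'
#' Tab-separated 4x4 probability matrix with row/column base labels; the
#' pseudocount travels in a `# pseudocount:` header comment.
#'
#' @param errmatrix an `error_matrix`.
#' @param path file path.
#' @export
write_error_matrix <- function(errmatrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pseudocount: %g", errmatrix$pseudocount), con)
  writeLines(paste(c("ref", DNA_BASES), collapse = "\t"), con)
  for (i in 1:4) {
    writeLines(paste(c(DNA_BASES[i], format(errmatrix$prob[i, ], digits = 17)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_error_matrix
#' @export
read_error_matrix <- function(path) {
  lines <- readLines(path)
  ps <- as.numeric(sub("# pseudocount:\\s*", "", lines[1]))
  x <- read.table(text = lines[-1], sep = "\t", header = TRUE, row.names = 1)
  prob <- as.matrix(x)
  dimnames(prob) <- list(ref = DNA_BASES, read = DNA_BASES)
  out <- make_error_matrix(prob / rowSums(prob))
  out$pseudocount <- ps
  out
}
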