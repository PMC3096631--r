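# Independent oracles used across the suite. These stay deliberately naive:
# the mapper oracle scans every offset on both strands, and the posterior
# oracle works in exact integer arithmetic (all intermediates < 2^53).

BASES <- c("A", "C", "G", "T")

codes_of <- function(s) match(strsplit(toupper(s), "", fixed = TRUE)[[1]], BASES)

rc_of <- function(s) {
  v <- rev(codes_of(s))
  paste(BASES[5 - v], collapse = "")
}

# exhaustive-offset ungapped mapping oracle; returns the minimum-mismatch
# stratum per read under best_all, or drops tied reads under unique_only
oracle_map <- function(reads, genome, max_mm, policy = "best_all") {
  gc <- codes_of(genome$sequence)
  G <- length(gc)
  rows <- list()
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[i]
    L <- nchar(s)
    if (L == 0 || L > G) next
    hits <- list()
    for (strand in c("+", "-")) {
      q <- codes_of(if (strand == "+") s else rc_of(s))
      n_off <- G - L + 1
      idx <- outer(seq_len(n_off) - 1L, seq_len(L), "+")
      ref_mat <- matrix(gc[idx], n_off, L)
      qm <- matrix(rep(q, each = n_off), n_off, L)
      mm <- rowSums(ref_mat != qm | is.na(qm))
      ok <- which(mm <= max_mm)
      if (length(ok) > 0) {
        hits[[strand]] <- data.frame(start = ok - 1L, strand = strand,
                                     mismatches = mm[ok])
      }
    }
    if (length(hits) == 0) next
    h <- do.call(rbind, hits)
    h <- h[h$mismatches == min(h$mismatches), , drop = FALSE]
    if (policy == "unique_only" && nrow(h) > 1) next
    h$read_id <- reads$id[i]
    rows[[length(rows) + 1]] <- h
  }
  if (length(rows) == 0) {
    return(tibble::tibble(read_id = character(), start = integer(),
                          strand = character(), mismatches = integer()))
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  dplyr::arrange(out[, c("read_id", "start", "strand", "mismatches")],
                 read_id, start, strand)
}

aln_key <- function(alnset) {
  dplyr::arrange(
    tibble::tibble(read_id = alnset$read_id, start = as.integer(alnset$start),
                   strand = alnset$strand,
                   mismatches = as.integer(alnset$mismatches)),
    read_id, start, strand)
}

# Exact posterior over the four bases: probabilities are num[b, b'] / denom
# with integer numerators, so likelihood numerators are exact integers.
posterior_oracle <- function(counts, num, denom) {
  coef <- factorial(sum(counts)) / prod(factorial(counts))
  lik <- vapply(1:4, function(b) coef * prod(num[b, ]^counts), numeric(1))
  lik / sum(lik)
}

# all count vectors over 4 categories with total depth exactly d
count_vectors_of_depth <- function(d) {
  grid <- expand.grid(A = 0:d, C = 0:d, G = 0:d)
  grid <- grid[grid$A + grid$C + grid$G <= d, , drop = FALSE]
  grid$T <- d - grid$A - grid$C - grid$G
  as.matrix(grid[, c("A", "C", "G", "T")])
}

# small deterministic read tibble
toy_reads <- function(seqs, quals = NULL, platform = "toy") {
  tibble::tibble(
    id = sprintf("r%03d", seq_along(seqs)),
    sequence = seqs,
    quality = if (is.null(quals)) rep(list(NULL), length(seqs)) else quals,
    platform = platform
  )
}

# fixed-composition error-free profile
clean_profile <- function(read_length = 36, junk_fraction = 0, name = "clean") {
  platform_profile(name, read_length,
                   error_rate = function(k, L) rep(0, length(k)),
                   junk_fraction = junk_fraction)
}
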