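#' Per-position base counts (pileup)
#'
#' Counts, for every reference position, the bases contributed by the aligned
#' reads, with minus-strand reads complemented into reference orientation.
#' Intended for `unique_only` alignment sets (multi-mapping reads are excluded
#' from calling). Masked (`N`) bases contribute no count.
#'
#' @param alnset an `alignment_set`.
#' @param genome the reference genome.
#' @return A `pileup`: list with `counts` (4 x genome-length integer matrix,
#'   rows A,C,G,T), `depth` (column sums), `ref_name`, `ref_length`.
#' @export
pileup <- function(alnset, genome) {
  counts <- cpp_pileup(alnset$start, alnset$seq, genome$length)
  rownames(counts) <- DNA_BASES
  structure(list(counts = counts, depth = as.integer(colSums(counts)),
                 ref_name = genome$name, ref_length = genome$length),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %s: %d positions, mean depth %.2f\n", x$ref_name,
              x$ref_length, mean(x$depth)))
  invisible(x)
}

#' @export
as_tibble.pileup <- function(x, ...) {
  tibble(position = seq_len(x$ref_length) - 1L,
         A = x$counts[1, ], C = x$counts[2, ],
         G = x$counts[3, ], T = x$counts[4, ],
         depth = x$depth)
}

base_index <- function(b) {
  i <- match(toupper(b), DNA_BASES)
  if (any(is.na(i))) abort("base must be one of A, C, G, T")
  i
}

#' Multinomial log-probability of a pileup observation
#'
#' Log of the multinomial probability of observing the count vector
#' `N = (N_A, N_C, N_G, N_T)` at one position when the true genomic base is
#' `b`, with category probabilities `p(.|b)` taken from the error matrix:
#' `log [ (sum N)! / prod N_b'! * prod p(b'|b)^N_b' ]`, evaluated in log
#' space. A zero probability paired with a positive count yields `-Inf`
#' (not an error).
#'
#' @param counts integer vector of 4 base counts (A, C, G, T order).
#' @param errmatrix an `error_matrix`.
#' @param true_base the hypothesised genomic base ("A", "C", "G" or "T").
#' @param include_coefficient include the multinomial coefficient (it cancels
#'   in the posterior normalisation).
#' @return Log-probability (scalar, possibly `-Inf`).
#' @export
observation_log_probability <- function(counts, errmatrix, true_base,
                                        include_coefficient = TRUE) {
  stopifnot(length(counts) == 4, all(counts >= 0))
  p <- errmatrix$prob[base_index(true_base), ]
  terms <- numeric(4)
  pos <- counts > 0
  if (any(p[pos] == 0)) return(-Inf)
  terms[pos] <- counts[pos] * log(p[pos])
  ll <- sum(terms)
  if (include_coefficient) {
    ll <- ll + lgamma(sum(counts) + 1) - sum(lgamma(counts + 1))
  }
  ll
}

#' Posterior probability of each genomic base at one position
#'
#' Bayes' rule with a uniform prior of 1/4 per base over the four multinomial
#' observation likelihoods, normalised with a numerically stable log-sum-exp.
#' At depth 0 the posterior equals the prior.
#'
#' @inheritParams observation_log_probability
#' @return Named numeric vector of 4 posteriors summing to 1.
#' @export
posterior_probs <- function(counts, errmatrix) {
  ll <- vapply(DNA_BASES, function(b) {
    observation_log_probability(counts, errmatrix, b, include_coefficient = FALSE)
  }, numeric(1))
  if (all(is.infinite(ll) & ll < 0)) {
    abort("all four likelihoods are zero: error matrix inconsistent with counts")
  }
  m <- max(ll)
  w <- exp(ll - m)
  w / sum(w)
}

#' Call the consensus base at one position
#'
#' The consensus is the posterior argmax (ties broken towards the
#' lexicographically smallest base and flagged `ambiguous`). A position is a
#' significant substitution when the consensus differs from the reference
#' base, its posterior exceeds `threshold`, and depth is positive (depth-0
#' positions are uncovered, never substitutions).
#'
#' @inheritParams observation_log_probability
#' @param ref_base reference base at the position.
#' @param threshold posterior probability threshold (default 1e-8, applied as
#'   strictly-greater-than).
#' @return One-row tibble: `consensus`, `consensus_posterior`, `ref_base`,
#'   `depth`, `is_substitution`, `ambiguous`, `posterior` (list column).
#' @export
call_position <- function(counts, errmatrix, ref_base, threshold = 1e-8) {
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1]")
  post <- posterior_probs(counts, errmatrix)
  i <- which.max(post)
  amb <- sum(post == post[i]) > 1
  depth <- sum(counts)
  tibble(
    consensus = DNA_BASES[i],
    consensus_posterior = post[[i]],
    ref_base = toupper(ref_base),
    depth = as.integer(depth),
    is_substitution = depth > 0 && DNA_BASES[i] != toupper(ref_base) &&
      post[[i]] > threshold,
    ambiguous = amb,
    posterior = list(post)
  )
}

LOG_FLOOR <- -1e9  # stands in for log(0) in the vectorised likelihood

#' Call significant substitutions over a whole pileup
#'
#' Vectorised per-position consensus calling: for every covered position the
#' posterior over the four genomic bases is computed from the multinomial
#' likelihood (the multinomial coefficient cancels in the normalisation) and
#' positions whose consensus differs from the reference with posterior above
#' `threshold` are reported. Depth-0 positions are never called.
#'
#' @param pile a [pileup()].
#' @param genome the reference genome.
#' @param errmatrix an `error_matrix`.
#' @param threshold consensus posterior threshold (default 1e-8).
#' @return A tibble sorted by position: `position` (0-based), `ref`, `alt`,
#'   `posterior`, `depth`, `A`, `C`, `G`, `T`, `ambiguous`.
#' @export
call_substitutions <- function(pile, genome, errmatrix, threshold = 1e-8) {
  stopifnot(inherits(pile, "pileup"), inherits(errmatrix, "error_matrix"))
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1]")
  logp <- log(errmatrix$prob)
  logp[errmatrix$prob == 0] <- LOG_FLOOR
  counts <- pile$counts
  ll <- logp %*% counts                 # 4 x G: rows = hypothesised base b
  mx <- apply(ll, 2, max)
  post <- exp(sweep(ll, 2, mx))
  post <- sweep(post, 2, colSums(post), "/")
  cons <- max.col(t(ll), ties.method = "first")  # lexicographic tie-break
  n_max <- colSums(ll == rep(mx, each = 4L))
  ref_codes <- dna_to_codes(genome$sequence)
  depth <- pile$depth
  cons_post <- post[cbind(cons, seq_along(cons))]
  is_sub <- depth > 0L & cons != ref_codes & cons_post > threshold
  idx <- which(is_sub)
  tibble(
    position = idx - 1L,
    ref = DNA_BASES[ref_codes[idx]],
    alt = DNA_BASES[cons[idx]],
    posterior = cons_post[idx],
    depth = depth[idx],
    A = counts[1, idx], C = counts[2, idx],
    G = counts[3, idx], T = counts[4, idx],
    ambiguous = n_max[idx] > 1L
  )
}

#' Export substitution calls
#'
#' `write_vcf()` writes a minimal VCF 4.2 (CHROM, 1-based POS, REF, ALT,
#' QUAL = -10 log10(1 - posterior) capped at 99, INFO with depth and the four
#' base counts). `write_calls_tsv()` writes the same information as a
#' tab-separated table.
#'
#' @param calls a call tibble from [call_substitutions()].
#' @param genome the reference genome (names the CHROM column).
#' @param path output path.
#' @export
write_vcf <- function(calls, genome, path) {
  qual <- -10 * log10(pmax(1 - calls$posterior, 1e-10))
  qual <- pmin(qual, 99)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", genome$name, genome$length),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Pileup depth\">",
    "##INFO=<ID=BC,Number=4,Type=Integer,Description=\"Base counts A,C,G,T\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls) > 0) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%.2f\tPASS\tDP=%d;BC=%d,%d,%d,%d",
                       genome$name, calls$position + 1L, calls$ref, calls$alt,
                       qual, calls$depth, calls$A, calls$C, calls$G, calls$T),
               con)
  }
  invisible(path)
}

#' @rdname write_vcf
#' @export
write_calls_tsv <- function(calls, genome, path) {
  out <- data.frame(chrom = genome$name, pos = calls$position + 1L,
                    ref = calls$ref, alt = calls$alt,
                    A = calls$A, C = calls$C, G = calls$G, T = calls$T,
                    depth = calls$depth, posterior = calls$posterior)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
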