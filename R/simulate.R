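#' Simulate platform-styled reads from a genome
#'
#' Draws approximately `mean_coverage * length(genome) / read_length` reads.
#' Each read is independently junk (uniform random sequence) with probability
#' `profile$junk_fraction`; non-junk reads are sampled uniformly from either
#' strand (minus-strand windows are reverse-complemented so that read
#' position 1 is always the sequencing start), then per-cycle substitution
#' errors are injected according to the profile's error model. Quality values
#' are emitted from the profile's `qv_model` applied to the error probability
#' actually used at each base, so decayed read tails receive negative
#' Solexa-scale QVs.
#'
#' @param genome a [reference_genome][generate_reference()] (typically the
#'   mutated sample genome).
#' @param profile a [platform_profile()].
#' @param mean_coverage target mean fold-coverage of genomic (non-junk,
#'   non-adapter) bases before junk dilution.
#' @param seed optional integer seed; fixed seed gives byte-identical FASTQ.
#' @return A tibble with columns `id`, `sequence`, `quality` (list of integer
#'   vectors, or `NULL` entries when the profile has no QV model), `platform`,
#'   and ground-truth columns `is_junk`, `true_start` (0-based), `true_strand`.
#' @examples
#' g <- generate_reference(5000, seed = 1)
#' rd <- simulate_reads(g, profile_ga(), mean_coverage = 2, seed = 1)
#' @export
simulate_reads <- function(genome, profile, mean_coverage, seed = NULL) {
  stopifnot(inherits(genome, "reference_genome"),
            inherits(profile, "platform_profile"))
  if (!is.numeric(mean_coverage) || mean_coverage <= 0) {
    abort("`mean_coverage` must be > 0")
  }
  G <- genome$length
  gcodes <- dna_to_codes(genome$sequence)
  n <- max(1L, as.integer(round(mean_coverage * G / profile$read_length)))

  with_seed_if(seed, {
    if (profile$length_sd > 0) {
      lens <- as.integer(round(rnorm(n, profile$read_length, profile$length_sd)))
      lens <- pmin(pmax(lens, 20L), G)
    } else {
      lens <- rep(as.integer(profile$read_length), n)
    }
    junk <- runif(n) < profile$junk_fraction
    minus <- runif(n) < 0.5
    starts <- as.integer(floor(runif(n) * (G - lens + 1L)))  # 0-based
    starts[junk] <- NA_integer_
    decayed <- runif(n) < profile$tail_decay_fraction
    decay_at <- ifelse(decayed,
                       pmax(2L, as.integer(ceiling(2 * lens / 3)) +
                              as.integer(floor(runif(n) * (lens - ceiling(2 * lens / 3) + 1)))),
                       NA_integer_)

    seqs <- character(n)
    quals <- vector("list", n)
    for (L in sort(unique(lens))) {
      idx <- which(lens == L)
      m <- length(idx)
      e_base <- profile$error_rate(seq_len(L), L)
      E <- matrix(rep(e_base, each = m), m, L)
      da <- decay_at[idx]
      has_decay <- !is.na(da)
      if (any(has_decay)) {
        sel <- col(E) >= matrix(ifelse(has_decay, da, L + 1L), m, L)
        E[sel] <- profile$decay_error
      }
      mat <- matrix(0L, m, L)
      jj <- junk[idx]
      if (any(jj)) {
        mat[jj, ] <- sample.int(4L, sum(jj) * L, replace = TRUE)
      }
      if (any(!jj)) {
        gi <- idx[!jj]
        win <- outer(starts[gi], 0:(L - 1L), "+") + 1L
        sub <- matrix(gcodes[win], nrow = length(gi), ncol = L)
        mi <- minus[gi]
        if (any(mi)) sub[mi, ] <- 5L - sub[mi, L:1, drop = FALSE]
        mat[!jj, ] <- sub
        # inject cycle-indexed substitution errors (non-junk reads only)
        Eg <- E[!jj, , drop = FALSE]
        hit <- matrix(runif(length(gi) * L), length(gi), L) < Eg
        if (any(hit)) {
          v <- mat[!jj, , drop = FALSE]
          v[hit] <- ((v[hit] - 1L + sample.int(3L, sum(hit), replace = TRUE)) %% 4L) + 1L
          mat[!jj, ] <- v
        }
      }
      chars <- matrix(DNA_BASES[mat], m, L)
      seqs[idx] <- do.call(paste0, asplit(chars, 2))
      if (!is.null(profile$qv_model)) {
        Q <- matrix(profile$qv_model(c(E)), m, L)
        quals[idx] <- lapply(seq_len(m), function(i) Q[i, ])
      }
    }

    if (!is.null(profile$adapter_5p) || !is.null(profile$adapter_3p)) {
      a5 <- profile$adapter_5p %||% ""
      a3 <- profile$adapter_3p %||% ""
      gi <- which(!junk)
      seqs[gi] <- paste0(a5, seqs[gi], a3)
      if (!is.null(profile$qv_model)) {
        q5 <- rep(40L, nchar(a5)); q3 <- rep(40L, nchar(a3))
        quals[gi] <- lapply(quals[gi], function(q) c(q5, q, q3))
      }
    }

    tibble(
      id = sprintf("%s_%07d", profile$name, seq_len(n)),
      sequence = seqs,
      quality = quals,
      platform = profile$name,
      is_junk = junk,
      true_start = starts,
      true_strand = ifelse(junk, NA_character_, ifelse(minus, "-", "+"))
    )
  })
}

read_lengths <- function(reads) nchar(reads$sequence)

check_read_set <- function(reads) {
  if (!is.data.frame(reads) || !all(c("id", "sequence") %in% names(reads))) {
    abort("`reads` must be a data frame with at least `id` and `sequence` columns")
  }
  invisible(reads)
}

#' Read and write FASTQ
#'
#' Sanger-style 4-line FASTQ with a declared ASCII offset (default 33).
#' Quality values outside the encodable range for the chosen offset (notably
#' negative Solexa QVs under offset 33) are clamped in the FASTQ and written
#' in full to a sidecar tab-separated file `<path>.qv.tsv`; `read_fastq()`
#' restores them from the sidecar when present. Use `offset = 64` to encode
#' Solexa QVs down to -5 natively.
#'
#' @param reads a read tibble (see [simulate_reads()]).
#' @param path output/input FASTQ path.
#' @param offset ASCII offset for quality encoding.
#' @return `write_fastq()` returns `path` invisibly; `read_fastq()` returns a
#'   read tibble.
#' @export
write_fastq <- function(reads, path, offset = 33L) {
  check_read_set(reads)
  if (is.null(reads$quality) || any(vapply(reads$quality, is.null, logical(1)))) {
    abort("all reads must carry quality values to be written as FASTQ")
  }
  lo <- 33L - offset; hi <- 126L - offset
  clipped <- vapply(reads$quality, function(q) any(q < lo | q > hi), logical(1))
  enc <- vapply(reads$quality, function(q) {
    intToUtf8(pmin(pmax(q, lo), hi) + offset)
  }, character(1))
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$id))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(enc))
  side <- paste0(path, ".qv.tsv")
  if (any(clipped)) {
    qv <- vapply(reads$quality[clipped], paste, character(1), collapse = ",")
    write.table(data.frame(id = reads$id[clipped], qv = qv),
                side, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (file.exists(side)) {
    unlink(side)
  }
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path, offset = 33L) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qual_raw <- as.character(S4Vectors::mcols(x)$qualities)
  quals <- lapply(qual_raw, function(s) utf8ToInt(s) - as.integer(offset))
  ids <- names(x)
  side <- paste0(path, ".qv.tsv")
  if (file.exists(side)) {
    sc <- read.table(side, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    hit <- match(sc$id, ids)
    quals[hit[!is.na(hit)]] <- lapply(sc$qv[!is.na(hit)], function(s) {
      as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
    })
  }
  tibble(id = ids, sequence = unname(as.character(x)), quality = quals,
         platform = NA_character_)
}

#' Read and write FASTA genomes
#'
#' @param genome a `reference_genome`.
#' @param path file path.
#' @return `write_fasta()` returns `path` invisibly; `read_fasta()` returns a
#'   `reference_genome` built from the first record.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "reference_genome"))
  x <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  new_reference_genome(names(x)[1], toupper(as.character(x[[1]])))
}

#' Read and write substitution truth sets
#'
#' Tab-separated with columns chrom, pos (1-based), ref, alt. Internal
#' coordinates are 0-based; the +1 shift happens only at this boundary.
#'
#' @param truth a truth tibble (`position` 0-based, `ref`, `alt`).
#' @param chrom chromosome/sequence name for the output.
#' @param path file path.
#' @export
write_truth <- function(truth, path, chrom = "ref") {
  write.table(
    data.frame(chrom = chrom, pos = truth$position + 1L,
               ref = truth$ref, alt = truth$alt),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  tibble(position = as.integer(x$pos) - 1L, ref = x$ref, alt = x$alt)
}
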