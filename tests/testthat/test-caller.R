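test_that("pileup counts every aligned base in reference orientation and skips N", {
  g <- generate_reference(100, 0.5, seed = 1)
  win <- substr(g$sequence, 11, 46)
  aln <- map_reads(toy_reads(c(win, rc_of(win))), g, 0)
  p <- pileup(aln, g)
  ref_codes <- codes_of(g$sequence)
  for (i in 11:46) expect_equal(unname(p$counts[ref_codes[i], i]), 2L)
  expect_equal(sum(p$counts), 72)
  expect_equal(sum(p$depth), sum(nchar(aln$seq)))
  # masked N bases contribute no count
  ch <- strsplit(win, "")[[1]]; ch[3] <- "N"
  alnN <- map_reads(toy_reads(paste(ch, collapse = "")), g, 3)
  pN <- pileup(alnN, g)
  expect_equal(sum(pN$counts[, 13]), 0L)
  expect_equal(sum(pN$counts), 35)
  tb <- tibble::as_tibble(pN)
  expect_equal(sum(tb$depth), 35)
})

test_that("multinomial observation probability matches closed forms", {
  em <- make_error_matrix(matrix(c(0.7, 0.1, 0.1, 0.1,
                                   0.1, 0.7, 0.1, 0.1,
                                   0.1, 0.1, 0.7, 0.1,
                                   0.1, 0.1, 0.1, 0.7), 4, 4, byrow = TRUE))
  # counts (2,1,0,0) | true A: 3!/(2!1!) * 0.7^2 * 0.1 = 0.147
  expect_equal(observation_log_probability(c(2, 1, 0, 0), em, "A"),
               log(0.147), tolerance = 1e-12)
  # single draw: log p(A|b)
  for (b in BASES) {
    expect_equal(observation_log_probability(c(1, 0, 0, 0), em, b),
                 log(em$prob[b, "A"]), tolerance = 1e-14)
  }
  # zero depth: empty product, log 1 = 0
  expect_equal(observation_log_probability(c(0, 0, 0, 0), em, "A"), 0)
  # structural zero with positive count: -Inf, not an error
  em0 <- make_error_matrix(matrix(c(1, 0, 0, 0,
                                    0.1, 0.7, 0.1, 0.1,
                                    0.1, 0.1, 0.7, 0.1,
                                    0.1, 0.1, 0.1, 0.7), 4, 4, byrow = TRUE))
  expect_identical(observation_log_probability(c(0, 1, 0, 0), em0, "A"), -Inf)
})

test_that("posteriors match the exact-arithmetic oracle on all depth <= 3 count vectors", {
  num <- matrix(c(7, 1, 1, 1,
                  1, 7, 1, 1,
                  1, 1, 7, 1,
                  2, 1, 2, 5), 4, 4, byrow = TRUE)
  em <- make_error_matrix(num / 10)
  for (d in 0:3) {
    for (i in seq_len(nrow(count_vectors_of_depth(d)))) {
      counts <- count_vectors_of_depth(d)[i, ]
      got <- posterior_probs(counts, em)
      want <- posterior_oracle(counts, num, 10)
      expect_equal(unname(got), want, tolerance = 1e-12)
      expect_equal(sum(got), 1, tolerance = 1e-9)
    }
  }
})

test_that("posterior degenerates to the prior for uninformative likelihoods and zero depth", {
  em_flat <- make_error_matrix(matrix(0.25, 4, 4))
  expect_equal(unname(posterior_probs(c(3, 1, 0, 2), em_flat)), rep(0.25, 4))
  em <- make_error_matrix(0.03)
  expect_equal(unname(posterior_probs(c(0, 0, 0, 0), em)), rep(0.25, 4))
  # strong data: posterior concentrates
  post <- posterior_probs(c(5, 0, 0, 0), make_error_matrix(0.03))
  expect_gt(post[["A"]], 0.999)
})

test_that("the multinomial coefficient cancels in the posterior", {
  em <- make_error_matrix(0.02)
  counts <- c(4, 2, 1, 0)
  with_coef <- vapply(BASES, function(b)
    observation_log_probability(counts, em, b, include_coefficient = TRUE),
    numeric(1))
  without <- vapply(BASES, function(b)
    observation_log_probability(counts, em, b, include_coefficient = FALSE),
    numeric(1))
  norm <- function(ll) { w <- exp(ll - max(ll)); w / sum(w) }
  expect_equal(norm(with_coef), norm(without), tolerance = 1e-14)
})

test_that("posterior is monotone in supporting counts under a diagonal-dominant matrix", {
  em <- make_error_matrix(0.05)
  others <- c(1, 2, 0)
  post_G <- vapply(0:12, function(k) {
    posterior_probs(c(others[1], others[2], k, others[3]), em)[["G"]]
  }, numeric(1))
  expect_true(all(diff(post_G) >= 0))
})

test_that("call_position applies the consensus and threshold rules with tie flagging", {
  em <- make_error_matrix(0.03)
  # overwhelming reference support: no substitution
  c1 <- call_position(c(10, 0, 0, 0), em, ref_base = "A")
  expect_false(c1$is_substitution)
  expect_equal(c1$consensus, "A")
  # planted A->G site with 10 clean G reads
  c2 <- call_position(c(0, 0, 10, 0), em, ref_base = "A")
  expect_true(c2$is_substitution)
  expect_equal(c2$consensus, "G")
  expect_gt(c2$consensus_posterior, 1 - 1e-8)
  # exact tie between C and G -> lexicographically smaller base, flagged
  em_sym <- make_error_matrix(matrix(c(0.97, 0.01, 0.01, 0.01,
                                       0.01, 0.485, 0.485, 0.02,
                                       0.01, 0.485, 0.485, 0.02,
                                       0.01, 0.01, 0.01, 0.97), 4, 4,
                                     byrow = TRUE))
  c3 <- call_position(c(0, 2, 2, 0), em_sym, ref_base = "A")
  expect_equal(c3$consensus, "C")
  expect_true(c3$ambiguous)
  # depth 0 is never a substitution even though consensus != ref
  c4 <- call_position(c(0, 0, 0, 0), em, ref_base = "T")
  expect_false(c4$is_substitution)
  expect_error(call_position(c(1, 0, 0, 0), em, "A", threshold = 0), "threshold")
})

test_that("whole-pileup calling agrees with per-position calls and recovers planted sites", {
  g <- insert_repeats(generate_reference(20000, 0.5, seed = 2), 3, 1000, 0,
                      seed = 3)
  pl <- plant_substitutions(g, 40, seed = 4, in_repeats_fraction = 0)
  rd <- simulate_reads(pl$genome, clean_profile(36), 20, seed = 5)
  aln <- map_reads(rd, g, 3, "unique_only")
  em <- estimate_read_probability(aln, g, 1)
  p <- pileup(aln, g)
  calls <- call_substitutions(p, g, em)
  expect_equal(calls$position, pl$truth$position)
  expect_equal(calls$alt, pl$truth$alt)
  expect_true(all(calls$depth > 0))
  # vectorised path matches the scalar path at called and uncalled positions
  ref_codes <- codes_of(g$sequence)
  for (pos in c(calls$position[1:3], setdiff(0:50, calls$position)[1:3])) {
    one <- call_position(p$counts[, pos + 1], em, BASES[ref_codes[pos + 1]])
    expect_equal(one$is_substitution, pos %in% calls$position)
    if (one$is_substitution) {
      row <- calls[calls$position == pos, ]
      expect_equal(one$consensus, row$alt)
      expect_equal(one$consensus_posterior, row$posterior, tolerance = 1e-9)
    }
  }
  # unmutated genome: no calls
  rd0 <- simulate_reads(g, clean_profile(36), 10, seed = 6)
  aln0 <- map_reads(rd0, g, 3, "unique_only")
  em0 <- estimate_read_probability(aln0, g, 1)
  expect_equal(nrow(call_substitutions(pileup(aln0, g), g, em0)), 0)
})

test_that("VCF and TSV exports are valid and 1-based", {
  g <- insert_repeats(generate_reference(8000, 0.5, seed = 7), 2, 500, 0,
                      seed = 7)
  pl <- plant_substitutions(g, 10, seed = 8)
  rd <- simulate_reads(pl$genome, clean_profile(36), 15, seed = 9)
  aln <- map_reads(rd, g, 3, "unique_only")
  em <- estimate_read_probability(aln, g, 1)
  calls <- call_substitutions(pileup(aln, g), g, em)
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(calls, g, vcf)
  parsed <- vcfR::read.vcfR(vcf, verbose = FALSE)
  expect_equal(as.integer(vcfR::getPOS(parsed)), calls$position + 1L)
  expect_equal(vcfR::getREF(parsed), calls$ref)
  expect_equal(vcfR::getALT(parsed), calls$alt)
  tsv <- tempfile(fileext = ".tsv")
  write_calls_tsv(calls, g, tsv)
  back <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(back$pos, calls$position + 1L)
  expect_equal(back$depth, calls$depth)
})
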