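test_that("exact substrings map once with zero mismatches; planted mismatches are located", {
  g <- generate_reference(2000, 0.5, seed = 1)
  win <- substr(g$sequence, 101, 140)
  rd <- toy_reads(win)
  aln <- map_reads(rd, g, 3)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$start, 100)
  expect_equal(aln$strand, "+")
  expect_equal(aln$mismatches, 0)
  # mutate base 5 (offset 4): mismatch offset reported there
  ch <- strsplit(win, "")[[1]]
  ch[5] <- setdiff(BASES, ch[5])[1]
  aln2 <- map_reads(toy_reads(paste(ch, collapse = "")), g, 3)
  expect_equal(aln2$mismatches, 1)
  expect_equal(aln2$mm_offsets[[1]], 4L)
  # its reverse complement maps to the same locus on the minus strand
  aln3 <- map_reads(toy_reads(rc_of(win)), g, 3)
  expect_equal(aln3$start, 100)
  expect_equal(aln3$strand, "-")
  expect_identical(aln3$seq, win)
})

test_that("multi-mapping reads are multiplied under best_all and excluded under unique_only", {
  # genome with an exact duplicated 60 bp block
  g0 <- generate_reference(1500, 0.5, seed = 2)
  block <- substr(g0$sequence, 201, 260)
  seq2 <- paste0(substr(g0$sequence, 1, 800), block,
                 substr(g0$sequence, 861, 1500))
  g <- pileupcall:::new_reference_genome("dup", seq2)
  rd <- toy_reads(substr(block, 10, 45))
  ba <- map_reads(rd, g, 3, "best_all")
  expect_equal(nrow(ba), 2)
  expect_setequal(ba$start, c(209, 809))
  uo <- map_reads(rd, g, 3, "unique_only")
  expect_equal(nrow(uo), 0)
  expect_equal(attr(uo, "multi_count"), 1L)
})

test_that("a unique sub-stratum placement survives unique_only even when worse strata tie", {
  # read matches locus A exactly and locus B with 1 mismatch: min stratum unique
  g0 <- generate_reference(1200, 0.5, seed = 8)
  block <- substr(g0$sequence, 101, 140)
  ch <- strsplit(block, "")[[1]]; ch[20] <- setdiff(BASES, ch[20])[1]
  g <- pileupcall:::new_reference_genome(
    "nearby", paste0(substr(g0$sequence, 1, 600), paste(ch, collapse = ""),
                     substr(g0$sequence, 641, 1200)))
  uo <- map_reads(toy_reads(block), g, 3, "unique_only")
  expect_equal(nrow(uo), 1)
  expect_equal(uo$start, 100)
  expect_equal(uo$mismatches, 0)
})

test_that("mapping equals the exhaustive-offset oracle on random genomes and reads", {
  set.seed(101)
  for (rep in 1:5) {
    g <- generate_reference(1000, 0.5, seed = 200 + rep)
    # reads: exact windows, mutated windows, reverse complements, junk
    starts <- sample(900, 20)
    wins <- substring(g$sequence, starts, starts + 35)
    mut <- vapply(wins, function(w) {
      ch <- strsplit(w, "")[[1]]
      k <- sample(36, sample(0:4, 1))
      for (p in k) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
      paste(ch, collapse = "")
    }, character(1))
    junk <- replicate(10, paste(sample(BASES, 36, TRUE), collapse = ""))
    rcs <- vapply(wins[1:5], rc_of, character(1))
    rd <- toy_reads(unname(c(wins, mut, rcs, junk)))
    for (policy in c("best_all", "unique_only")) {
      got <- aln_key(map_reads(rd, g, 3, policy))
      want <- oracle_map(rd, g, 3, policy)
      expect_equal(got, want, ignore_attr = TRUE)
    }
  }
})

test_that("mapped-read count is non-decreasing in the mismatch budget", {
  g <- generate_reference(3000, 0.5, seed = 4)
  rd <- simulate_reads(g, platform_profile("noisy", 36,
    error_rate = function(k, L) rep(0.04, length(k))), 3, seed = 5)
  n_mapped <- vapply(0:4, function(mm) {
    length(unique(map_reads(rd, g, mm)$read_id))
  }, numeric(1))
  expect_true(all(diff(n_mapped) >= 0))
})

test_that("strand symmetry: mapping reverse-complemented reads mirrors placements", {
  g <- generate_reference(2000, 0.5, seed = 6)
  rd <- simulate_reads(g, clean_profile(36), 2, seed = 7)
  fwd <- aln_key(map_reads(rd, g, 1))
  rc <- rd
  rc$sequence <- vapply(rd$sequence, rc_of, character(1), USE.NAMES = FALSE)
  rev <- aln_key(map_reads(rc, g, 1))
  expect_equal(fwd$start, rev$start)
  expect_equal(fwd$mismatches, rev$mismatches)
  expect_true(all(fwd$strand != rev$strand))
})

test_that("reads longer than the reference are unmapped with a warning", {
  g <- generate_reference(30, 0.5, seed = 1)
  rd <- toy_reads(strrep("A", 50))
  expect_warning(aln <- map_reads(rd, g, 3), "longer than the reference")
  expect_equal(nrow(aln), 0)
  expect_equal(attr(aln, "unmapped_count"), 1L)
})

test_that("SAM round trip reproduces the alignment set with recomputed mismatches", {
  g <- generate_reference(3000, 0.5, seed = 9, name = "ref")
  rd <- simulate_reads(g, platform_profile("e1", 36,
    error_rate = function(k, L) rep(0.01, length(k))), 4, seed = 10)
  aln <- map_reads(rd, g, 3, "best_all")
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, sam)
  back <- import_sam(sam, g, 3, "best_all")
  expect_equal(aln_key(back), aln_key(aln))
  expect_equal(attr(back, "dropped_count"), 0L)
  # recomputed mismatch offsets agree with direct comparison
  o <- order(back$read_id, back$start)
  o0 <- order(aln$read_id, aln$start)
  expect_identical(back$mm_offsets[o], aln$mm_offsets[o0])
  # unique_only on import applies the same exclusion
  back_u <- import_sam(sam, g, 3, "unique_only")
  expect_equal(aln_key(back_u), aln_key(map_reads(rd, g, 3, "unique_only")))
})

test_that("SAM records with indels are dropped and counted", {
  g <- generate_reference(200, 0.5, seed = 11, name = "ref")
  win <- substr(g$sequence, 11, 46)
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    sprintf("@SQ\tSN:ref\tLN:%d", g$length),
    sprintf("r1\t0\tref\t11\t255\t36M\t*\t0\t0\t%s\t*", win),
    sprintf("r2\t0\tref\t11\t255\t10M2I24M\t*\t0\t0\t%s\t*", win),
    sprintf("r3\t0\tref\t11\t255\t10M1D26M\t*\t0\t0\t%s\t*", win)
  ), sam)
  aln <- import_sam(sam, g, 3)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$read_id, "r1")
  expect_equal(attr(aln, "dropped_count"), 2L)
})
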