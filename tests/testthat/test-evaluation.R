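test_that("call classification matches set arithmetic and splits uncovered FNs", {
  depth <- c(rep(2L, 150), rep(0L, 150), rep(3L, 100))
  truth <- tibble::tibble(position = c(100L, 200L, 320L),
                          ref = c("A", "C", "G"), alt = c("G", "T", "A"))
  calls <- tibble::tibble(position = c(100L, 340L), ref = c("A", "T"),
                          alt = c("G", "C"))
  res <- classify_calls(calls, truth, depth)
  expect_equal(res$TP, 1L)
  expect_equal(res$FP, 1L)
  expect_equal(res$FN, 2L)
  expect_equal(res$FN_uncovered, 1L)  # position 200 has depth 0
  expect_equal(res$TP + res$FN, nrow(truth))
  expect_equal(res$mean_coverage, sum(depth) / length(depth))
  # a wrong-alt call at a true position is FP + FN, not TP
  wrong <- tibble::tibble(position = 100L, ref = "A", alt = "T")
  res2 <- classify_calls(wrong, truth, depth)
  expect_equal(res2$TP, 0L)
  expect_equal(res2$FP, 1L)
  expect_equal(res2$FN, 3L)
  # empty calls, empty truth: all zeros
  none <- classify_calls(calls[0, ], truth[0, ], depth)
  expect_true(all(c(none$TP, none$FP, none$FN, none$FN_uncovered) == 0))
  expect_error(classify_calls(tibble::tibble(position = 999L, alt = "A"),
                              truth, depth), "range")
})

test_that("subsampling draws the exact count, deterministically under a seed", {
  rd <- toy_reads(replicate(1000, paste(sample(BASES, 10, TRUE), collapse = "")))
  half <- subsample_reads(rd, 1 / 2, seed = 1)
  expect_equal(nrow(half), 500)
  expect_identical(half, subsample_reads(rd, 1 / 2, seed = 1))
  expect_false(identical(half$id, subsample_reads(rd, 1 / 2, seed = 2)$id))
  expect_true(all(half$id %in% rd$id))
  expect_false(any(duplicated(half$id)))
  full <- subsample_reads(rd, 1, seed = 3)
  expect_identical(sort(full$id), sort(rd$id))
  expect_error(subsample_reads(rd, 0, seed = 1), "fraction")
  expect_error(subsample_reads(rd, 1.2, seed = 1), "fraction")
})

test_that("saturation experiment rows are consistent and TP rises with coverage", {
  g <- insert_repeats(generate_reference(15000, 0.508, seed = 10), 3, 800, 0,
                      seed = 10)
  pl <- plant_substitutions(g, 60, seed = 11, in_repeats_fraction = 0.1)
  rd <- simulate_reads(pl$genome, platform_profile("e05", 36,
    error_rate = function(k, L) rep(0.005, length(k))), 25, seed = 12)
  st <- saturation_experiment(rd, g, pl$truth,
                              fractions = c(1/16, 1/4, 1), seeds = 1:2)
  expect_equal(nrow(st), 6)
  expect_true(all(st$TP + st$FN == nrow(pl$truth)))
  expect_true(all(st$FN_uncovered <= st$FN))
  # coverage scales roughly with fraction
  expect_true(all(diff(tapply(st$mean_coverage, st$fraction, mean)) > 0))
  # detection increases with coverage (rank correlation over all rows)
  expect_gt(cor(st$mean_coverage, st$TP, method = "spearman"), 0)
  # the identical chain at fraction 1 reproduces a direct full-data evaluation
  aln <- map_reads(rd, g, 3, "unique_only")
  em <- estimate_read_probability(aln, g, 1)
  full <- classify_calls(call_substitutions(pileup(aln, g), g, em),
                         pl$truth, depth_and_uncovered(aln, g))
  one <- st[st$fraction == 1, ][1, ]
  expect_equal(one$TP, full$TP)
  expect_equal(one$FP, full$FP)
  expect_equal(one$mean_coverage, full$mean_coverage)
})

test_that("saturation fit recovers generating parameters and handles degenerate input", {
  n <- c(2, 4, 8, 16, 32, 64)
  # self-consistency on a noiseless curve
  f <- fit_saturation(tibble::tibble(n = n, TP = 259 * (1 - 0.8 * n^-1.2)))
  expect_equal(f$T_total, 259, tolerance = 1e-6)
  expect_equal(f$A, 0.8, tolerance = 1e-6)
  expect_equal(f$B, 1.2, tolerance = 1e-6)
  # fitted curve at the inputs beats or ties the generating parameters
  expect_lte(f$residual, sum((predict(f, n) - 259 * (1 - 0.8 * n^-1.2))^2) + 1e-12)
  # grid recovery within 1e-4 relative error
  for (T in c(100, 259)) for (A in c(0.3, 0.8)) for (B in c(0.5, 2)) {
    fg <- fit_saturation(tibble::tibble(n = n, TP = T * (1 - A * n^-B)))
    expect_lt(max(abs(c(fg$T_total - T, fg$A - A, fg$B - B) / c(T, A, B))), 1e-4)
  }
  # constant TP: A pinned to 0, B undefined, curve constant
  fd <- fit_saturation(tibble::tibble(n = n, TP = rep(42, 6)))
  expect_true(fd$degenerate)
  expect_equal(fd$A, 0)
  expect_true(is.na(fd$B))
  expect_equal(predict(fd, c(1, 10)), c(42, 42))
  # T_fixed variant
  ff <- fit_saturation(tibble::tibble(n = n, TP = 100 * (1 - 0.5 * n^-1)),
                       T_fixed = 100)
  expect_equal(ff$A, 0.5, tolerance = 1e-6)
  expect_equal(ff$B, 1, tolerance = 1e-6)
  expect_error(fit_saturation(tibble::tibble(n = c(1, 2), TP = c(1, 2))),
               "3 distinct")
  # bounded parameters keep the fitted curve monotone even on noisy input
  set.seed(13)
  noisy <- tibble::tibble(n = n, TP = pmax(0, 200 * (1 - 0.9 * n^-0.8) +
                                             rnorm(6, 0, 8)))
  fn <- fit_saturation(noisy)
  grid <- seq(1, 100, by = 0.5)
  expect_true(all(diff(predict(fn, grid)) >= 0))
  # broom-style accessors
  expect_equal(tidy(f)$term, c("T_total", "A", "B"))
  expect_equal(glance(f)$nobs, 6)
})
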