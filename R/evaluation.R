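#' Score substitution calls against a truth set
#'
#' A call is a true positive only when both position and alternative base
#' match the truth (a wrong-alt call at a true position counts as a false
#' positive and leaves the truth entry a false negative). False negatives at
#' depth-0 positions are reported separately as `FN_uncovered`.
#'
#' @param calls a call tibble ([call_substitutions()]).
#' @param truth a truth tibble (`position` 0-based, `ref`, `alt`).
#' @param depth a [depth_and_uncovered()] `depth_track` (or an integer depth
#'   vector) on the same reference.
#' @return One-row tibble: `mean_coverage`, `TP`, `FP`, `FN`, `FN_uncovered`.
#' @export
classify_calls <- function(calls, truth, depth) {
  dvec <- if (inherits(depth, "depth_track")) depth$depth else as.integer(depth)
  G <- length(dvec)
  if (any(calls$position < 0 | calls$position >= G) ||
      any(truth$position < 0 | truth$position >= G)) {
    abort("call/truth positions out of range for the supplied depth track")
  }
  key_call <- paste(calls$position, calls$alt)
  key_truth <- paste(truth$position, truth$alt)
  tp <- sum(key_call %in% key_truth)
  fp <- nrow(calls) - tp
  fn_pos <- truth$position[!(key_truth %in% key_call)]
  tibble(
    mean_coverage = sum(as.numeric(dvec)) / G,
    TP = as.integer(tp), FP = as.integer(fp),
    FN = length(fn_pos),
    FN_uncovered = sum(dvec[fn_pos + 1L] == 0L)
  )
}

#' Randomly subsample reads without replacement
#'
#' Draws `floor(fraction * n)` reads uniformly; deterministic under a fixed
#' seed.
#'
#' @param reads a read tibble.
#' @param fraction fraction in `(0, 1]`.
#' @param seed optional integer seed.
#' @export
subsample_reads <- function(reads, fraction, seed = NULL) {
  check_read_set(reads)
  check_fraction(fraction, "fraction", closed_low = FALSE)
  n <- nrow(reads)
  k <- floor(fraction * n)
  with_seed_if(seed, reads[sort(sample.int(n, k)), , drop = FALSE])
}

#' Coverage-subsampling detection experiment
#'
#' For each fraction of the default twofold ladder 1/32 ... 1/2 (and each
#' seed), reruns the identical calling chain on the subsample: unique-only
#' mapping, error-matrix re-estimation within the subsample, pileup, Bayesian
#' consensus calling, and scoring against the truth. Mean coverage is
#' recomputed from the subsample's own depth track.
#'
#' @param reads the full (preprocessed) read tibble.
#' @param genome the calling reference.
#' @param truth the substitution truth set.
#' @param fractions subsampling fractions.
#' @param seeds one or more integer seeds per fraction.
#' @param max_mismatch mapping mismatch budget.
#' @param pseudocount error-matrix smoothing.
#' @param threshold consensus posterior threshold.
#' @return A tibble with one row per (fraction, seed): `fraction`, `seed`,
#'   `mean_coverage`, `TP`, `FP`, `FN`, `FN_uncovered`.
#' @export
saturation_experiment <- function(reads, genome, truth,
                                  fractions = c(1/32, 1/16, 1/8, 1/4, 1/2),
                                  seeds = 1:3, max_mismatch = 3L,
                                  pseudocount = 1, threshold = 1e-8) {
  grid <- tidyr::expand_grid(fraction = fractions, seed = seeds)
  purrr::pmap_dfr(grid, function(fraction, seed) {
    sub <- subsample_reads(reads, fraction, seed = seed)
    aln <- map_reads(sub, genome, max_mismatch = max_mismatch,
                     policy = "unique_only")
    dt <- depth_and_uncovered(aln, genome)
    res <- if (nrow(aln) == 0) {
      tibble(mean_coverage = 0, TP = 0L, FP = 0L, FN = nrow(truth),
             FN_uncovered = nrow(truth))
    } else {
      em <- estimate_read_probability(aln, genome, pseudocount = pseudocount)
      calls <- call_substitutions(pileup(aln, genome), genome, em,
                                  threshold = threshold)
      classify_calls(calls, truth, dt)
    }
    dplyr::bind_cols(tibble(fraction = fraction, seed = seed), res)
  })
}

#' Fit the power-law detection saturation model
#'
#' Least-squares fit of `TP(n) = T (1 - A n^-B)` to (coverage, TP) points,
#' the assumption being that the fraction of undetected substitutions decays
#' as a power of the mean coverage `n`. Parameters are bounded
#' (`T >= max(TP)`, `A >= 0`, `B >= 0`) so the fitted curve is non-decreasing,
#' and the Levenberg-Marquardt optimisation is multi-started over
#' `B in {0.5, 1, 2}` with the best residual kept.
#'
#' @param points a data frame with columns `n` (mean coverage) and `TP`, or a
#'   numeric vector `n` together with `TP`.
#' @param TP optional numeric vector when `points` is a vector of coverages.
#' @param T_fixed optional known asymptote; when given only `A` and `B` are
#'   fitted.
#' @return A `saturation_fit` with elements `T_total`, `A`, `B`, `residual`
#'   (sum of squared errors), `converged`, `degenerate`, and the data.
#' @export
fit_saturation <- function(points, TP = NULL, T_fixed = NULL) {
  if (!is.data.frame(points)) points <- tibble(n = points, TP = TP)
  stopifnot(all(c("n", "TP") %in% names(points)))
  points <- points[order(points$n), , drop = FALSE]
  if (length(unique(points$n)) < 3) abort("need >= 3 distinct coverage values")
  if (any(points$TP < 0) || any(points$n <= 0)) {
    abort("coverages must be positive and TP counts non-negative")
  }
  tp_max <- max(points$TP)
  if (is.null(T_fixed) && length(unique(points$TP)) == 1) {
    return(new_saturation_fit(tp_max, 0, NA_real_, residual = 0,
                              converged = TRUE, degenerate = TRUE,
                              data = points, T_fixed = FALSE))
  }
  best <- NULL
  for (B0 in c(0.5, 1, 2)) {
    fit <- tryCatch({
      if (is.null(T_fixed)) {
        minpack.lm::nlsLM(
          TP ~ Tt * (1 - A * n^(-B)), data = points,
          start = list(Tt = tp_max * 1.05 + 1e-6, A = 0.5, B = B0),
          lower = c(Tt = tp_max, A = 0, B = 0),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      } else {
        minpack.lm::nlsLM(
          TP ~ T_fixed * (1 - A * n^(-B)), data = points,
          start = list(A = 0.5, B = B0), lower = c(A = 0, B = 0),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) abort("saturation fit failed to converge from any start")
  cf <- coef(best$fit)
  new_saturation_fit(
    T_total = if (is.null(T_fixed)) cf[["Tt"]] else T_fixed,
    A = cf[["A"]], B = cf[["B"]], residual = best$rss,
    converged = best$fit$convInfo$isConv %||% TRUE, degenerate = FALSE,
    data = points, T_fixed = !is.null(T_fixed))
}

new_saturation_fit <- function(T_total, A, B, residual, converged, degenerate,
                               data, T_fixed) {
  structure(list(T_total = T_total, A = A, B = B, residual = residual,
                 converged = converged, degenerate = degenerate, data = data,
                 T_fixed = T_fixed),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("<saturation_fit> TP(n) = T (1 - A n^-B)\n")
  cat(sprintf("  T = %.4g%s, A = %.4g, B = %s, SSE = %.4g\n",
              x$T_total, if (x$T_fixed) " (fixed)" else "", x$A,
              if (is.na(x$B)) "undefined (constant TP)" else sprintf("%.4g", x$B),
              x$residual))
  invisible(x)
}

#' @export
predict.saturation_fit <- function(object, n = object$data$n, ...) {
  if (is.na(object$B)) return(rep(object$T_total, length(n)))
  object$T_total * (1 - object$A * n^(-object$B))
}

#' @export
tidy.saturation_fit <- function(x, ...) {
  tibble(term = c("T_total", "A", "B"),
         estimate = c(x$T_total, x$A, x$B))
}

#' @export
glance.saturation_fit <- function(x, ...) {
  tibble(residual = x$residual, converged = x$converged,
         degenerate = x$degenerate, nobs = nrow(x$data))
}
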