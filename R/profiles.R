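#' Platform read profiles
#'
#' A platform profile bundles the knobs that distinguish the three emulated
#' sequencing chemistries: the read-length model, a per-cycle substitution
#' error rate, the fraction of unmappable "junk" reads, an integer
#' quality-value (QV) model, optional adapters, and an optional tail
#' signal-decay component. Error rates and junk fractions are calibrated
#' qualitatively (mapped-read ratios, per-base accuracy, and the rising 3'
#' mismatch profile of GA-style data); none of the upstream instruments
#' publishes a quantitative ramp.
#'
#' `qv_model` maps the per-base error probability actually used during
#' simulation to a reported integer QV on the Solexa odds scale
#' `QV = -10 log10(e / (1 - e))` plus Gaussian reporting noise; error
#' probabilities above 0.5 therefore yield negative QVs, which is what makes
#' a "trim QV < 0" policy meaningful.
#'
#' @param name profile name (tags the reads).
#' @param read_length fixed read length in bases, or mean length when
#'   `length_sd > 0`.
#' @param length_sd standard deviation of read length (0 = fixed length).
#' @param error_rate function(position, read_length) -> substitution error
#'   probability in `[0, 1]` per read position (sequencing cycle).
#' @param junk_fraction fraction of reads drawn as uniform random sequence.
#' @param qv_model function(error_prob_vector) -> integer QVs (may be
#'   negative); `NULL` suppresses quality values.
#' @param adapter_5p,adapter_3p optional adapter sequences attached verbatim
#'   to each non-junk read.
#' @param tail_decay_fraction fraction of reads whose signal decays at a
#'   random cycle in the final third of the read.
#' @param decay_error per-base error probability after the decay point.
#' @return A `platform_profile` object.
#' @export
platform_profile <- function(name, read_length, length_sd = 0,
                             error_rate = function(k, L) rep(0, length(k)),
                             junk_fraction = 0,
                             qv_model = qv_solexa_model(),
                             adapter_5p = NULL, adapter_3p = NULL,
                             tail_decay_fraction = 0, decay_error = 0.55) {
  check_fraction(junk_fraction, "junk_fraction")
  check_fraction(tail_decay_fraction, "tail_decay_fraction")
  if (read_length < 1) abort("`read_length` must be >= 1")
  e <- error_rate(seq_len(as.integer(read_length)), as.integer(read_length))
  if (any(e < 0 | e > 1)) abort("`error_rate` must return probabilities in [0, 1]")
  structure(
    list(name = name, read_length = read_length, length_sd = length_sd,
         error_rate = error_rate, junk_fraction = junk_fraction,
         qv_model = qv_model, adapter_5p = adapter_5p, adapter_3p = adapter_3p,
         tail_decay_fraction = tail_decay_fraction, decay_error = decay_error),
    class = "platform_profile"
  )
}

#' @export
print.platform_profile <- function(x, ...) {
  len <- if (x$length_sd > 0) sprintf("%g +/- %g bp", x$read_length, x$length_sd)
         else sprintf("%d bp", as.integer(x$read_length))
  cat(sprintf("<platform_profile> %s: %s, junk %.0f%%\n", x$name, len,
              100 * x$junk_fraction))
  invisible(x)
}

#' Solexa-scale quality value model
#'
#' @param noise_sd standard deviation of the Gaussian reporting noise added to
#'   the true Solexa-scale QV before rounding.
#' @param qv_range clamp range for emitted QVs.
#' @return function(error_probs) -> integer QVs.
#' @export
qv_solexa_model <- function(noise_sd = 2, qv_range = c(-5L, 40L)) {
  force(noise_sd); force(qv_range)
  function(e) {
    e <- pmin(pmax(e, 1e-5), 1 - 1e-5)
    q <- -10 * log10(e / (1 - e)) + rnorm(length(e), 0, noise_sd)
    as.integer(pmin(pmax(round(q), qv_range[1]), qv_range[2]))
  }
}

#' Built-in platform profiles
#'
#' Three presets emulating the platform behaviours compared in this package:
#' * `profile_flx()` — long reads (mean 240 bp insert + 10 bp adapters at both
#'   ends, so ~260 bp total), high per-base accuracy (0.1% flat error), 10%
#'   junk.
#' * `profile_ga()` — 36 bp reads with a per-cycle error ramp from 0.2% at
#'   cycle 1 to 8% at cycle 36, 15% of reads with tail signal decay (which
#'   produces negative Solexa QVs), 25% junk.
#' * `profile_solid()` — 25 or 50 bp reads, 0.2% flat error, about half of
#'   all reads junk.
#'
#' @param read_length read length override (SOLiD: 25 or 50).
#' @return A `platform_profile`.
#' @name builtin_profiles
NULL

#' @rdname builtin_profiles
#' @export
profile_flx <- function() {
  platform_profile(
    name = "FLX", read_length = 240, length_sd = 40,
    error_rate = function(k, L) rep(0.001, length(k)),
    junk_fraction = 0.10,
    adapter_5p = "GCCTCCCTCG", adapter_3p = "CGAGGGAGGC"
  )
}

#' @rdname builtin_profiles
#' @export
profile_ga <- function() {
  platform_profile(
    name = "GA", read_length = 36,
    error_rate = function(k, L) 0.002 + (0.08 - 0.002) * (k - 1) / pmax(L - 1, 1),
    junk_fraction = 0.25,
    tail_decay_fraction = 0.15
  )
}

#' @rdname builtin_profiles
#' @export
profile_solid <- function(read_length = 50) {
  if (!read_length %in% c(25, 50)) abort("SOLiD-like read_length must be 25 or 50")
  platform_profile(
    name = paste0("SOLiD", read_length), read_length = read_length,
    error_rate = function(k, L) rep(0.002, length(k)),
    junk_fraction = 0.5
  )
}

#' Look up a built-in profile by name
#' @param name one of "flx", "ga", "solid25", "solid50".
#' @return A `platform_profile`.
#' @export
get_profile <- function(name) {
  switch(tolower(name),
    flx = profile_flx(),
    ga = profile_ga(),
    solid25 = profile_solid(25),
    solid50 = , solid = profile_solid(50),
    abort(sprintf("unknown profile '%s' (use flx, ga, solid25 or solid50)", name))
  )
}
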