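#' Reference run volumes for the emulated platform configurations
#'
#' Published per-run data volumes for the three platform configurations the
#' built-in profiles emulate: one FLX run (mean read length including
#' adapters), one GA fragment run, and three SOLiD libraries (25-base mate
#' pair, and the summed 50-base mate-pair and fragment replicates).
#' `redundancy` is total bases over the ~4.6 Mb *E. coli* genome. These
#' volumes calibrate the simulator's data-volume regimes and provide the
#' arithmetic self-check in [run_volume_totals()].
#'
#' @return A tibble with `method`, `read_length`, `n_reads`, `total_bases`,
#'   `redundancy`, and `fixed_length` (whether `read_length` is exact rather
#'   than a mean).
#' @export
platform_run_volumes <- function() {
  tibble(
    method = c("FLX", "GA", "SOLiD M25", "SOLiD M50", "SOLiD F50"),
    read_length = c(260.7, 36, 25, 50, 50),
    n_reads = c(475819, 9624599, 125399243, 226945098, 100015475),
    total_bases = c(124042803, 346485564, 3134981075, 11347254900, 5000773750),
    redundancy = c(26.8, 75, 678.4, 2455.4, 1082.1),
    fixed_length = c(FALSE, TRUE, TRUE, TRUE, TRUE)
  )
}

#' Check run-volume arithmetic
#'
#' For every fixed-length data set, recomputes `read_length * n_reads` and
#' compares it with the reported total base count (exact integer equality is
#' expected).
#'
#' @param volumes a run-volume tibble, by default [platform_run_volumes()].
#' @return The tibble restricted to fixed-length rows, with `computed_total`
#'   and logical `exact_match` columns added.
#' @export
run_volume_totals <- function(volumes = platform_run_volumes()) {
  v <- volumes[volumes$fixed_length, , drop = FALSE]
  v$computed_total <- v$read_length * v$n_reads
  v$exact_match <- v$computed_total == v$total_bases
  v
}
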