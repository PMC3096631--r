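#' Pipeline configuration
#'
#' Builds and validates the single configuration object consumed by
#' [run_pipeline()]. Unknown keys are rejected; omitted keys take the defaults
#' below (the calling defaults — mismatch budget 3, QV threshold 0, minimum
#' length 32, pseudocount 1, posterior threshold 1e-8 — are the method's
#' reference parameter set).
#'
#' @param ... configuration keys: `genome_length`, `gc_content`,
#'   `n_substitutions`, `repeat_copies`, `repeat_unit_length`,
#'   `repeat_divergence`, `in_repeats_fraction`, `profiles` (character vector
#'   of built-in profile names), `mean_coverage` (single value or named per
#'   profile), `max_mismatch`, `qv_threshold`, `min_length`, `trim_mode`,
#'   `pseudocount`, `threshold`, `fractions`, `subsample_seeds`, `seed`,
#'   `run_saturation`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  validate_config(list(...))
}

config_defaults <- function() {
  list(
    genome_length = 5e4, gc_content = 0.508,
    n_substitutions = 259L, repeat_copies = 7L, repeat_unit_length = 2000L,
    repeat_divergence = 0, in_repeats_fraction = 12 / 259,
    profiles = c("flx", "ga", "solid50"),
    mean_coverage = 20,
    max_mismatch = 3L, qv_threshold = 0L, min_length = 32L,
    trim_mode = "three_prime_run",
    pseudocount = 1, threshold = 1e-8,
    fractions = c(1/32, 1/16, 1/8, 1/4, 1/2), subsample_seeds = 1:3,
    seed = 1L, run_saturation = TRUE
  )
}

#' Validate a pipeline configuration
#'
#' Checks every parameter against its documented domain, rejects unknown
#' keys, injects defaults for omitted ones, and reports all problems at once.
#'
#' @param config a named list of configuration values.
#' @return The completed configuration (class `pipeline_config`), or an error
#'   aggregating every violated constraint.
#' @export
validate_config <- function(config) {
  defaults <- config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  errors <- character(0)
  if (length(unknown) > 0) {
    errors <- c(errors, sprintf("unknown key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, config[setdiff(names(config), unknown)])
  chk <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  chk(is.numeric(cfg$genome_length) && cfg$genome_length > 0,
      "genome_length must be > 0")
  chk(is.numeric(cfg$gc_content) && cfg$gc_content > 0 && cfg$gc_content < 1,
      "gc_content must be in (0, 1)")
  chk(cfg$n_substitutions >= 0, "n_substitutions must be >= 0")
  chk(cfg$repeat_copies >= 2, "repeat_copies must be >= 2")
  chk(cfg$repeat_copies * cfg$repeat_unit_length < cfg$genome_length,
      "repeat units must fit inside the genome")
  chk(cfg$repeat_divergence >= 0 && cfg$repeat_divergence <= 1,
      "repeat_divergence must be in [0, 1]")
  chk(cfg$in_repeats_fraction >= 0 && cfg$in_repeats_fraction <= 1,
      "in_repeats_fraction must be in [0, 1]")
  chk(all(vapply(cfg$profiles, function(p)
        !inherits(tryCatch(get_profile(p), error = function(e) e), "error"),
        logical(1))),
      "profiles must name built-in profiles (flx, ga, solid25, solid50)")
  chk(all(cfg$mean_coverage > 0), "mean_coverage must be > 0")
  chk(cfg$max_mismatch >= 0, "max_mismatch must be >= 0")
  chk(cfg$min_length >= 1, "min_length must be >= 1")
  chk(cfg$trim_mode %in% c("three_prime_run", "per_base_mask"),
      "trim_mode must be three_prime_run or per_base_mask")
  chk(cfg$pseudocount >= 0, "pseudocount must be >= 0")
  chk(cfg$threshold > 0 && cfg$threshold <= 1, "threshold must be in (0, 1]")
  chk(all(cfg$fractions > 0 & cfg$fractions <= 1),
      "fractions must be in (0, 1]")
  if (length(errors) > 0) {
    abort(paste0("invalid configuration:\n", paste("-", errors, collapse = "\n")))
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full comparison pipeline on synthetic data
#'
#' End-to-end chain: generate the reference (with repeat units), plant
#' substitutions, simulate reads per platform profile, trim/filter, map
#' (best-stratum for the quality comparison, unique-only for calling),
#' compute mapping statistics and uncovered-region GC analysis, estimate the
#' error matrix, call substitutions, score against the planted truth, and
#' optionally run the coverage-subsampling saturation experiment with a
#' power-law fit per profile.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, report tables (TSV), calls
#'   (VCF), uncovered intervals (BED) and a YAML manifest of all parameters
#'   and seeds are written there.
#' @param quiet suppress progress messages.
#' @return A report bundle (list): `genome`, `truth`, `mapping_summary`
#'   (mapped ratio / accuracy / coverage per profile), `uncovered_summary`,
#'   `evaluation` (TP/FP/FN per profile), `error_profiles` (mismatch-by-cycle
#'   per profile), `saturation` (experiment table) and `saturation_fits`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         quiet = FALSE) {
  config <- validate_config(unclass(config))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  seed <- as.integer(config$seed)

  say("[simulate] genome %d bp, %d substitutions, %d repeat copies x %d bp",
      as.integer(config$genome_length), config$n_substitutions,
      config$repeat_copies, as.integer(config$repeat_unit_length))
  ref <- generate_reference(config$genome_length, config$gc_content,
                            seed = seed)
  ref <- insert_repeats(ref, config$repeat_copies, config$repeat_unit_length,
                        config$repeat_divergence, seed = seed + 1L)
  planted <- plant_substitutions(ref, config$n_substitutions, seed = seed + 2L,
                                 in_repeats_fraction = config$in_repeats_fraction)
  sample_genome <- planted$genome
  truth <- planted$truth

  coverage_of <- function(p) {
    cv <- config$mean_coverage
    if (!is.null(names(cv)) && p %in% names(cv)) cv[[p]] else cv[[1]]
  }

  mapping_rows <- list(); uncov_sets <- list(); eval_rows <- list()
  profiles_tbl <- list(); sat_rows <- list(); sat_fits <- list()
  calls_by_profile <- list()

  for (pname in config$profiles) {
    prof <- get_profile(pname)
    cv <- coverage_of(pname)
    say("[%s] simulating %gx reads", prof$name, cv)
    reads <- simulate_reads(sample_genome, prof, cv, seed = seed + 10L)
    n_raw <- nrow(reads)
    if (!is.null(prof$adapter_5p) || !is.null(prof$adapter_3p)) {
      reads <- strip_adapters(reads, c(prof$adapter_5p, prof$adapter_3p))
    }
    pol <- trim_policy(config$qv_threshold, config$min_length, config$trim_mode)
    reads <- trim_by_quality(reads, pol)
    reads <- filter_short(reads, config$min_length)
    say("[%s] preprocess: %d reads in, %d kept", prof$name, n_raw, nrow(reads))

    aln_all <- map_reads(reads, ref, config$max_mismatch, policy = "best_all")
    dt <- depth_and_uncovered(aln_all, ref)
    mapping_rows[[pname]] <- tibble(
      profile = prof$name,
      reads_total = nrow(reads),
      mapped_ratio_pct = mapped_ratio(aln_all, reads),
      accuracy_pct = per_base_accuracy(aln_all, ref),
      mean_coverage = dt$mean_coverage,
      uncovered_bases = length(dt$uncovered)
    )
    uncov_sets[[pname]] <- dt$uncovered
    profiles_tbl[[pname]] <- dplyr::mutate(mismatch_by_position(aln_all, ref),
                                           profile = prof$name)

    say("[%s] calling (unique-only mapping, pseudocount %g, threshold %g)",
        prof$name, config$pseudocount, config$threshold)
    aln_u <- map_reads(reads, ref, config$max_mismatch, policy = "unique_only")
    dt_u <- depth_and_uncovered(aln_u, ref)
    em <- estimate_read_probability(aln_u, ref, config$pseudocount)
    calls <- call_substitutions(pileup(aln_u, ref), ref, em, config$threshold)
    calls_by_profile[[pname]] <- calls
    eval_rows[[pname]] <- dplyr::bind_cols(
      tibble(profile = prof$name), classify_calls(calls, truth, dt_u))

    if (isTRUE(config$run_saturation)) {
      say("[%s] saturation experiment: fractions %s x %d seed(s)", prof$name,
          paste(signif(config$fractions, 3), collapse = ","),
          length(config$subsample_seeds))
      st <- saturation_experiment(reads, ref, truth, config$fractions,
                                  config$subsample_seeds, config$max_mismatch,
                                  config$pseudocount, config$threshold)
      st$profile <- prof$name
      sat_rows[[pname]] <- st
      pts <- tibble(n = st$mean_coverage, TP = st$TP)
      full_pt <- tibble(n = dt_u$mean_coverage, TP = eval_rows[[pname]]$TP)
      sat_fits[[pname]] <- tryCatch(
        fit_saturation(dplyr::bind_rows(pts, full_pt)),
        error = function(e) NULL)
    }
  }

  mapping_summary <- dplyr::bind_rows(mapping_rows)
  uncovered_summary <- NULL
  if (length(uncov_sets) >= 2) {
    uncommon <- uncommon_uncovered(uncov_sets)
    uncovered_summary <- tibble(
      profile = mapping_summary$profile,
      uncovered = vapply(uncov_sets, length, integer(1)),
      uncovered_uncommon = vapply(uncommon, length, integer(1)),
      gc_pct = vapply(uncommon, function(p) {
        if (length(p) == 0) NA_real_ else gc_of_positions(p, ref)
      }, numeric(1)),
      genome_gc_pct = 100 * gc_content(ref)
    )
  }
  bundle <- list(
    config = config, genome = ref, sample_genome = sample_genome, truth = truth,
    mapping_summary = mapping_summary,
    uncovered_summary = uncovered_summary,
    error_profiles = dplyr::bind_rows(profiles_tbl),
    evaluation = dplyr::bind_rows(eval_rows),
    calls = calls_by_profile,
    saturation = if (length(sat_rows)) dplyr::bind_rows(sat_rows) else NULL,
    saturation_fits = sat_fits,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  if (!is.null(outdir)) write_report_bundle(bundle, outdir)
  say("[done] %.1f s", bundle$elapsed_sec)
  bundle
}

write_report_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(x, f) if (!is.null(x)) {
    write.table(x, file.path(outdir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wtsv(bundle$mapping_summary, "mapping_summary.tsv")
  wtsv(bundle$uncovered_summary, "uncovered_summary.tsv")
  wtsv(bundle$error_profiles, "error_profiles.tsv")
  wtsv(bundle$evaluation, "evaluation.tsv")
  wtsv(bundle$saturation, "saturation.tsv")
  write_fasta(bundle$genome, file.path(outdir, "reference.fasta"))
  write_truth(bundle$truth, file.path(outdir, "truth.tsv"),
              chrom = bundle$genome$name)
  for (p in names(bundle$calls)) {
    write_vcf(bundle$calls[[p]], bundle$genome,
              file.path(outdir, sprintf("calls_%s.vcf", p)))
  }
  fits <- bundle$saturation_fits
  if (length(fits) > 0) {
    fit_tbl <- purrr::imap_dfr(fits, function(f, p) {
      if (is.null(f)) return(tibble(profile = p))
      dplyr::bind_cols(tibble(profile = p), tidy(f) |>
        tidyr::pivot_wider(names_from = "term", values_from = "estimate"),
        glance(f))
    })
    wtsv(fit_tbl, "saturation_fits.tsv")
  }
  manifest <- unclass(bundle$config)
  manifest$fractions <- as.numeric(manifest$fractions)
  manifest$subsample_seeds <- as.integer(manifest$subsample_seeds)
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}
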