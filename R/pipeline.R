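# Orchestration: simulate -> call -> analyse, with an on-disk report.

#' Run the full EMS-bias analysis pipeline on a simulated study
#'
#' Simulates a study (or reuses one), calls EMS SNPs, and runs every
#' analysis stage: mutation spectrum, flank GC, k-mer context enrichment
#' against a random-site baseline, sliding-window density scan, CpG
#' islands, DH/TE/expression/signal overlays, genic annotation, and the
#' panel cross-reference. When `outdir` is given, writes the simulation
#' inputs, versioned TSV/JSON result tables, and a run log recording every
#' parameter and seed; reruns with an identical config are byte-identical.
#'
#' @param config A [sim_config()].
#' @param outdir Optional report directory.
#' @param sim Optional pre-built `ems_simulation` (must match `config`).
#' @param caller A [caller_params()].
#' @param baseline_n,baseline_reps Random-site baseline size.
#' @return List of class `ems_pipeline_result` with elements `sim`, `snps`,
#'   `performance`, `spectrum`, `flank_gc50`, `flank_gc1`, `context`
#'   (per position set), `scan`, `cpg`, `dh`, `te`, `expression`,
#'   `signal_summary`, `coverage`, `annotation`, `panel_sharing`.
#' @export
run_ems_pipeline <- function(config = sim_config(), outdir = NULL,
                             sim = NULL, caller = caller_params(),
                             baseline_n = 10000, baseline_reps = 10) {
  sim <- sim %||% simulate_ems_study(config)
  genome <- sim$genome
  snps <- call_ems_snps(sim$bulk_variants, caller,
                        n_bulks = config$n_bulks)
  perf <- caller_performance(snps, sim$truth$ems)
  spectrum <- mutation_spectrum(snps, genome)
  fg50 <- flank_gc(snps, genome, 50)
  fg1 <- flank_gc(snps, genome, 1)
  baseline <- random_site_baseline(genome, n = min(baseline_n,
                                                   sum(chrom_lengths(genome))),
                                  reps = baseline_reps, seed = config$seed)
  context <- purrr::map(
    setNames(names(POSITION_SETS), names(POSITION_SETS)),
    function(ps) {
      obs <- kmer_context_freqs(snps, genome, ps)
      base <- dplyr::filter(baseline$kmer, .data$position_set == ps)
      context_enrichment(obs, base)
    }
  )
  scan <- bin_scan(snps, chrom_lengths(genome))
  islands <- find_cpg_islands(genome)
  cpg <- islands_per_bin(islands, scan)
  dh_m <- merge_dh_sites(sim$tracks$dh)
  dh <- dh_per_bin(dh_m, scan)
  te <- te_ratio_per_bin(sim$genes, scan)
  expr <- expression_summary(sim$tracks$fpkm, sim$genes, snps, scan)
  sig <- snp_signal(snps, sim$tracks$signals)
  cov <- coverage_filter(sig)
  sig_kept <- dplyr::semi_join(
    sig, dplyr::filter(cov, .data$kept), by = "modification"
  )
  sig_sum <- class_signal_summary(sig_kept, scan)
  ann <- annotate_snps(snps, sim$genes, sim$exons, genome)
  panel_f <- filter_natural_panel(sim$panel)
  sharing <- shared_with_panel(snps, panel_f)
  res <- structure(
    list(
      sim = sim, snps = snps, performance = perf, spectrum = spectrum,
      flank_gc50 = fg50, flank_gc1 = fg1, context = context, scan = scan,
      cpg = cpg, dh = dh, te = te, expression = expr,
      signal_summary = sig_sum, coverage = cov, annotation = ann,
      panel_sharing = sharing
    ),
    class = "ems_pipeline_result"
  )
  if (!is.null(outdir)) write_pipeline_report(res, config, outdir)
  res
}

write_pipeline_report <- function(res, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_simulation(res$sim, file.path(outdir, "inputs"))
  rdir <- file.path(outdir, "results")
  dir.create(rdir, showWarnings = FALSE)
  readr::write_tsv(as_tibble(res$snps), file.path(rdir, "ems_snps.tsv"))
  readr::write_tsv(as_tibble(res$spectrum), file.path(rdir, "spectrum.tsv"))
  readr::write_tsv(dplyr::bind_rows(res$context),
                   file.path(rdir, "context_enrichment.tsv"))
  readr::write_tsv(tidy(res$scan), file.path(rdir, "bins.tsv"))
  readr::write_tsv(res$cpg$class_summary, file.path(rdir, "cpg_classes.tsv"))
  readr::write_tsv(res$dh$class_summary, file.path(rdir, "dh_classes.tsv"))
  readr::write_tsv(res$te$class_summary, file.path(rdir, "te_classes.tsv"))
  readr::write_tsv(res$expression$class_summary,
                   file.path(rdir, "expression_classes.tsv"))
  readr::write_tsv(res$signal_summary, file.path(rdir, "signal_classes.tsv"))
  readr::write_tsv(as_tibble(res$annotation),
                   file.path(rdir, "annotation.tsv"))
  summary <- list(
    seed = config$seed,
    n_bulks = config$n_bulks,
    genome_bp = sum(chrom_lengths(res$sim$genome)),
    caller = res$performance,
    scan = glance(res$scan),
    flank_gc50 = res$flank_gc50$mean_gc,
    panel = res$panel_sharing$summary
  )
  jsonlite::write_json(summary, file.path(rdir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows")
  # run log: full parameter record (no timestamps, so reruns are identical)
  log <- c(
    "emsbias pipeline run",
    paste0("seed: ", config$seed),
    paste0("config: ", jsonlite::toJSON(
      config[setdiff(names(config), "ems_rate_model")],
      auto_unbox = TRUE, digits = NA
    )),
    paste0("rate_model: ", jsonlite::toJSON(
      unclass(config$ems_rate_model), auto_unbox = TRUE, digits = NA
    ))
  )
  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' Built-in acceptance checks of a pipeline run
#'
#' Evaluates the package's internal consistency checks on a completed run
#' and returns a machine-readable verdict table: chi-square threshold
#' arithmetic, caller precision/recall against the simulated truth,
#' spectrum-fraction and bin-class-count invariants.
#'
#' @param res An `ems_pipeline_result`.
#' @param min_precision,min_recall Caller performance bounds.
#' @return Tibble: check, value, pass.
#' @export
acceptance_report <- function(res, min_precision = 0.95, min_recall = 0.95) {
  cuts <- chi_square_thresholds(4.65)
  spec_ok <- abs(sum(res$spectrum$fraction) - 1) < 1e-9
  cc <- res$scan$class_counts
  tibble(
    check = c(
      "chi_square_low_cut_mu4.65", "chi_square_high_cut_mu4.65",
      "caller_precision", "caller_recall",
      "spectrum_fractions_sum_to_1", "class_counts_sum_to_bins"
    ),
    value = c(
      cuts["low_cut"], cuts["high_cut"],
      res$performance$precision, res$performance$recall,
      sum(res$spectrum$fraction), sum(cc)
    ),
    pass = c(
      abs(cuts["low_cut"] - 0.42) < 0.01, abs(cuts["high_cut"] - 8.88) < 0.01,
      res$performance$precision >= min_precision,
      res$performance$recall >= min_recall,
      spec_ok, sum(cc) == nrow(res$scan$bins)
    )
  )
}
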