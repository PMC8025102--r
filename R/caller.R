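# Cross-bulk identification of EMS-induced SNPs.

#' Caller thresholds for EMS SNP identification
#'
#' Defaults follow the multi-bulk comparison rules of bulked-segregant EMS
#' mapping: a candidate needs at least `min_alt_mq20` mutant reads with
#' mapping quality >= 20 in its test bulk, the mean mutant read count across
#' all other bulks must be <= `max_other_bulk_mean_alt`, and alt evidence in
#' any other bulk above `error_tolerance` (as a read fraction) marks the
#' site as shared/natural rather than sequencing error. Dense SNP runs
#' (residual heterozygous fragments inherited from breeding) are masked
#' when any `fragment_mask_window`-bp window in one bulk holds at least
#' `fragment_mask_min_snps` candidates.
#'
#' @param min_alt_mq20 Minimum MQ>=20 alt reads in the test bulk.
#' @param max_other_bulk_mean_alt Maximum mean alt reads over other bulks.
#' @param error_tolerance Maximum tolerated alt fraction in another bulk.
#' @param fragment_mask_window Residual-fragment window size (bp).
#' @param fragment_mask_min_snps Minimum candidate SNPs per window to mask.
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(min_alt_mq20 = 3,
                          max_other_bulk_mean_alt = 1,
                          error_tolerance = 0.20,
                          fragment_mask_window = 1e5,
                          fragment_mask_min_snps = 20) {
  vals <- c(min_alt_mq20, max_other_bulk_mean_alt, error_tolerance,
            fragment_mask_window, fragment_mask_min_snps)
  if (any(vals < 0)) abort("caller thresholds must be >= 0")
  structure(
    list(
      min_alt_mq20 = min_alt_mq20,
      max_other_bulk_mean_alt = max_other_bulk_mean_alt,
      error_tolerance = error_tolerance,
      fragment_mask_window = fragment_mask_window,
      fragment_mask_min_snps = fragment_mask_min_snps
    ),
    class = "caller_params"
  )
}

#' SNP index: alt-read fraction in a bulk
#'
#' @param alt_reads,total_reads Read counts (vectorised).
#' @return `alt_reads / total_reads`.
#' @export
snp_index <- function(alt_reads, total_reads) {
  if (any(total_reads <= 0)) abort("total_reads must be > 0 (undefined depth)")
  if (any(alt_reads < 0) || any(alt_reads > total_reads)) {
    abort("need 0 <= alt_reads <= total_reads")
  }
  alt_reads / total_reads
}

#' Sixth power of the Euclidean distance between allele-frequency vectors
#'
#' `ED = sqrt(sum_b (f_test,b - f_other,b)^2)` over the four bases; raising
#' to the 6th power sharpens linkage peaks, so SNPs tightly linked to the
#' mutant phenotype stand out.
#'
#' @param test_freqs,other_mean_freqs Numeric 4-vectors over A/C/G/T, each
#'   summing to 1 (tolerance 1e-6).
#' @return ED^6 (non-negative scalar).
#' @export
euclidean_distance6 <- function(test_freqs, other_mean_freqs) {
  for (v in list(test_freqs, other_mean_freqs)) {
    if (length(v) != 4 || any(v < 0) || abs(sum(v) - 1) > 1e-6) {
      abort("allele-frequency vectors must be length 4, non-negative, sum to 1")
    }
  }
  sqrt(sum((test_freqs - other_mean_freqs)^2))^6
}

#' Evaluate candidate sites across bulks
#'
#' Applies the cross-bulk uniqueness filter at every site with alt evidence:
#' accept iff exactly one bulk reaches `min_alt_mq20` MQ-passing alt reads,
#' the mean alt reads across the other bulks is at most
#' `max_other_bulk_mean_alt`, and no other bulk shows an alt fraction above
#' `error_tolerance` (evidence up to the tolerance is attributed to
#' sequencing error). Rejections carry machine-readable reason codes.
#'
#' @param bulk_variants Bulk-variant tibble (bulk_id, chrom, pos, ref, alt,
#'   total_reads, alt_reads, alt_reads_mq20).
#' @param params A [caller_params()].
#' @param n_bulks Total number of bulks (defaults to the number of distinct
#'   `bulk_id`s; bulks with no record at a site contribute zero alt reads).
#' @return Tibble, one row per (chrom, pos): accepted flag, reason
#'   (`low_support` / `shared` / NA), test bulk and its read counts.
#' @export
filter_candidates <- function(bulk_variants, params = caller_params(),
                              n_bulks = NULL) {
  n_bulks <- n_bulks %||% dplyr::n_distinct(bulk_variants$bulk_id)
  if (n_bulks < 2) abort("cross-bulk comparison requires >= 2 bulks")
  # Within a site the test bulk is the one with the most MQ-passing alt
  # reads; if exactly one bulk reaches the support threshold it is that one.
  site <- bulk_variants %>%
    dplyr::mutate(af = .data$alt_reads / .data$total_reads) %>%
    dplyr::group_by(.data$chrom, .data$pos) %>%
    dplyr::summarise(
      n_pass = sum(alt_reads_mq20 >= params$min_alt_mq20),
      i = which.max(alt_reads_mq20),
      ref = ref[1],
      alt = alt[i],
      test_bulk = bulk_id[i],
      total_reads = total_reads[i],
      alt_reads_test = alt_reads[i],
      alt_reads_mq20 = alt_reads_mq20[i],
      other_alt_sum = sum(alt_reads) - alt_reads[i],
      other_af_sum = sum(af) - af[i],
      other_max_af = if (dplyr::n() > 1) max(af[-i]) else 0,
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      other_mean_alt = .data$other_alt_sum / (n_bulks - 1),
      other_mean_af = .data$other_af_sum / (n_bulks - 1),
      reason = dplyr::case_when(
        .data$n_pass == 0 ~ "low_support",
        .data$n_pass > 1 ~ "shared",
        .data$other_mean_alt > params$max_other_bulk_mean_alt ~ "shared",
        .data$other_max_af > params$error_tolerance ~ "shared",
        TRUE ~ NA_character_
      ),
      accepted = is.na(.data$reason)
    ) %>%
    dplyr::select(
      "chrom", "pos", "ref", "alt", "test_bulk", "total_reads",
      alt_reads = "alt_reads_test", "alt_reads_mq20", "other_mean_alt",
      "other_mean_af", "other_max_af", "accepted", "reason"
    ) %>%
    dplyr::arrange(.data$chrom, .data$pos)
  site
}

#' Mask residual heterozygous fragments
#'
#' Any window of `fragment_mask_window` bp containing at least
#' `fragment_mask_min_snps` candidate SNPs of one bulk is masked; the
#' reported mask is the union (per bulk) of the candidate spans of all
#' qualifying windows, with overlapping/adjacent windows merged.
#'
#' @param candidates Tibble with bulk_id, chrom, pos (candidate SNPs).
#' @param params A [caller_params()].
#' @return Tibble of masked intervals: bulk_id, chrom, start, end.
#' @export
mask_residual_fragments <- function(candidates, params = caller_params()) {
  if (nrow(candidates) == 0) {
    return(tibble(bulk_id = character(), chrom = character(),
                  start = numeric(), end = numeric()))
  }
  k <- params$fragment_mask_min_snps
  w <- params$fragment_mask_window
  candidates %>%
    dplyr::group_by(.data$bulk_id, .data$chrom) %>%
    dplyr::group_modify(function(d, key) {
      p <- sort(d$pos)
      n <- length(p)
      if (n < k) return(tibble(start = numeric(0), end = numeric(0)))
      i <- seq_len(n - k + 1)
      ok <- p[i + k - 1] - p[i] <= w - 1
      if (!any(ok)) return(tibble(start = numeric(0), end = numeric(0)))
      iv <- tibble(chrom = "x", start = p[i][ok], end = p[i + k - 1][ok])
      merge_intervals(iv)[, c("start", "end")]
    }) %>%
    dplyr::ungroup()
}

#' Call EMS-induced SNPs from multi-bulk variant tables
#'
#' Runs the candidate filter, masks residual heterozygous fragments, and
#' annotates accepted SNPs with their SNP index, ED^6 (test-bulk vs
#' mean-of-other-bulks allele-frequency distance, 6th power) and mutation
#' type on the plus strand.
#'
#' @inheritParams filter_candidates
#' @return Tibble of class `ems_snp_set`, sorted by (chrom, pos): chrom,
#'   pos, ref, alt, bulk_id, total_reads, alt_reads, alt_reads_mq20, si,
#'   ed6, mutation_type. Attributes `rejects` (tibble with reason codes),
#'   `masks` (masked intervals) and `params`.
#' @export
call_ems_snps <- function(bulk_variants, params = caller_params(),
                          n_bulks = NULL) {
  n_bulks <- n_bulks %||% dplyr::n_distinct(bulk_variants$bulk_id)
  if (n_bulks < 2) abort("cross-bulk comparison requires >= 2 bulks")
  site <- filter_candidates(bulk_variants, params, n_bulks)
  acc <- dplyr::filter(site, .data$accepted)
  rej <- dplyr::filter(site, !.data$accepted)
  masks <- mask_residual_fragments(
    dplyr::rename(acc, bulk_id = "test_bulk"), params
  )
  if (nrow(masks) > 0 && nrow(acc) > 0) {
    in_mask <- rep(FALSE, nrow(acc))
    for (j in seq_len(nrow(masks))) {
      in_mask <- in_mask |
        (acc$test_bulk == masks$bulk_id[j] & acc$chrom == masks$chrom[j] &
           acc$pos >= masks$start[j] & acc$pos <= masks$end[j])
    }
    rej <- dplyr::bind_rows(
      rej,
      acc[in_mask, ] %>%
        dplyr::mutate(accepted = FALSE, reason = "residual_fragment")
    )
    acc <- acc[!in_mask, ]
  }
  out <- acc %>%
    dplyr::mutate(
      bulk_id = .data$test_bulk,
      si = snp_index(.data$alt_reads, .data$total_reads),
      ed6 = (sqrt(2) * abs(.data$si - .data$other_mean_af))^6,
      mutation_type = paste0(.data$ref, ">", .data$alt)
    ) %>%
    dplyr::select(
      "chrom", "pos", "ref", "alt", "bulk_id", "total_reads", "alt_reads",
      "alt_reads_mq20", "si", "ed6", "mutation_type"
    ) %>%
    dplyr::arrange(.data$chrom, .data$pos)
  structure(out, class = c("ems_snp_set", class(out)),
            rejects = dplyr::arrange(rej, .data$chrom, .data$pos),
            masks = masks, params = params, n_bulks = n_bulks)
}

#' Filter a natural-SNP panel by support, MAF and missingness
#'
#' Retains biallelic sites typed in at least `min_typed` varieties with
#' minor allele frequency >= `min_maf` and missing rate < `max_missing`.
#' Multiallelic records (alt longer than one base or comma-separated) are
#' skipped with a warning count.
#'
#' @param sites Tibble from [panel_site_stats()] (chrom, pos, ref, alt,
#'   n_typed, maf, missing_rate), or an `ems_panel`.
#' @param min_typed,min_maf,max_missing Thresholds.
#' @return Filtered tibble; attribute `n_multiallelic_skipped`.
#' @export
filter_natural_panel <- function(sites, min_typed = 30, min_maf = 0.01,
                                 max_missing = 0.8) {
  if (inherits(sites, "ems_panel")) sites <- panel_site_stats(sites)
  multi <- grepl(",", sites$alt, fixed = TRUE) | nchar(sites$alt) != 1 |
    nchar(sites$ref) != 1
  if (any(multi)) {
    warn(paste0("skipped ", sum(multi), " multiallelic/non-SNP record(s)"))
    sites <- sites[!multi, ]
  }
  out <- sites %>%
    dplyr::filter(
      .data$n_typed >= min_typed,
      .data$maf >= min_maf,
      .data$missing_rate < max_missing
    )
  attr(out, "n_multiallelic_skipped") <- sum(multi)
  out
}

#' Compare a called SNP set with the simulator ground truth
#'
#' @param snps An `ems_snp_set` (or tibble with chrom, pos, bulk_id).
#' @param truth EMS truth tibble from the simulator.
#' @return One-row tibble: n_called, n_truth, n_matched, precision, recall.
#' @export
caller_performance <- function(snps, truth) {
  key <- function(d) paste(d$chrom, d$pos, d$bulk_id)
  called <- key(snps)
  tru <- key(truth)
  n_match <- sum(called %in% tru)
  tibble(
    n_called = length(called), n_truth = length(tru), n_matched = n_match,
    precision = if (length(called) > 0) n_match / length(called) else NA_real_,
    recall = if (length(tru) > 0) n_match / length(tru) else NA_real_
  )
}
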