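# DH sites, epigenetic signal extraction, TE ratios and expression overlay.

#' Merge DNase I hypersensitive sites within a gap
#'
#' Intervals separated by at most `gap` bp (the single-end read length of
#' the source assay) are merged transitively; output is sorted and
#' disjoint. Idempotent.
#'
#' @param dh Tibble: chrom, start, end (1-based inclusive).
#' @param gap Maximum gap (bp) between merged neighbours.
#' @return Merged tibble: chrom, start, end.
#' @export
merge_dh_sites <- function(dh, gap = 36) {
  if (nrow(dh) > 0 && (any(dh$start < 1) || any(dh$end < dh$start))) {
    abort("DH intervals must satisfy 1 <= start <= end")
  }
  merge_intervals(dh, gap = gap)
}

#' DH sites per bin with class summary
#'
#' Merged DH sites are assigned to every bin containing their midpoint; the
#' class summary reports the fraction of bins with more than `threshold`
#' sites.
#'
#' @param dh Merged DH tibble.
#' @param scan An `ems_bin_scan` (or classified bin tibble).
#' @param threshold Count threshold (strictly greater than).
#' @return List: `bins` (+ dh_count), `class_summary` (class, n_bins,
#'   n_gt_threshold, fraction_gt_threshold), `overall_fraction`.
#' @export
dh_per_bin <- function(dh, scan, threshold = 20) {
  bins <- if (inherits(scan, "ems_bin_scan")) scan$bins else scan
  pts <- tibble(chrom = dh$chrom, pos = interval_midpoint(dh$start, dh$end))
  bins$dh_count <- count_positions_in_bins(bins, pts)
  cs <- bins %>%
    dplyr::group_by(.data$class) %>%
    dplyr::summarise(
      n_bins = dplyr::n(),
      n_gt_threshold = sum(.data$dh_count > threshold),
      fraction_gt_threshold = mean(.data$dh_count > threshold),
      .groups = "drop"
    )
  list(bins = bins, class_summary = cs,
       overall_fraction = mean(bins$dh_count > threshold))
}

#' Per-SNP epigenetic signal (max over experiments, +/-10 bp fallback)
#'
#' For each modification, a SNP's value is the maximum signal over the
#' modification's experiments at the SNP base; if no experiment covers the
#' base, the maximum within `flank` bp is used (source `flank10`); SNPs
#' still uncovered are `missing`.
#'
#' @param snps Tibble with chrom, pos.
#' @param signals Signal tibble: modification, experiment, chrom, start,
#'   end, value (BedGraph-style constant-value intervals).
#' @param flank Fallback window half-width in bp.
#' @return Tibble: chrom, pos, modification, value, source
#'   (`at_site` / `flank10` / `missing`).
#' @export
snp_signal <- function(snps, signals, flank = 10) {
  if (nrow(signals) == 0) abort("need at least one experiment track")
  purrr::map_dfr(unique(signals$modification), function(mod) {
    tr <- dplyr::filter(signals, .data$modification == mod)
    val_at <- max_signal_in_window(snps, tr, 0)
    val_fl <- max_signal_in_window(snps, tr, flank)
    tibble(
      chrom = snps$chrom, pos = snps$pos, modification = mod,
      value = dplyr::coalesce(val_at, val_fl),
      source = dplyr::case_when(
        !is.na(val_at) ~ "at_site",
        !is.na(val_fl) ~ "flank10",
        TRUE ~ "missing"
      )
    )
  })
}

# Max track value overlapping [pos - flank, pos + flank]; NA if uncovered.
max_signal_in_window <- function(snps, track, flank) {
  out <- rep(NA_real_, nrow(snps))
  for (ch in unique(snps$chrom)) {
    si <- which(snps$chrom == ch)
    ti <- which(track$chrom == ch)
    if (length(ti) == 0) next
    q <- IRanges::IRanges(start = pmax(snps$pos[si] - flank, 1),
                          end = snps$pos[si] + flank)
    s <- IRanges::IRanges(start = track$start[ti], end = track$end[ti])
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) == 0) next
    d <- tibble(
      i = S4Vectors::queryHits(ov),
      v = track$value[ti[S4Vectors::subjectHits(ov)]]
    ) %>%
      dplyr::group_by(.data$i) %>%
      dplyr::summarise(mx = max(.data$v))
    out[si[d$i]] <- d$mx
  }
  out
}

#' Coverage filter for modifications
#'
#' A modification is retained only when its signal covers (at site or
#' within the fallback flank) at least `min_cover` of the SNPs.
#'
#' @param snp_signals Tibble from [snp_signal()].
#' @param min_cover Minimum covered fraction (default 0.5, "at least half").
#' @return Tibble: modification, coverage, kept.
#' @export
coverage_filter <- function(snp_signals, min_cover = 0.5) {
  snp_signals %>%
    dplyr::group_by(.data$modification) %>%
    dplyr::summarise(coverage = mean(.data$source != "missing"),
                     .groups = "drop") %>%
    dplyr::mutate(kept = .data$coverage >= min_cover)
}

# Class of the bin containing each point; with overlapping bins the class
# of the covering bin with the higher SNP count wins (ties: earlier bin).
point_bin_class <- function(points, bins, all_bins = FALSE) {
  asg <- assign_to_bins(bins, points)
  if (nrow(asg) == 0) {
    return(factor(rep(NA, nrow(points)),
                  levels = levels(bins$class), ordered = TRUE))
  }
  best <- asg %>%
    dplyr::mutate(count = bins$snp_count[.data$bin_idx]) %>%
    dplyr::arrange(.data$point_idx, dplyr::desc(.data$count), .data$bin_idx) %>%
    dplyr::distinct(.data$point_idx, .keep_all = TRUE)
  cls <- factor(rep(NA, nrow(points)), levels = levels(bins$class),
                ordered = TRUE)
  cls[best$point_idx] <- bins$class[best$bin_idx]
  cls
}

#' Mean signal per modification and bin class
#'
#' Each SNP inherits the class of the covering bin with the higher SNP
#' count; per modification and class, the mean of per-SNP maximum signals
#' is reported (missing values excluded; classes with no covered SNP give
#' NA).
#'
#' @param snp_signals Tibble from [snp_signal()].
#' @param scan An `ems_bin_scan`.
#' @return Tibble: modification, class, n_snps, n_covered, mean_signal.
#' @export
class_signal_summary <- function(snp_signals, scan) {
  bins <- scan$bins
  snps <- dplyr::distinct(snp_signals, .data$chrom, .data$pos)
  snps$class <- point_bin_class(snps, bins)
  d <- dplyr::left_join(snp_signals, snps, by = c("chrom", "pos"))
  d %>%
    dplyr::group_by(.data$modification, .data$class) %>%
    dplyr::summarise(
      n_snps = dplyr::n(),
      n_covered = sum(.data$source != "missing"),
      mean_signal = if (sum(.data$source != "missing") > 0) {
        mean(.data$value[.data$source != "missing"])
      } else NA_real_,
      .groups = "drop"
    ) %>%
    tidyr::complete(.data$modification, .data$class)
}

#' TE / non-TE gene ratio per bin
#'
#' Genes are assigned to bins by span midpoint. Bins without genes are
#' flagged `no_genes`; all-TE bins (non-TE denominator 0) are flagged
#' `zero_denominator` and excluded from the class summary, which reports
#' the fraction of bins with ratio above `threshold`.
#'
#' @param genes Gene tibble with chrom, start, end, biotype.
#' @param scan An `ems_bin_scan` (or classified bin tibble).
#' @param threshold Ratio threshold for the class summary (default 0.5,
#'   "TE-enriched").
#' @return List: `bins` (+ n_te, n_non_te, te_ratio, ratio_flag),
#'   `class_summary`.
#' @export
te_ratio_per_bin <- function(genes, scan, threshold = 0.5) {
  bins <- if (inherits(scan, "ems_bin_scan")) scan$bins else scan
  mid <- tibble(chrom = genes$chrom,
                pos = interval_midpoint(genes$start, genes$end))
  te <- genes$biotype == "TE"
  bins$n_te <- count_positions_in_bins(bins, mid[te, ])
  bins$n_non_te <- count_positions_in_bins(bins, mid[!te, ])
  bins <- bins %>%
    dplyr::mutate(
      te_ratio = dplyr::if_else(.data$n_non_te > 0,
                                .data$n_te / .data$n_non_te, NA_real_),
      ratio_flag = dplyr::case_when(
        .data$n_te + .data$n_non_te == 0 ~ "no_genes",
        .data$n_non_te == 0 ~ "zero_denominator",
        TRUE ~ "ok"
      )
    )
  cs <- bins %>%
    dplyr::filter(.data$ratio_flag == "ok") %>%
    dplyr::group_by(.data$class) %>%
    dplyr::summarise(
      n_bins = dplyr::n(),
      fraction_gt_threshold = mean(.data$te_ratio > threshold),
      mean_ratio = mean(.data$te_ratio),
      .groups = "drop"
    )
  list(bins = bins, class_summary = cs)
}

#' Low-expression fractions per bin class, split by EMS targeting
#'
#' Gene mean FPKM is the unweighted mean over datasets; a gene is
#' EMS-targeted when at least one EMS SNP lies within its body or
#' `flank` bp on either side. Genes inherit the class of the covering bin
#' with the higher SNP count (midpoint assignment); genes absent from the
#' expression matrix are excluded.
#'
#' @param fpkm Tibble: gene_id + one numeric column per dataset.
#' @param genes Gene tibble.
#' @param snps EMS SNP tibble (chrom, pos).
#' @param scan An `ems_bin_scan`.
#' @param flank Targeting flank in bp (default 3 kb).
#' @param low_cutoff FPKM cutoff for "low expression" (default 1).
#' @return List: `genes` (gene_id, mean_fpkm, low_expression, ems_targeted,
#'   class), `class_summary` (class, targeted, n_genes, fraction_low).
#' @export
expression_summary <- function(fpkm, genes, snps, scan, flank = 3000,
                               low_cutoff = 1) {
  bins <- scan$bins
  mat <- as.matrix(fpkm[, setdiff(names(fpkm), "gene_id"), drop = FALSE])
  expr <- tibble(
    gene_id = fpkm$gene_id,
    mean_fpkm = rowMeans(mat)
  )
  d <- dplyr::inner_join(genes, expr, by = "gene_id")
  # targeting: any SNP within [start - flank, end + flank]
  targeted <- rep(FALSE, nrow(d))
  for (ch in unique(d$chrom)) {
    gi <- which(d$chrom == ch)
    p <- snps$pos[snps$chrom == ch]
    if (length(p) == 0) next
    q <- IRanges::IRanges(start = pmax(d$start[gi] - flank, 1),
                          end = d$end[gi] + flank)
    s <- IRanges::IRanges(start = p, width = 1)
    targeted[gi] <- IRanges::countOverlaps(q, s) > 0
  }
  d$ems_targeted <- targeted
  d$low_expression <- d$mean_fpkm < low_cutoff
  d$class <- point_bin_class(
    tibble(chrom = d$chrom, pos = interval_midpoint(d$start, d$end)), bins
  )
  cs <- d %>%
    dplyr::group_by(.data$class, .data$ems_targeted) %>%
    dplyr::summarise(
      n_genes = dplyr::n(),
      fraction_low = mean(.data$low_expression),
      mean_fpkm = mean(.data$mean_fpkm),
      .groups = "drop"
    )
  list(
    genes = dplyr::select(d, "gene_id", "chrom", "start", "end", "biotype",
                          "mean_fpkm", "low_expression", "ems_targeted",
                          "class"),
    class_summary = cs
  )
}
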