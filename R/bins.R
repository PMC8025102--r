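# Overlapping sliding-window scan of SNP density with chi-square thresholds.

#' Build overlapping genomic bins
#'
#' Windows of `window` bp are placed at every multiple of `step` before the
#' chromosome end; trailing windows that run past the end are emitted
#' clipped (never discarded), so every interior position is covered by
#' exactly `window / step` bins. Coordinates are 1-based inclusive.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param window Window size in bp (default 100 kb).
#' @param step Step size in bp (default 50 kb; 20/25 kb are the alternate
#'   scan resolutions).
#' @return Tibble: chrom, start, end, width, clipped.
#' @export
make_bins <- function(chrom_lengths, window = 1e5, step = 5e4) {
  if (step <= 0 || step > window) abort("need 0 < step <= window")
  purrr::map_dfr(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts0 <- seq(0, max(0, L - 1), by = step)
    starts0 <- starts0[starts0 < L]
    d <- tibble(
      chrom = ch, start = starts0 + 1, end = pmin(starts0 + window, L)
    )
    d$width <- d$end - d$start + 1
    d$clipped <- d$width < window
    d[, c("chrom", "start", "end", "width", "clipped")]
  })
}

#' Count SNPs per (overlapping) bin
#'
#' Membership is inclusive of both bin edges; a SNP in an overlap region is
#' counted in every covering bin.
#'
#' @param bins Tibble from [make_bins()].
#' @param snps Tibble with chrom, pos.
#' @return `bins` with an `snp_count` column.
#' @export
count_snps_per_bin <- function(bins, snps) {
  bins$snp_count <- count_positions_in_bins(bins, snps)
  bins
}

# Shared midpoint-free counting: how many of `points` (chrom, pos) fall in
# each bin.
count_positions_in_bins <- function(bins, points) {
  counts <- integer(nrow(bins))
  if (nrow(points) == 0) return(counts)
  for (ch in unique(bins$chrom)) {
    bi <- which(bins$chrom == ch)
    p <- points$pos[points$chrom == ch]
    if (length(p) == 0) next
    q <- IRanges::IRanges(start = p, width = 1)
    s <- IRanges::IRanges(start = bins$start[bi], end = bins$end[bi])
    counts[bi] <- IRanges::countOverlaps(s, q)
  }
  counts
}

# Assign interval midpoints (or plain positions) to covering bins; returns a
# tibble (bin_idx, point_idx).
assign_to_bins <- function(bins, points) {
  hits <- list()
  for (ch in unique(bins$chrom)) {
    bi <- which(bins$chrom == ch)
    pi <- which(points$chrom == ch)
    if (length(pi) == 0) next
    q <- IRanges::IRanges(start = points$pos[pi], width = 1)
    s <- IRanges::IRanges(start = bins$start[bi], end = bins$end[bi])
    ov <- IRanges::findOverlaps(q, s)
    hits[[ch]] <- tibble(
      point_idx = pi[S4Vectors::queryHits(ov)],
      bin_idx = bi[S4Vectors::subjectHits(ov)]
    )
  }
  dplyr::bind_rows(hits)
}

#' Chi-square density thresholds around a mean bin count
#'
#' Solves `(n - mu)^2 / mu = qchisq(1 - alpha, 1)` for the bin counts that
#' differ significantly from a uniform-placement mean: `low = mu -
#' sqrt(chi2 * mu)` (floored at 0) and `high = mu + sqrt(chi2 * mu)`.
#'
#' @param mu Mean SNP count per bin (> 0).
#' @param alpha Significance level (default 0.05, df = 1).
#' @return Named numeric: low_cut, high_cut.
#' @export
chi_square_thresholds <- function(mu, alpha = 0.05) {
  if (!is.numeric(mu) || mu <= 0) abort("`mu` must be > 0")
  chi2 <- qchisq(1 - alpha, df = 1)
  half <- sqrt(chi2 * mu)
  c(low_cut = max(mu - half, 0), high_cut = mu + half)
}

#' Classify bins into coldspot / low / mid / hotspot
#'
#' Coldspots have no SNPs; hotspots have at least `hotspot_min` (default
#' 10); the remaining bins split at `mid_min` (default 5) into the low
#' (`[1, 5)`) and mid (`[5, 10)`) density groups, so the four classes are
#' mutually exclusive and exhaustive.
#'
#' @param bins Tibble with an `snp_count` column.
#' @param hotspot_min Minimum count for a hotspot.
#' @param mid_min Boundary between the low and mid groups.
#' @return `bins` with a `class` factor (coldspot < low < mid < hotspot).
#' @export
classify_bins <- function(bins, hotspot_min = 10, mid_min = 5) {
  bins$class <- factor(
    dplyr::case_when(
      bins$snp_count == 0 ~ "coldspot",
      bins$snp_count >= hotspot_min ~ "hotspot",
      bins$snp_count >= mid_min ~ "mid",
      TRUE ~ "low"
    ),
    levels = c("coldspot", "low", "mid", "hotspot"), ordered = TRUE
  )
  bins
}

#' Per-bin ED^6 linkage profile
#'
#' @param bins Tibble of bins.
#' @param snps Tibble with chrom, pos and an `ed6` column.
#' @return `bins` with max_ed6 and mean_ed6 (0 for empty bins).
#' @export
bin_ed6_profile <- function(bins, snps) {
  bins$max_ed6 <- 0
  bins$mean_ed6 <- 0
  if (nrow(snps) == 0 || !"ed6" %in% names(snps)) return(bins)
  asg <- assign_to_bins(bins, snps)
  if (nrow(asg) == 0) return(bins)
  agg <- asg %>%
    dplyr::mutate(ed6 = snps$ed6[.data$point_idx]) %>%
    dplyr::group_by(.data$bin_idx) %>%
    dplyr::summarise(mx = max(.data$ed6), mn = mean(.data$ed6))
  bins$max_ed6[agg$bin_idx] <- agg$mx
  bins$mean_ed6[agg$bin_idx] <- agg$mn
  bins
}

#' Sliding-window hotspot/coldspot scan of EMS SNP density
#'
#' Builds overlapping bins, counts SNPs per bin, derives the chi-square
#' significance thresholds from the mean bin count, classifies bins
#' (coldspot / low / mid / hotspot; the hotspot call is the integer rule
#' `count >= hotspot_min`, reported alongside the chi-square cut that
#' justifies it) and profiles per-bin ED^6 when available.
#'
#' @param snps SNP tibble (chrom, pos, optionally ed6).
#' @param chrom_lengths Named chromosome lengths.
#' @param window,step Bin geometry in bp.
#' @param alpha Chi-square significance level.
#' @param hotspot_min Hotspot count threshold.
#' @param include_clipped Include clipped trailing bins in the mean.
#' @return Object of class `ems_bin_scan`: list with `bins` (tibble:
#'   chrom, start, end, width, clipped, snp_count, class, max_ed6,
#'   mean_ed6), `window`, `step`, `alpha`, `mu`, `low_cut`, `high_cut`,
#'   `class_counts`.
#' @export
bin_scan <- function(snps, chrom_lengths, window = 1e5, step = 5e4,
                     alpha = 0.05, hotspot_min = 10, include_clipped = TRUE) {
  bins <- make_bins(chrom_lengths, window, step)
  bins <- count_snps_per_bin(bins, snps)
  mu_bins <- if (include_clipped) bins else dplyr::filter(bins, !.data$clipped)
  mu <- mean(mu_bins$snp_count)
  cuts <- if (mu > 0) chi_square_thresholds(mu, alpha) else
    c(low_cut = NA_real_, high_cut = NA_real_)
  bins <- classify_bins(bins, hotspot_min)
  bins <- bin_ed6_profile(bins, snps)
  structure(
    list(
      bins = bins, window = window, step = step, alpha = alpha, mu = mu,
      low_cut = unname(cuts["low_cut"]), high_cut = unname(cuts["high_cut"]),
      hotspot_min = hotspot_min,
      class_counts = table(bins$class)
    ),
    class = "ems_bin_scan"
  )
}

#' @exportS3Method generics::tidy
tidy.ems_bin_scan <- function(x, ...) {
  as_tibble(x$bins)
}

#' @exportS3Method generics::glance
glance.ems_bin_scan <- function(x, ...) {
  cc <- as.list(x$class_counts)
  tibble(
    n_bins = nrow(x$bins), window = x$window, step = x$step,
    mu = x$mu, low_cut = x$low_cut, high_cut = x$high_cut,
    n_coldspot = cc$coldspot, n_low = cc$low, n_mid = cc$mid,
    n_hotspot = cc$hotspot
  )
}

#' @exportS3Method base::print
print.ems_bin_scan <- function(x, ...) {
  cat("EMS SNP density scan:", nrow(x$bins), "bins of", x$window,
      "bp (step", x$step, "bp)\n")
  cat(sprintf("mean %.3f SNPs/bin; chi-square cuts (alpha=%.2f): <=%.2f / >=%.2f\n",
              x$mu, x$alpha, x$low_cut, x$high_cut))
  print(x$class_counts)
  invisible(x)
}
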