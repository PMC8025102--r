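# CpG-island calling (Gardiner-Garden-style window criteria) and per-bin /
# per-SNP-flank CpG statistics.

#' CpG island calling parameters
#'
#' The four standard criteria: 100-bp windows slid by 1 bp must have
#' GC >= 50% and observed/expected CpG >= 0.6; merged passing spans must be
#' at least 200 bp long.
#'
#' @param window Window size (bp).
#' @param min_len Minimum island length (bp).
#' @param gc_min Minimum window GC fraction.
#' @param oe_min Minimum window observed/expected CpG ratio.
#' @param shift Window shift (bp).
#' @return List of class `cpg_params`.
#' @export
cpg_params <- function(window = 100, min_len = 200, gc_min = 0.50,
                       oe_min = 0.6, shift = 1) {
  if (window > min_len) abort("`window` must be <= `min_len`")
  structure(
    list(window = window, min_len = min_len, gc_min = gc_min,
         oe_min = oe_min, shift = shift),
    class = "cpg_params"
  )
}

#' Observed/expected CpG ratio of a sequence window
#'
#' `(N_CpG * L) / (N_C * N_G)`; 0 when the sequence has no C or no G.
#'
#' @param seq Character vector of sequence windows.
#' @return Numeric vector of ratios.
#' @export
obs_exp_cpg <- function(seq) {
  L <- nchar(seq)
  if (any(L == 0)) abort("window length must be > 0")
  nc <- str_count(seq, fixed("C"))
  ng <- str_count(seq, fixed("G"))
  ncpg <- str_count(seq, fixed("CG"))
  ifelse(nc * ng == 0, 0, ncpg * L / (nc * ng))
}

# Vectorised window sums over one chromosome string; returns pass mask over
# window start positions. N bases count as neither C nor G but occupy
# window length.
cpg_window_pass <- function(v, params) {
  L <- length(v)
  w <- params$window
  if (L < w) return(logical(0))
  isC <- as.integer(v == "C")
  isG <- as.integer(v == "G")
  isCpG <- as.integer(v == "C" & c(v[-1], "") == "G")
  cs_c <- cumsum(isC)
  cs_g <- cumsum(isG)
  cs_cg <- cumsum(isCpG)
  starts <- seq(1, L - w + 1, by = params$shift)
  wc <- cs_c[starts + w - 1] - c(0, cs_c)[starts]
  wg <- cs_g[starts + w - 1] - c(0, cs_g)[starts]
  # CpG dinucleotide fully inside the window: its C at positions
  # [start, start+w-2]
  wcg <- cs_cg[starts + w - 2] - c(0, cs_cg)[starts]
  gc_frac <- (wc + wg) / w
  oe <- ifelse(wc * wg == 0, 0, wcg * w / (wc * wg))
  gc_frac >= params$gc_min & oe >= params$oe_min
}

#' Call CpG islands on a sequence or genome
#'
#' Slides a `window`-bp window by `shift` bp; windows with GC >=
#' `gc_min` and observed/expected CpG >= `oe_min` are marked, overlapping
#' or adjacent passing windows are merged into maximal spans, and spans of
#' at least `min_len` bp are reported with whole-span GC and obs/exp
#' (descriptive; the calling criterion is per-window).
#'
#' @param x An `ems_genome` or a single sequence string.
#' @param params A [cpg_params()].
#' @return Tibble: chrom, start, end, length, gc_fraction, obs_exp_cpg.
#'   Sequences shorter than the window give an empty result.
#' @export
find_cpg_islands <- function(x, params = cpg_params()) {
  seqs <- if (inherits(x, "ems_genome")) x$seq else
    setNames(as.character(x), if (is.null(names(x))) "seq" else names(x))
  out <- purrr::map_dfr(names(seqs), function(ch) {
    v <- strsplit(seqs[[ch]], "", fixed = TRUE)[[1]]
    pass <- cpg_window_pass(v, params)
    if (!any(pass)) return(tibble())
    starts <- which(pass)
    # connected components of bases covered by any passing window
    L <- length(v)
    cov <- integer(L + 1)
    cov[starts] <- cov[starts] + 1L
    ends1 <- pmin(starts + params$window, L + 1)
    cov[ends1] <- cov[ends1] - 1L
    covered <- cumsum(cov)[seq_len(L)] > 0
    r <- rle(covered)
    stops <- cumsum(r$lengths)
    iv <- tibble(
      chrom = ch,
      start = (stops - r$lengths + 1)[r$values],
      end = stops[r$values]
    )
    iv <- dplyr::filter(iv, .data$end - .data$start + 1 >= params$min_len)
    if (nrow(iv) == 0) return(tibble())
    span <- substring(seqs[[ch]], iv$start, iv$end)
    tibble(
      chrom = ch, start = iv$start, end = iv$end,
      length = iv$end - iv$start + 1,
      gc_fraction = str_count(span, "[GC]") / nchar(span),
      obs_exp_cpg = obs_exp_cpg(span)
    )
  })
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  length = numeric(), gc_fraction = numeric(),
                  obs_exp_cpg = numeric())
  }
  out
}

#' CpG islands per bin with class summary
#'
#' Each island is assigned to every bin containing its midpoint. The class
#' summary reports, per SNP-density class, the fraction of bins harbouring
#' at least `threshold` islands.
#'
#' @param islands Tibble from [find_cpg_islands()].
#' @param scan An `ems_bin_scan` (or a classified bin tibble).
#' @param threshold Island-count threshold for the class summary.
#' @return List: `bins` (bin tibble + island_count), `class_summary`
#'   (tibble: class, n_bins, n_ge_threshold, fraction_ge_threshold),
#'   `overall_fraction` (all bins).
#' @export
islands_per_bin <- function(islands, scan, threshold = 40) {
  bins <- if (inherits(scan, "ems_bin_scan")) scan$bins else scan
  pts <- tibble(
    chrom = islands$chrom,
    pos = interval_midpoint(islands$start, islands$end)
  )
  bins$island_count <- count_positions_in_bins(bins, pts)
  cs <- bins %>%
    dplyr::group_by(.data$class) %>%
    dplyr::summarise(
      n_bins = dplyr::n(),
      n_ge_threshold = sum(.data$island_count >= threshold),
      fraction_ge_threshold = mean(.data$island_count >= threshold),
      .groups = "drop"
    )
  list(
    bins = bins,
    class_summary = cs,
    overall_fraction = mean(bins$island_count >= threshold)
  )
}

#' CpG islands in the flanks of each SNP
#'
#' Calls islands on the sequence spanning `flank` bp on both sides of each
#' SNP (clipped at chromosome ends) and groups SNPs by their island count.
#'
#' @param snps Tibble with chrom, pos.
#' @param genome An `ems_genome`.
#' @param flank Flank width (bp) on each side.
#' @param params A [cpg_params()].
#' @return List: `per_snp` (chrom, pos, island_count), `groups` (tibble:
#'   island_count, n, fraction; fractions sum to 1).
#' @export
flanking_cpg_count <- function(snps, genome, flank = 5000,
                               params = cpg_params()) {
  lens <- chrom_lengths(genome)
  cnt <- integer(nrow(snps))
  for (j in seq_len(nrow(snps))) {
    ch <- snps$chrom[j]
    lo <- max(1, snps$pos[j] - flank)
    hi <- min(lens[[ch]], snps$pos[j] + flank)
    s <- substring(genome$seq[[ch]], lo, hi)
    cnt[j] <- nrow(find_cpg_islands(s, params))
  }
  per_snp <- tibble(chrom = snps$chrom, pos = snps$pos, island_count = cnt)
  groups <- per_snp %>%
    dplyr::count(.data$island_count, name = "n") %>%
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  list(per_snp = per_snp, groups = groups)
}
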