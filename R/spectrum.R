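# Mutation spectrum, flanking composition, and k-mer context enrichment.

POSITION_SETS <- list(
  "-1/0" = c(-1, 0), "0/+1" = c(0, 1),
  "-2/-1/0" = c(-2, -1, 0), "-1/0/+1" = c(-1, 0, 1), "0/+1/+2" = c(0, 1, 2)
)

check_ref_match <- function(snps, genome) {
  obs <- genome_base(genome, snps$chrom, snps$pos)
  bad <- which(obs != snps$ref)
  if (length(bad) > 0) {
    b <- bad[1]
    abort(sprintf(
      "reference mismatch at %s:%d (SNP ref %s, genome %s)",
      snps$chrom[b], snps$pos[b], snps$ref[b], obs[b]
    ))
  }
  invisible(TRUE)
}

#' Mutation spectrum over the 12 substitution types
#'
#' Counts each SNP's ref>alt type on the plus strand and reports the
#' fraction of SNPs whose reference base is G or C.
#'
#' @param snps Tibble with chrom, pos, ref, alt.
#' @param genome Optional `ems_genome`; when given, every SNP's ref allele
#'   is checked against the genome (mismatch is a data-integrity error).
#' @return Tibble of class `ems_spectrum`: type, ref, alt, n, fraction
#'   (all 12 types, zero-filled). Attributes `gc_site_fraction`, `n_snps`.
#' @export
mutation_spectrum <- function(snps, genome = NULL) {
  if (!is.null(genome) && nrow(snps) > 0) check_ref_match(snps, genome)
  types <- mutation_types()
  tab <- table(factor(paste0(snps$ref, ">", snps$alt), levels = types))
  out <- tibble(
    type = types,
    ref = substr(types, 1, 1),
    alt = substr(types, 3, 3),
    n = as.integer(tab),
    fraction = if (nrow(snps) > 0) as.integer(tab) / nrow(snps) else NA_real_
  )
  gc_frac <- if (nrow(snps) > 0) mean(snps$ref %in% c("G", "C")) else NA_real_
  structure(out, class = c("ems_spectrum", class(out)),
            gc_site_fraction = gc_frac, n_snps = nrow(snps))
}

#' GC content of sequences flanking SNPs
#'
#' Computes the mean GC fraction over the `flank_bp` bases on each side of
#' every SNP, excluding the SNP base itself. SNPs whose flanks run off the
#' chromosome are skipped (and counted). For `flank_bp = 1` the fraction of
#' SNPs with at least one G/C immediate neighbour is also reported.
#'
#' @param snps Tibble with chrom, pos.
#' @param genome An `ems_genome`.
#' @param flank_bp Flank width in bp on each side (1 and 50 in the standard
#'   analyses).
#' @return One-row tibble: flank_bp, mean_gc, prop_gc_adjacent (NA unless
#'   flank_bp == 1), n_used, n_skipped.
#' @export
flank_gc <- function(snps, genome, flank_bp = 50) {
  lens <- chrom_lengths(genome)
  gc_each <- rep(NA_real_, nrow(snps))
  adj <- rep(NA, nrow(snps))
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    pos <- snps$pos[idx]
    ok <- pos - flank_bp >= 1 & pos + flank_bp <= lens[[ch]]
    s <- genome$seq[[ch]]
    left <- substring(s, pos[ok] - flank_bp, pos[ok] - 1)
    right <- substring(s, pos[ok] + 1, pos[ok] + flank_bp)
    both <- paste0(left, right)
    gc_each[idx[ok]] <-
      str_count(both, "[GC]") / (2 * flank_bp)
    if (flank_bp == 1) {
      adj[idx[ok]] <- grepl("[GC]", both)
    }
  }
  used <- !is.na(gc_each)
  tibble(
    flank_bp = flank_bp,
    mean_gc = mean(gc_each[used]),
    prop_gc_adjacent = if (flank_bp == 1) mean(adj[used]) else NA_real_,
    n_used = sum(used),
    n_skipped = sum(!used)
  )
}

# Extract k-mers at the given offsets (relative to the SNP at 0) for each
# SNP; NA where the context runs off the chromosome.
extract_context <- function(snps, genome, offsets) {
  lens <- chrom_lengths(genome)
  out <- rep(NA_character_, nrow(snps))
  lo <- min(offsets)
  hi <- max(offsets)
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    pos <- snps$pos[idx]
    ok <- pos + lo >= 1 & pos + hi <= lens[[ch]]
    if (!any(ok)) next
    s <- genome$seq[[ch]]
    km <- rep("", sum(ok))
    for (o in offsets) {
      km <- paste0(km, substring(s, pos[ok] + o, pos[ok] + o))
    }
    out[idx[ok]] <- km
  }
  out
}

#' k-mer context frequencies around SNP sites
#'
#' Extracts the reference-strand di- or trinucleotide at the stated offsets
#' (the SNP site is position 0) for each SNP and tabulates fractions over
#' SNPs with a valid (on-chromosome) context.
#'
#' @param snps Tibble with chrom, pos.
#' @param genome An `ems_genome`.
#' @param position_set One of `"-1/0"`, `"0/+1"`, `"-2/-1/0"`, `"-1/0/+1"`,
#'   `"0/+1/+2"`.
#' @return Tibble: position_set, kmer, n, fraction (all possible k-mers,
#'   zero-filled). Attribute `n_skipped`.
#' @export
kmer_context_freqs <- function(snps, genome, position_set = "-1/0") {
  if (!position_set %in% names(POSITION_SETS)) {
    abort(paste0("unknown position set: ", position_set))
  }
  offsets <- POSITION_SETS[[position_set]]
  km <- extract_context(snps, genome, offsets)
  valid <- !is.na(km)
  k <- length(offsets)
  all_kmers <- apply(
    expand.grid(rep(list(DNA_BASES), k))[, k:1, drop = FALSE],
    1, paste, collapse = ""
  )
  tab <- table(factor(km[valid], levels = sort(all_kmers)))
  out <- tibble(
    position_set = position_set,
    kmer = names(tab),
    n = as.integer(tab),
    fraction = if (sum(valid) > 0) as.integer(tab) / sum(valid) else NA_real_
  )
  attr(out, "n_skipped") <- sum(!valid)
  out
}

#' Random-site baseline for context statistics
#'
#' Draws `reps` replicates of `n` uniform positions (without replacement
#' within a replicate, N bases excluded) and computes per-k-mer fractions
#' for every position set plus the mean 50-bp flank GC, reporting
#' mean +/- SD across replicates.
#'
#' @param genome An `ems_genome`.
#' @param n Sites per replicate.
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @param flank_bp Flank width for the GC summary.
#' @return List: `kmer` (tibble: position_set, kmer, mean_fraction,
#'   sd_fraction, reps), `flank_gc` (tibble: mean_gc, sd_gc, reps).
#' @export
random_site_baseline <- function(genome, n = 10000, reps = 10, seed = 1L,
                                 flank_bp = 50) {
  set.seed(derive_seed(seed, 9L))
  lens <- chrom_lengths(genome)
  total <- sum(lens)
  if (n > total) abort("`n` exceeds genome length")
  offs <- cumsum(c(0, head(lens, -1)))
  names(offs) <- names(lens)
  km_reps <- list()
  gc_reps <- numeric(reps)
  for (r in seq_len(reps)) {
    g <- sample.int(total, n)
    ch_idx <- findInterval(g, offs + 1)
    d <- tibble(
      chrom = names(lens)[ch_idx],
      pos = g - offs[ch_idx]
    )
    # drop N sites (none are generated by the simulator, but files may have them)
    b <- character(nrow(d))
    for (ch in unique(d$chrom)) {
      i <- d$chrom == ch
      b[i] <- genome_bases_chr(genome$seq[[ch]], d$pos[i])
    }
    d <- d[b %in% DNA_BASES, ]
    km_reps[[r]] <- purrr::map_dfr(
      names(POSITION_SETS),
      function(ps) dplyr::mutate(kmer_context_freqs(d, genome, ps), rep = r)
    )
    gc_reps[r] <- flank_gc(d, genome, flank_bp)$mean_gc
  }
  km <- dplyr::bind_rows(km_reps) %>%
    dplyr::group_by(.data$position_set, .data$kmer) %>%
    dplyr::summarise(
      mean_fraction = mean(.data$fraction),
      sd_fraction = stats::sd(.data$fraction),
      mean_n = mean(.data$n),
      reps = dplyr::n(),
      .groups = "drop"
    )
  list(
    kmer = km,
    flank_gc = tibble(mean_gc = mean(gc_reps), sd_gc = stats::sd(gc_reps),
                      reps = reps)
  )
}

#' Chi-square enrichment test for one k-mer (2x2, 1 df)
#'
#' Contingency table (k-mer vs not) x (observed set vs baseline), tested
#' without continuity correction by default. A zero margin yields
#' statistic 0, p = 1 and a degenerate flag.
#'
#' @param obs_count,obs_total Counts in the observed (SNP) set.
#' @param base_count,base_total Counts in the baseline set.
#' @param correct Apply Yates continuity correction.
#' @return Tibble: statistic, p_value, degenerate (vectorised over inputs).
#' @export
context_enrichment_test <- function(obs_count, obs_total, base_count,
                                    base_total, correct = FALSE) {
  if (any(obs_total <= 0) || any(base_total <= 0)) {
    abort("totals must be > 0")
  }
  a <- obs_count
  b <- obs_total - obs_count
  c_ <- base_count
  d <- base_total - base_count
  n <- a + b + c_ + d
  row1 <- a + b
  row2 <- c_ + d
  col1 <- a + c_
  col2 <- b + d
  degenerate <- row1 == 0 | row2 == 0 | col1 == 0 | col2 == 0
  num <- abs(a * d - b * c_)
  if (correct) num <- pmax(num - n / 2, 0)
  stat <- ifelse(degenerate, 0, n * num^2 / (row1 * row2 * col1 * col2))
  tibble(
    statistic = stat,
    p_value = ifelse(degenerate, 1, pchisq(stat, df = 1, lower.tail = FALSE)),
    degenerate = degenerate
  )
}

#' Context enrichment of SNP k-mers against a baseline
#'
#' Joins an observed k-mer table with a baseline table and tests each k-mer
#' (2x2 chi-square, 1 df, no continuity correction). Raw p-values are the
#' decision rule; Benjamini-Hochberg adjusted values are reported alongside.
#'
#' @param obs Tibble from [kmer_context_freqs()] for the SNP set.
#' @param baseline Tibble with columns kmer and n (e.g. a
#'   [kmer_context_freqs()] on genome-wide or random sites, or the `kmer`
#'   element of [random_site_baseline()] using `mean_n`).
#' @param correct Yates correction flag.
#' @return `obs` with baseline_n, baseline_fraction, statistic, p_value,
#'   p_adjust_bh, enriched columns.
#' @export
context_enrichment <- function(obs, baseline, correct = FALSE) {
  if (!"n" %in% names(baseline) && "mean_n" %in% names(baseline)) {
    baseline$n <- baseline$mean_n
  }
  base <- baseline %>%
    dplyr::select("kmer", baseline_n = "n")
  d <- dplyr::left_join(obs, base, by = "kmer") %>%
    dplyr::mutate(baseline_n = dplyr::coalesce(.data$baseline_n, 0))
  obs_total <- sum(d$n)
  base_total <- sum(d$baseline_n)
  tst <- context_enrichment_test(d$n, obs_total, d$baseline_n, base_total,
                                 correct = correct)
  d %>%
    dplyr::mutate(
      baseline_fraction = .data$baseline_n / base_total,
      statistic = tst$statistic,
      p_value = tst$p_value,
      p_adjust_bh = p.adjust(tst$p_value, method = "BH"),
      enriched = .data$fraction > .data$baseline_fraction
    )
}
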