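# DH merging, signal extraction, coverage filter, TE/expression overlays.

test_that("DH merging joins intervals within the gap and is idempotent", {
  # gap 30 <= 36: merge
  a <- tibble::tibble(chrom = "chr1", start = c(1, 81), end = c(50, 120))
  m <- merge_dh_sites(a, gap = 36)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 1)
  expect_equal(m$end, 120)
  # gap 100: unchanged
  b <- tibble::tibble(chrom = "chr1", start = c(1, 151), end = c(50, 160))
  expect_equal(nrow(merge_dh_sites(b, gap = 36)), 2)
  # transitive chain collapses to one interval
  ch <- tibble::tibble(chrom = "chr1", start = c(1, 81, 151), end = c(50, 120, 160))
  mc <- merge_dh_sites(ch, gap = 36)
  expect_equal(nrow(mc), 1)
  expect_equal(mc$end, 160)
  # idempotence
  expect_equal(merge_dh_sites(mc, gap = 36), mc)
  expect_error(merge_dh_sites(tibble::tibble(chrom = "chr1", start = -1, end = 5)),
               "start")
  # random instances match the fixpoint oracle
  set.seed(17)
  for (r in 1:3) {
    s <- sort(sample.int(2000, 30))
    iv <- tibble::tibble(chrom = sample(c("c1", "c2"), 30, replace = TRUE),
                         start = s, end = s + sample.int(60, 30))
    got <- merge_dh_sites(iv, gap = 36)
    want <- oracle_merge(iv, gap = 36)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("per-bin DH summary applies the strict > threshold", {
  bins <- make_bins(c(chr1 = 150000))
  bins$snp_count <- c(15, 0, 3)
  bins <- classify_bins(bins)
  scan <- structure(list(bins = bins), class = "ems_bin_scan")
  dh <- tibble::tibble(chrom = "chr1", start = seq(1000, 42000, by = 2000))
  dh$end <- dh$start + 50 # 21 sites, midpoints all in bin 1 only
  out <- dh_per_bin(dh, scan, threshold = 20)
  expect_equal(out$bins$dh_count[1], 21)
  hot <- out$class_summary[out$class_summary$class == "hotspot", ]
  expect_equal(hot$fraction_gt_threshold, 1)
  out2 <- dh_per_bin(dh[1:20, ], scan, threshold = 20)
  expect_equal(out2$class_summary$fraction_gt_threshold[
    out2$class_summary$class == "hotspot"], 0)
})

test_that("per-SNP signal takes the experiment maximum with 10-bp fallback", {
  snps <- tibble::tibble(chrom = "chr1", pos = c(100, 300, 500))
  tr <- tibble::tibble(
    modification = "m", experiment = c("e1", "e2", "e1"),
    chrom = "chr1", start = c(95, 90, 305), end = c(110, 105, 307),
    value = c(3, 5, 0.5)
  )
  out <- snp_signal(snps, tr, flank = 10)
  expect_equal(out$value[out$pos == 100], 5)
  expect_equal(out$source[out$pos == 100], "at_site")
  # pos 300 uncovered at site; value 0.5 at offset +5..+7
  expect_equal(out$value[out$pos == 300], 0.5)
  expect_equal(out$source[out$pos == 300], "flank10")
  expect_true(is.na(out$value[out$pos == 500]))
  expect_equal(out$source[out$pos == 500], "missing")
  expect_error(snp_signal(snps, tr[0, ]), "experiment")
})

test_that("signal extraction equals a 21-bp brute-force scan on random tracks", {
  set.seed(23)
  for (r in 1:3) {
    tr <- tibble::tibble(
      modification = "m",
      experiment = sample(c("e1", "e2", "e3"), 40, replace = TRUE),
      chrom = "chr1",
      start = sample.int(3000, 40)
    )
    tr$end <- tr$start + sample.int(80, 40)
    tr$value <- round(runif(40, 0, 10), 3)
    snps <- tibble::tibble(chrom = "chr1", pos = sample.int(3200, 50))
    got <- snp_signal(snps, tr, flank = 10)
    for (i in seq_len(nrow(snps))) {
      p <- snps$pos[i]
      at <- tr$value[tr$start <= p & tr$end >= p]
      win <- tr$value[tr$start <= p + 10 & tr$end >= p - 10]
      want <- if (length(at) > 0) max(at) else if (length(win) > 0) max(win)
        else NA_real_
      expect_equal(got$value[got$pos == p][1], want)
    }
    # never exceeds the global track maximum
    expect_lte(max(got$value, na.rm = TRUE), max(tr$value))
    # invariant to experiment ordering
    got2 <- snp_signal(snps, tr[sample.int(nrow(tr)), ], flank = 10)
    expect_equal(dplyr::arrange(got, pos)$value, dplyr::arrange(got2, pos)$value)
  }
})

test_that("coverage filter keeps modifications covering at least half", {
  sig <- tibble::tibble(
    modification = rep(c("a", "b", "c"), each = 10),
    chrom = "chr1", pos = rep(1:10, 3),
    value = 1,
    source = c(rep("at_site", 4), rep("missing", 6),   # 40% -> drop
               rep("at_site", 5), rep("missing", 5),   # 50% -> keep
               rep("at_site", 10))                     # 100% -> keep
  )
  cf <- coverage_filter(sig)
  expect_equal(cf$kept, c(FALSE, TRUE, TRUE))
})

test_that("class means average covered SNP maxima within classes", {
  bins <- make_bins(c(chr1 = 150000))
  bins$snp_count <- c(12, 1, 0)
  bins <- classify_bins(bins)
  scan <- structure(list(bins = bins), class = "ems_bin_scan")
  sig <- tibble::tibble(
    modification = "m", chrom = "chr1",
    pos = c(10, 20, 140000),
    value = c(1, 3, 7), source = "at_site"
  )
  out <- class_signal_summary(sig, scan)
  expect_equal(out$mean_signal[out$class == "hotspot"], 2)
  # pos 140000 lies in two bins (counts 1 and 0); the denser bin wins -> low
  expect_equal(out$mean_signal[out$class == "low"], 7)
  expect_true(is.na(out$mean_signal[out$class == "coldspot"]))
})

test_that("TE ratios and flags follow the midpoint counts", {
  bins <- make_bins(c(chr1 = 150000))
  bins$snp_count <- c(12, 0, 0)
  bins <- classify_bins(bins)
  scan <- structure(list(bins = bins), class = "ems_bin_scan")
  genes <- tibble::tibble(
    gene_id = sprintf("g%d", 1:9), chrom = "chr1",
    start = c(rep(1000, 3), rep(2000, 6)), end = c(rep(2000, 3), rep(3000, 6)),
    strand = "+",
    biotype = c(rep("TE", 3), rep("non-TE", 6))
  )
  out <- te_ratio_per_bin(genes, scan)
  expect_equal(out$bins$te_ratio[1], 0.5)
  expect_equal(out$bins$ratio_flag[2], "no_genes")
  all_te <- genes
  all_te$biotype <- "TE"
  out2 <- te_ratio_per_bin(all_te, scan)
  expect_equal(out2$bins$ratio_flag[1], "zero_denominator")
  # zero TE genes: ratio 0 wherever defined
  no_te <- genes
  no_te$biotype <- "non-TE"
  out3 <- te_ratio_per_bin(no_te, scan)
  expect_true(all(out3$bins$te_ratio[out3$bins$ratio_flag == "ok"] == 0))
})

test_that("expression summary splits low-expression fractions by targeting", {
  bins <- make_bins(c(chr1 = 150000))
  bins$snp_count <- c(12, 0, 0)
  bins <- classify_bins(bins)
  scan <- structure(list(bins = bins), class = "ems_bin_scan")
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1",
    start = c(1000, 5000, 9000), end = c(2000, 6000, 10000), strand = "+",
    biotype = "non-TE"
  )
  fpkm <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                         d1 = c(0.2, 0.5, 3.0), d2 = c(0.2, 0.5, 3.0))
  snps <- tibble::tibble(chrom = "chr1", pos = 1500) # targets g1 only
  out <- expression_summary(fpkm, genes, snps, scan)
  expect_equal(out$genes$mean_fpkm, c(0.2, 0.5, 3.0))
  expect_equal(out$genes$ems_targeted, c(TRUE, FALSE, FALSE))
  hot <- out$class_summary[out$class_summary$class == "hotspot", ]
  expect_equal(hot$fraction_low[hot$ems_targeted], 1)     # g1
  expect_equal(hot$fraction_low[!hot$ems_targeted], 0.5)  # g2 low, g3 not
  # overall low fraction among these genes: 2/3
  expect_equal(mean(out$genes$low_expression), 2 / 3)
  # genes absent from the matrix are excluded, not zero-filled
  out2 <- expression_summary(fpkm[1:2, ], genes, snps, scan)
  expect_equal(nrow(out2$genes), 2)
})
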