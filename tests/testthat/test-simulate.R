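# Synthetic-data generator: composition targets, determinism, implantation
# statistics, bulk read evidence, panel and track structure.

test_that("genome composition hits domain GC targets and is deterministic", {
  cfg <- sim_config(seed = 5, n_chrom = 1, chrom_len = 5e5, het_fraction = 0)
  g <- sim_genome(cfg)
  v <- strsplit(g$seq[[1]], "")[[1]]
  expect_equal(mean(v %in% c("G", "C")), cfg$gc_eu, tolerance = 0.01 / cfg$gc_eu)
  # byte-identical rerun
  g2 <- sim_genome(cfg)
  expect_identical(g$seq, g2$seq)

  cfg2 <- sim_config(seed = 5, n_chrom = 1, chrom_len = 6e5, het_fraction = 0.4)
  gh <- sim_genome(cfg2)
  gc_by_kind <- vapply(seq_len(nrow(gh$domains)), function(j) {
    d <- gh$domains[j, ]
    vv <- strsplit(substring(gh$seq[[d$chrom]], d$start, d$end), "")[[1]]
    mean(vv %in% c("G", "C"))
  }, numeric(1))
  het <- gh$domains$kind == "heterochromatin"
  expect_gte(mean(gc_by_kind[het]) - mean(gc_by_kind[!het]), 0.10)
  # domains tile the chromosome without overlap
  dom <- dplyr::arrange(gh$domains, start)
  expect_equal(dom$start[1], 1)
  expect_equal(dom$end[nrow(dom)], 6e5)
  expect_true(all(dom$start[-1] == dom$end[-nrow(dom)] + 1))
})

test_that("gene models are translatable and TE genes prefer heterochromatin", {
  s <- small_sim()
  genes <- s$sim$genes
  exons <- s$sim$exons
  genome <- s$sim$genome
  expect_gt(nrow(genes), 0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- exons[exons$gene_id == g$gene_id, ]
    expect_gte(nrow(ex), 1)
    cds <- emsbias:::cds_sequence(g, exons, genome)
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
  }
  # TE fraction higher inside heterochromatin than outside
  mid <- floor((genes$start + genes$end) / 2)
  in_het <- rep(FALSE, nrow(genes))
  dom <- genome$domains[genome$domains$kind == "heterochromatin", ]
  for (j in seq_len(nrow(dom))) {
    in_het <- in_het | (genes$chrom == dom$chrom[j] & mid >= dom$start[j] &
                          mid <= dom$end[j])
  }
  te <- genes$biotype == "TE"
  expect_gt(mean(te[in_het]), mean(te[!in_het]))
})

test_that("implantation follows the hazard model", {
  cfg <- sim_config(seed = 9, n_chrom = 1, chrom_len = 3e5, het_fraction = 0)
  g <- sim_genome(cfg)
  # identity model: total count within 3 SD of n_bulks * rate * L
  r <- 2e-5
  tr <- implant_ems_mutations(g, identity_rate_model(r), n_bulks = 10, seed = 2)
  expected <- 10 * r * 3e5
  expect_lt(abs(nrow(tr) - expected), 3 * sqrt(expected))
  # per-bin counts Poisson-dispersed under the identity model
  bins <- make_bins(chrom_lengths(g), window = 1e4, step = 1e4)
  cnt <- count_snps_per_bin(bins, tr)$snp_count
  disp <- sum((cnt - mean(cnt))^2) / mean(cnt) # ~ chisq(n-1)
  p <- pchisq(disp, df = length(cnt) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
  expect_gt(pchisq(disp, df = length(cnt) - 1), 0.01)

  # gc_multiplier = 4 biases sites toward G/C
  m <- context_rate_model(base_rate = r, gc_multiplier = 4,
                          kmer_multipliers = numeric(0),
                          heterochromatin_multiplier = 1)
  tr_gc <- implant_ems_mutations(g, m, n_bulks = 10, seed = 2)
  v <- strsplit(g$seq[[1]], "")[[1]]
  gc_genome <- mean(v %in% c("G", "C"))
  bt <- stats::binom.test(sum(tr_gc$ref %in% c("G", "C")), nrow(tr_gc),
                          gc_genome, alternative = "greater")
  expect_lt(bt$p.value, 0.01)

  # zero rate: empty truth set
  tr0 <- implant_ems_mutations(g, identity_rate_model(0), n_bulks = 3, seed = 1)
  expect_equal(nrow(tr0), 0)

  # unrealistically dense request is refused
  expect_error(
    implant_ems_mutations(g, identity_rate_model(0.05), n_bulks = 10, seed = 1),
    "dense|10%"
  )

  # sites unique to one bulk; exactly one causal site per bulk with freq 1
  expect_equal(anyDuplicated(paste(tr$chrom, tr$pos)), 0)
  per_bulk <- dplyr::count(dplyr::filter(tr, causal), bulk_id)
  expect_true(all(per_bulk$n == 1))
  expect_true(all(tr$freq[tr$causal] == 1))
  expect_true(all(tr$freq[!tr$causal] == 0.5))
})

test_that("bulk read evidence matches the pool model", {
  s <- small_sim()
  sim <- s$sim
  bv <- sim$bulk_variants
  truth <- sim$truth$ems
  # causal sites: all reads are alt (SNP index 1)
  causal <- dplyr::semi_join(
    bv, dplyr::filter(truth, causal), by = c("bulk_id", "chrom", "pos")
  )
  expect_gt(nrow(causal), 0)
  expect_true(all(causal$alt_reads == causal$total_reads))
  # heterozygous sites: mean SNP index near 0.5
  het <- dplyr::semi_join(
    bv, dplyr::filter(truth, !causal), by = c("bulk_id", "chrom", "pos")
  )
  expect_gt(nrow(het), 30)
  expect_gt(mean(het$alt_reads / het$total_reads), 0.45)
  expect_lt(mean(het$alt_reads / het$total_reads), 0.55)
  # conservation: every implanted site appears only in its own bulk's records
  ems_key <- paste(truth$chrom, truth$pos)
  hits <- bv[paste(bv$chrom, bv$pos) %in% ems_key & !(bv$bulk_id %in% NA), ]
  ori <- dplyr::filter(hits, alt_reads_mq20 >= 3)
  joined <- dplyr::inner_join(ori, truth, by = c("chrom", "pos"),
                              suffix = c("", ".t"))
  expect_true(all(joined$bulk_id == joined$bulk_id.t))
  # natural sites appear in every bulk
  nat <- sim$truth$natural
  if (nrow(nat) > 0) {
    nb <- dplyr::count(
      bv[paste(bv$chrom, bv$pos) %in% paste(nat$chrom, nat$pos), ],
      chrom, pos
    )
    expect_gt(mean(nb$n == s$config$n_bulks), 0.95)
  }
  # mapping-quality counts never exceed alt reads
  expect_true(all(bv$alt_reads_mq20 <= bv$alt_reads))
  expect_true(all(bv$alt_reads <= bv$total_reads))
})

test_that("error sites vanish when seq_error_rate covers no reads", {
  cfg <- sim_config(seed = 13, n_chrom = 1, chrom_len = 2e5, n_bulks = 3,
                    seq_error_rate = 0, error_site_rate = 1e-4,
                    natural_site_rate = 0, residual_fragment_prob = 0,
                    n_genes = 5, n_expr_datasets = 2,
                    ems_rate_model = context_rate_model(base_rate = 4e-6))
  sim <- simulate_ems_study(cfg)
  truth_key <- paste(sim$truth$ems$chrom, sim$truth$ems$pos)
  extra <- sim$bulk_variants[!(paste(sim$bulk_variants$chrom,
                                     sim$bulk_variants$pos) %in% truth_key), ]
  expect_equal(nrow(extra), 0)
})

test_that("natural panel obeys its distributions and truth overlap", {
  s <- small_sim()
  g <- s$sim$genome
  cfg <- s$config
  # point-mass distributions
  p <- sim_natural_panel(g, truth = NULL, cfg, maf_dist = 0.5, missing_dist = 0)
  st <- panel_site_stats(p)
  expect_true(all(st$missing_rate == 0))
  expect_true(all(abs(st$maf - 0.5) < 0.2)) # HWE draws around 0.5
  # all-missing sites fail the downstream filter
  p2 <- sim_natural_panel(g, truth = NULL, cfg, maf_dist = 0.3,
                          missing_dist = 0.9)
  kept <- filter_natural_panel(panel_site_stats(p2))
  expect_equal(nrow(kept), 0)
  # overlap fraction with the truth set
  tr <- s$sim$truth$ems
  st3 <- panel_site_stats(s$sim$panel)
  shared <- sum(paste(st3$chrom, st3$pos) %in% paste(tr$chrom, tr$pos))
  expect_equal(shared / nrow(tr), cfg$panel_overlap_fraction, tolerance = 0.35)
})

test_that("tracks carry the configured domain contrasts", {
  s <- small_sim()
  sim <- s$sim
  sig <- sim$tracks$signals
  dom <- sim$genome$domains
  mid_in_het <- function(chrom, start, end) {
    m <- floor((start + end) / 2)
    out <- rep(FALSE, length(m))
    hd <- dom[dom$kind == "heterochromatin", ]
    for (j in seq_len(nrow(hd))) {
      out <- out | (chrom == hd$chrom[j] & m >= hd$start[j] & m <= hd$end[j])
    }
    out
  }
  meth <- sig[sig$modification == "DNA_methylation", ]
  het <- mid_in_het(meth$chrom, meth$start, meth$end)
  expect_gte(mean(meth$value[het]), 2 * mean(meth$value[!het]))
  ac <- sig[sig$modification == "H3K9ac", ]
  het_ac <- mid_in_het(ac$chrom, ac$start, ac$end)
  expect_gte(mean(ac$value[!het_ac]), 2 * mean(ac$value[het_ac]))
  # DH denser in euchromatin
  dh <- sim$tracks$dh
  dhh <- mid_in_het(dh$chrom, dh$start, dh$end)
  eu_bp <- sum(dom$end[dom$kind != "heterochromatin"] -
                 dom$start[dom$kind != "heterochromatin"] + 1)
  het_bp <- sum(dom$end[dom$kind == "heterochromatin"] -
                  dom$start[dom$kind == "heterochromatin"] + 1)
  expect_gt(sum(!dhh) / eu_bp, sum(dhh) / het_bp)
  # FPKM matrix shape and low-expression bias in heterochromatin/TE genes
  expect_equal(ncol(sim$tracks$fpkm) - 1, s$config$n_expr_datasets)
  fp <- sim$tracks$fpkm
  mean_fpkm <- rowMeans(as.matrix(fp[, -1]))
  genes <- sim$genes
  low_genes <- genes$biotype == "TE" |
    mid_in_het(genes$chrom, genes$start, genes$end)
  expect_gt(mean(mean_fpkm[low_genes] < 1), mean(mean_fpkm[!low_genes] < 1))
})

test_that("single-column expression request yields one dataset", {
  cfg <- sim_config(seed = 2, n_chrom = 1, chrom_len = 1e5, n_bulks = 2,
                    n_genes = 8, n_expr_datasets = 1)
  g <- sim_genome(cfg)
  gm <- sim_genes(g, cfg)
  tk <- sim_tracks(gm$genome, gm$genes, cfg)
  expect_equal(ncol(tk$fpkm), 2) # gene_id + 1 dataset
})

test_that("uniform (euchromatin-only) DH placement is Poisson-dispersed", {
  cfg <- sim_config(seed = 21, n_chrom = 1, chrom_len = 1e6, het_fraction = 0,
                    n_genes = 0)
  g <- sim_genome(cfg)
  tk <- sim_tracks(g, genes = NULL, cfg)
  bins <- make_bins(chrom_lengths(g), window = 5e4, step = 5e4)
  mids <- tibble::tibble(
    chrom = tk$dh$chrom, pos = floor((tk$dh$start + tk$dh$end) / 2)
  )
  cnt <- bins
  cnt$snp_count <- emsbias:::count_positions_in_bins(bins, mids)
  x <- cnt$snp_count
  disp <- sum((x - mean(x))^2) / mean(x)
  expect_gt(pchisq(disp, df = length(x) - 1, lower.tail = FALSE), 0.01)
  expect_gt(pchisq(disp, df = length(x) - 1), 0.01)
})
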