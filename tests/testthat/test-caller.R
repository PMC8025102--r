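# Cross-bulk EMS SNP caller: SI, ED^6, filter chain, fragment masking,
# panel filter.

test_that("snp_index is the alt-read fraction with guarded depth", {
  expect_equal(snp_index(15, 30), 0.5)
  expect_equal(snp_index(40, 40), 1.0)
  expect_equal(snp_index(0, 25), 0.0)
  expect_error(snp_index(1, 0), "depth")
  expect_error(snp_index(5, 4), "alt_reads")
})

test_that("euclidean_distance6 matches direct arithmetic", {
  expect_equal(euclidean_distance6(c(0.25, 0.25, 0.25, 0.25),
                                   c(0.25, 0.25, 0.25, 0.25)), 0)
  expect_equal(euclidean_distance6(c(0, 0, 0, 1), c(0, 0, 0.5, 0.5)), 0.125)
  expect_equal(euclidean_distance6(c(0, 0, 0, 1), c(0, 0, 1, 0)), 8)
  expect_error(euclidean_distance6(c(0.5, 0.6, 0, 0), c(1, 0, 0, 0)), "sum")
  expect_error(euclidean_distance6(c(1, 0, 0), c(1, 0, 0, 0)), "length 4")
})

make_site <- function(...) {
  # rows: list of c(bulk, alt, total, mq20)
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      bulk_id = r[[1]], chrom = "chr1", pos = 100L, ref = "G", alt = "A",
      total_reads = as.integer(r[[3]]), alt_reads = as.integer(r[[2]]),
      alt_reads_mq20 = as.integer(r[[4]])
    )
  }))
}

test_that("candidate filter applies the uniqueness rules", {
  # accept: 3 MQ-passing reads in one bulk, other-bulk mean alt 0.4 (2/5)
  d <- make_site(list("b1", 4, 40, 3), list("b2", 2, 40, 2))
  res <- filter_candidates(d, n_bulks = 6)
  expect_true(res$accepted)
  expect_equal(res$test_bulk, "b1")
  # low support
  d2 <- make_site(list("b1", 2, 40, 2))
  res2 <- filter_candidates(d2, n_bulks = 6)
  expect_false(res2$accepted)
  expect_equal(res2$reason, "low_support")
  # shared: alt fraction 0.45 in a second bulk exceeds the 20% tolerance
  d3 <- make_site(list("b1", 20, 40, 18), list("b2", 18, 40, 1))
  res3 <- filter_candidates(d3, n_bulks = 60)
  expect_false(res3$accepted)
  expect_equal(res3$reason, "shared")
  # shared: two bulks pass the support threshold (tie is rejected)
  d4 <- make_site(list("b1", 20, 40, 18), list("b2", 19, 40, 17))
  res4 <- filter_candidates(d4, n_bulks = 6)
  expect_false(res4$accepted)
  expect_equal(res4$reason, "shared")
  # shared: mean alt reads over other bulks above 1
  d5 <- make_site(list("b1", 20, 40, 18), list("b2", 7, 40, 2))
  res5 <- filter_candidates(d5, n_bulks = 3)
  expect_false(res5$accepted)
  expect_equal(res5$reason, "shared")
})

test_that("residual-fragment masking finds dense windows and merges them", {
  p <- caller_params(fragment_mask_window = 1e5, fragment_mask_min_snps = 20)
  # 25 SNPs inside one 100-kb window: all masked
  cand <- tibble::tibble(
    bulk_id = "b1", chrom = "chr1",
    pos = seq(10000, by = 3000, length.out = 25)
  )
  m <- mask_residual_fragments(cand, p)
  expect_equal(nrow(m), 1)
  expect_true(all(cand$pos >= m$start & cand$pos <= m$end))
  # density below threshold: no masks
  sparse <- tibble::tibble(
    bulk_id = "b1", chrom = "chr1", pos = seq(1e4, 2e6, by = 1.2e5)
  )
  expect_equal(nrow(mask_residual_fragments(sparse, p)), 0)
  # consecutive qualifying windows over one long dense run merge into a
  # single interval wider than the window itself
  cand2 <- tibble::tibble(
    bulk_id = "b1", chrom = "chr1",
    pos = seq(1e4, by = 2000, length.out = 60)
  )
  m2 <- mask_residual_fragments(cand2, p)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$start, 1e4)
  expect_equal(m2$end, max(cand2$pos))
  expect_gt(m2$end - m2$start + 1, p$fragment_mask_window)
})

test_that("caller refuses a single bulk and drops fully shared tables", {
  one <- tibble::tibble(bulk_id = "b1", chrom = "chr1", pos = 5L, ref = "G",
                        alt = "A", total_reads = 30L, alt_reads = 15L,
                        alt_reads_mq20 = 14L)
  expect_error(call_ems_snps(one), ">= 2 bulks")
  # identical (natural) evidence in all bulks: nothing accepted
  shared <- dplyr::bind_rows(lapply(sprintf("b%d", 1:4), function(b) {
    tibble::tibble(bulk_id = b, chrom = "chr1", pos = c(10L, 20L), ref = "C",
                   alt = "T", total_reads = 40L, alt_reads = 38L,
                   alt_reads_mq20 = 36L)
  }))
  out <- call_ems_snps(shared)
  expect_equal(nrow(out), 0)
  expect_true(all(attr(out, "rejects")$reason == "shared"))
})

test_that("a clean unique heterozygous SNP is called with SI ~0.5 and ED^6 = 8 * SI^6", {
  d <- dplyr::bind_rows(
    tibble::tibble(bulk_id = "b1", chrom = "chr1", pos = 1000L, ref = "G",
                   alt = "A", total_reads = 40L, alt_reads = 19L,
                   alt_reads_mq20 = 18L),
    tibble::tibble(bulk_id = "b2", chrom = "chr1", pos = 2000L, ref = "C",
                   alt = "T", total_reads = 40L, alt_reads = 40L,
                   alt_reads_mq20 = 38L)
  )
  out <- call_ems_snps(d, n_bulks = 2)
  expect_equal(nrow(out), 2)
  s1 <- out[out$pos == 1000, ]
  expect_equal(s1$si, 19 / 40)
  expect_equal(s1$ed6, (sqrt(2) * 19 / 40)^6)
  expect_equal(s1$mutation_type, "G>A")
  s2 <- out[out$pos == 2000, ]
  expect_equal(s2$si, 1)
  expect_equal(s2$ed6, 8) # causal-site distance (0,...,1) vs ref-only
})

test_that("caller equals the brute-force oracle on random multi-bulk tables", {
  set.seed(301)
  for (rep in 1:3) {
    n_bulks <- 5
    n_sites <- 400
    pos <- sample.int(5e5, n_sites)
    rows <- list()
    for (i in seq_len(n_sites)) {
      kind <- sample(c("unique", "shared", "noise"), 1)
      bulks <- switch(kind,
        unique = sample(sprintf("b%d", 1:n_bulks), 1),
        shared = sprintf("b%d", 1:n_bulks),
        noise = sample(sprintf("b%d", 1:n_bulks), sample(1:3, 1))
      )
      for (b in bulks) {
        dp <- rpois(1, 35) + 1
        ar <- switch(kind,
          unique = rbinom(1, dp, 0.5),
          shared = rbinom(1, dp, 0.95),
          noise = rbinom(1, dp, runif(1, 0, 0.25))
        )
        rows[[length(rows) + 1]] <- tibble::tibble(
          bulk_id = b, chrom = "chr1", pos = pos[i], ref = "G", alt = "A",
          total_reads = dp, alt_reads = ar,
          alt_reads_mq20 = rbinom(1, ar, 0.95)
        )
      }
    }
    d <- dplyr::bind_rows(rows)
    d <- d[d$alt_reads > 0, ]
    p <- caller_params(fragment_mask_window = 5e4, fragment_mask_min_snps = 15)
    got <- call_ems_snps(d, p, n_bulks = n_bulks)
    want <- oracle_call(d, p, n_bulks = n_bulks)
    expect_equal(paste(got$bulk_id, got$chrom, got$pos),
                 paste(want$bulk_id, want$chrom, want$pos))
  }
})

test_that("accepted SNPs are unique to their bulk and support is monotone", {
  s <- small_sim()
  bv <- s$sim$bulk_variants
  out <- call_ems_snps(bv, n_bulks = s$config$n_bulks)
  # uniqueness: in every other bulk the alt fraction is within tolerance
  for (i in seq_len(min(nrow(out), 200))) {
    others <- bv[bv$chrom == out$chrom[i] & bv$pos == out$pos[i] &
                   bv$bulk_id != out$bulk_id[i], ]
    if (nrow(others) > 0) {
      expect_true(all(others$alt_reads / others$total_reads <= 0.20))
    }
  }
  # raising the support threshold only removes calls (on bulk data)
  out5 <- call_ems_snps(bv, caller_params(min_alt_mq20 = 5),
                        n_bulks = s$config$n_bulks)
  expect_true(all(paste(out5$chrom, out5$pos) %in% paste(out$chrom, out$pos)))
})

test_that("residual fragments are excluded from simulated calls", {
  cfg <- sim_config(seed = 31, n_chrom = 1, chrom_len = 1e6, n_bulks = 4,
                    residual_fragment_prob = 1, n_genes = 10,
                    n_expr_datasets = 2,
                    ems_rate_model = context_rate_model(base_rate = 3e-6))
  sim <- simulate_ems_study(cfg)
  expect_gt(nrow(sim$truth$fragments), 0)
  out <- call_ems_snps(sim$bulk_variants, n_bulks = 4)
  frag <- sim$truth$fragments
  for (j in seq_len(nrow(frag))) {
    inside <- out$bulk_id == frag$bulk_id[j] & out$chrom == frag$chrom[j] &
      out$pos >= frag$start[j] & out$pos <= frag$end[j]
    # dense residual heterozygosity must not be called as EMS
    expect_lte(sum(inside), 2)
  }
  perf <- caller_performance(out, sim$truth$ems)
  expect_gt(perf$precision, 0.9)
})

test_that("panel filter enforces support, MAF and missingness", {
  sites <- tibble::tibble(
    chrom = "chr1", pos = 1:5, ref = "A", alt = c("G", "T", "C", "G", "G,T"),
    n_typed = c(29, 100, 100, 100, 50),
    maf = c(0.3, 0.005, 0.3, 0.3, 0.2),
    missing_rate = c(0.1, 0.1, 0.85, 0.1, 0.1)
  )
  expect_warning(kept <- filter_natural_panel(sites), "multiallelic")
  expect_equal(kept$pos, 4L)
  expect_equal(attr(kept, "n_multiallelic_skipped"), 1L)
})
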