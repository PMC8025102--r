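# Shared fixtures: toy genomes built in code and memoised simulations.

toy_genome <- function(seqs, domains = NULL) {
  if (is.null(names(seqs))) names(seqs) <- paste0("chr", seq_along(seqs))
  if (is.null(domains)) {
    domains <- tibble::tibble(
      chrom = names(seqs), start = 1,
      end = vapply(seqs, nchar, numeric(1)), kind = "euchromatin"
    )
  }
  structure(
    list(seq = seqs, domains = domains, planted_islands = tibble::tibble()),
    class = "ems_genome"
  )
}

# random sequence helper
rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.fixtures <- new.env(parent = emptyenv())

# Small full simulation reused across module tests (fast, ~seconds).
small_sim <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- sim_config(
      seed = 42, n_chrom = 2, chrom_len = 4e5, n_bulks = 5, n_genes = 40,
      n_expr_datasets = 6,
      ems_rate_model = context_rate_model(base_rate = 4e-6)
    )
    .fixtures$small <- list(config = cfg, sim = simulate_ems_study(cfg))
  }
  .fixtures$small
}

# Study-scale simulation and pipeline used by the bias-recovery checks:
# 5-Mb genome, 10 bulks, default rate model, fixed seed.
study_result <- function() {
  if (is.null(.fixtures$study)) {
    cfg <- sim_config(seed = 1, n_chrom = 1, chrom_len = 5e6, n_bulks = 10)
    .fixtures$study <- list(config = cfg, res = run_ems_pipeline(cfg))
  }
  .fixtures$study
}

# Brute-force island caller: enumerate every window, mark passing bases,
# report connected components >= min_len.
oracle_cpg_islands <- function(seq, params = cpg_params()) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(v)
  w <- params$window
  covered <- logical(L)
  if (L >= w) {
    for (s in seq_len(L - w + 1)) {
      win <- substr(seq, s, s + w - 1)
      gc <- sum(strsplit(win, "")[[1]] %in% c("G", "C")) / w
      if (gc >= params$gc_min && obs_exp_cpg(win) >= params$oe_min) {
        covered[s:(s + w - 1)] <- TRUE
      }
    }
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= params$min_len
  tibble::tibble(start = starts[keep], end = ends[keep])
}

# Brute-force transitive interval merge by fixpoint pairwise merging.
oracle_merge <- function(df, gap) {
  rows <- lapply(seq_len(nrow(df)), function(i) df[i, ])
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_along(rows)) {
      for (j in seq_along(rows)) {
        if (i >= j || is.null(rows[[i]]) || is.null(rows[[j]])) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom != b$chrom) next
        gap_ab <- max(a$start, b$start) - min(a$end, b$end) - 1
        if (gap_ab <= gap) {
          rows[[i]]$start <- min(a$start, b$start)
          rows[[i]]$end <- max(a$end, b$end)
          rows[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
    rows <- Filter(Negate(is.null), rows)
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, chrom, start)
}

# Brute-force caller: re-derive the accepted set per the filter definition.
oracle_call <- function(bulk_variants, params = caller_params(),
                        n_bulks = length(unique(bulk_variants$bulk_id))) {
  d <- bulk_variants
  keys <- unique(paste(d$chrom, d$pos))
  acc <- list()
  for (k in keys) {
    rows <- d[paste(d$chrom, d$pos) == k, ]
    pass <- rows$alt_reads_mq20 >= params$min_alt_mq20
    if (sum(pass) != 1) next
    t <- which(pass)
    others <- rows[-t, ]
    if ((sum(others$alt_reads)) / (n_bulks - 1) > params$max_other_bulk_mean_alt) next
    if (nrow(others) > 0 &&
        any(others$alt_reads / others$total_reads > params$error_tolerance)) next
    acc[[k]] <- rows[t, c("bulk_id", "chrom", "pos")]
  }
  cand <- dplyr::bind_rows(acc)
  if (nrow(cand) == 0) return(cand)
  # residual-fragment mask: any window of width W with >= k candidates
  drop <- rep(FALSE, nrow(cand))
  for (b in unique(cand$bulk_id)) for (ch in unique(cand$chrom)) {
    i <- which(cand$bulk_id == b & cand$chrom == ch)
    p <- sort(cand$pos[i])
    kk <- params$fragment_mask_min_snps
    if (length(p) < kk) next
    for (s in seq_len(length(p) - kk + 1)) {
      if (p[s + kk - 1] - p[s] <= params$fragment_mask_window - 1) {
        drop[i][cand$pos[i] >= p[s] & cand$pos[i] <= p[s + kk - 1]] <- TRUE
      }
    }
  }
  dplyr::arrange(cand[!drop, ], chrom, pos)
}
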