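# Implanting EMS mutations and assembling per-bulk variant evidence.

# Per-base mutation hazard for one chromosome under a context rate model.
site_hazard_chr <- function(genome, chrom, model) {
  v <- strsplit(genome$seq[[chrom]], "", fixed = TRUE)[[1]]
  L <- length(v)
  lam <- rep(model$base_rate, L)
  is_gc <- v == "G" | v == "C"
  lam[is_gc] <- lam[is_gc] * model$gc_multiplier
  if (length(model$kmer_multipliers) > 0) {
    for (k in names(model$kmer_multipliers)) {
      kk <- strsplit(k, "", fixed = TRUE)[[1]]
      # trinucleotide frame -2/-1/0: mutated site is the last base
      idx <- which(v == kk[3])
      idx <- idx[idx >= 3]
      idx <- idx[v[idx - 1] == kk[2] & v[idx - 2] == kk[1]]
      lam[idx] <- lam[idx] * model$kmer_multipliers[[k]]
    }
  }
  if (model$heterochromatin_multiplier != 1) {
    hm <- het_mask(genome, chrom)
    lam[hm] <- lam[hm] * model$heterochromatin_multiplier
  }
  list(bases = v, hazard = lam)
}

draw_alt_allele <- function(ref, model) {
  n <- length(ref)
  alt <- character(n)
  u <- runif(n)
  for (i in seq_len(n)) {
    alt[i] <- switch(ref[i],
      G = if (u[i] < model$gc_transition_prob) "A" else sample(c("C", "T"), 1),
      C = if (u[i] < model$gc_transition_prob) "T" else sample(c("A", "G"), 1),
      A = if (u[i] < model$at_transition_prob) "G" else sample(c("C", "T"), 1),
      T = if (u[i] < model$at_transition_prob) "C" else sample(c("G", "A"), 1)
    )
  }
  alt
}

#' Implant EMS mutations per bulk under a context rate model
#'
#' Each bulk receives a Poisson number of mutations placed with per-site
#' hazard `base_rate` times the applicable context multipliers (see
#' [context_rate_model()]). One implanted site per bulk is designated the
#' causal mutation and is fixed in the pool (expected SNP index 1); all
#' other sites are heterozygous in every pooled individual (expected SNP
#' index 0.5). Sites are unique to their bulk; cross-bulk position
#' collisions are dropped from the later bulk.
#'
#' @param genome An `ems_genome`.
#' @param model A [context_rate_model()].
#' @param n_bulks Number of bulks.
#' @param seed Integer seed.
#' @return Tibble: bulk_id, chrom, pos, ref, alt, freq (expected pooled alt
#'   fraction), causal (logical).
#' @export
implant_ems_mutations <- function(genome, model, n_bulks, seed = 1L) {
  set.seed(derive_seed(seed, 3L))
  lens <- chrom_lengths(genome)
  haz <- lapply(names(lens), function(ch) site_hazard_chr(genome, ch, model))
  names(haz) <- names(lens)
  per_bulk_mean <- sum(vapply(haz, function(h) sum(h$hazard), numeric(1)))
  if (per_bulk_mean * n_bulks > 0.1 * sum(lens)) {
    abort("expected mutation count exceeds 10% of genome length; lower base_rate")
  }
  out <- list()
  for (b in seq_len(n_bulks)) {
    bulk <- sprintf("bulk%02d", b)
    rows <- list()
    for (ch in names(lens)) {
      h <- haz[[ch]]
      # independent per-site Bernoulli(hazard) draws (hazards << 1)
      pos <- which(runif(length(h$hazard)) < h$hazard)
      if (length(pos) == 0) next
      ref <- h$bases[pos]
      rows[[ch]] <- tibble(
        bulk_id = bulk, chrom = ch, pos = pos, ref = ref,
        alt = draw_alt_allele(ref, model)
      )
    }
    d <- dplyr::bind_rows(rows)
    if (nrow(d) == 0 && model$base_rate > 0) {
      # force a causal site so every bulk is mappable
      ch <- sample(names(lens), 1)
      h <- haz[[ch]]
      pos <- which.max(h$hazard * runif(length(h$hazard)))
      d <- tibble(
        bulk_id = bulk, chrom = ch, pos = pos, ref = h$bases[pos],
        alt = draw_alt_allele(h$bases[pos], model)
      )
    }
    if (nrow(d) == 0) next
    d$freq <- 0.5
    d$causal <- FALSE
    d$causal[sample.int(nrow(d), 1)] <- TRUE
    d$freq[d$causal] <- 1.0
    out[[b]] <- d
  }
  truth <- dplyr::bind_rows(out)
  if (nrow(truth) == 0) {
    return(tibble(bulk_id = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(), freq = numeric(),
                  causal = logical()))
  }
  # uniqueness across bulks: keep the first bulk at a colliding position
  truth <- dplyr::distinct(truth, .data$chrom, .data$pos, .keep_all = TRUE)
  dplyr::arrange(truth, .data$bulk_id, .data$chrom, .data$pos)
}

# Shared background (natural) homozygous sites, present in all bulks.
sim_natural_sites <- function(genome, config) {
  set.seed(derive_seed(config$seed, 4L))
  lens <- chrom_lengths(genome)
  purrr::map_dfr(names(lens), function(ch) {
    n <- rpois(1, lens[[ch]] * config$natural_site_rate)
    if (n == 0) return(tibble())
    pos <- sort(sample.int(lens[[ch]], n))
    ref <- genome_bases_chr(genome$seq[[ch]], pos)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1), character(1),
                  USE.NAMES = FALSE)
    tibble(chrom = ch, pos = pos, ref = ref, alt = alt, freq = 1.0)
  })
}

# Residual heterozygous fragments: dense unique het sites in single bulks.
sim_residual_fragments <- function(genome, config) {
  set.seed(derive_seed(config$seed, 5L))
  lens <- chrom_lengths(genome)
  frags <- list()
  sites <- list()
  for (b in seq_len(config$n_bulks)) {
    if (runif(1) >= config$residual_fragment_prob) next
    bulk <- sprintf("bulk%02d", b)
    ch <- sample(names(lens), 1)
    L <- lens[[ch]]
    flen <- min(config$residual_fragment_len, L)
    start <- sample.int(L - flen + 1, 1)
    end <- start + flen - 1
    n <- rpois(1, flen * config$residual_fragment_density)
    frags[[length(frags) + 1]] <- tibble(
      bulk_id = bulk, chrom = ch, start = start, end = end
    )
    if (n == 0) next
    pos <- sort(sample(start:end, min(n, flen)))
    ref <- genome_bases_chr(genome$seq[[ch]], pos)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1), character(1),
                  USE.NAMES = FALSE)
    sites[[length(sites) + 1]] <- tibble(
      bulk_id = bulk, chrom = ch, pos = pos, ref = ref, alt = alt, freq = 0.5
    )
  }
  list(fragments = dplyr::bind_rows(frags), sites = dplyr::bind_rows(sites))
}

#' Simulate per-bulk read evidence (variant tables) from implanted truth
#'
#' At every variant site the sequencing depth is Poisson(`depth`) and the
#' alt-read count binomial at the site's expected pooled alt fraction:
#' 0.5 at heterozygous EMS and residual-fragment sites, 1.0 at the causal
#' site and at shared natural (background) sites. Sequencing-error sites
#' are unique to a bulk with alt fraction drawn uniformly below
#' `seq_error_rate`. Records with zero alt reads are dropped (a variant
#' caller would not emit them). `alt_reads_mq20` thins alt reads at the
#' mapping-quality pass rate.
#'
#' @param genome An `ems_genome`.
#' @param truth Tibble from [implant_ems_mutations()].
#' @param natural Tibble of shared sites (chrom, pos, ref, alt, freq).
#' @param residual List from the residual-fragment generator (fragments,
#'   sites), or NULL.
#' @param config A [sim_config()].
#' @return Tibble: bulk_id, chrom, pos, ref, alt, total_reads, alt_reads,
#'   alt_reads_mq20, origin (ems/causal/natural/residual/error).
#' @export
sim_bulk_variants <- function(genome, truth, natural, residual, config) {
  set.seed(derive_seed(config$seed, 6L))
  lens <- chrom_lengths(genome)
  bulks <- sprintf("bulk%02d", seq_len(config$n_bulks))
  recs <- list()
  # EMS truth: only in own bulk
  t <- truth
  t$origin <- ifelse(t$causal, "causal", "ems")
  recs[["ems"]] <- t[, c("bulk_id", "chrom", "pos", "ref", "alt", "freq", "origin")]
  # natural: all bulks
  if (nrow(natural) > 0) {
    nat <- tidyr::crossing(bulk_id = bulks, natural)
    nat$origin <- "natural"
    recs[["nat"]] <- nat[, c("bulk_id", "chrom", "pos", "ref", "alt", "freq", "origin")]
  }
  if (!is.null(residual) && nrow(residual$sites) > 0) {
    rs <- residual$sites
    rs$origin <- "residual"
    recs[["res"]] <- rs[, c("bulk_id", "chrom", "pos", "ref", "alt", "freq", "origin")]
  }
  # sequencing-error sites, unique per bulk
  err <- list()
  for (b in bulks) {
    for (ch in names(lens)) {
      n <- rpois(1, lens[[ch]] * config$error_site_rate)
      if (n == 0) next
      pos <- sample.int(lens[[ch]], n)
      ref <- genome_bases_chr(genome$seq[[ch]], pos)
      alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1),
                    character(1), USE.NAMES = FALSE)
      err[[paste(b, ch)]] <- tibble(
        bulk_id = b, chrom = ch, pos = pos, ref = ref, alt = alt,
        freq = runif(n, 0, config$seq_error_rate), origin = "error"
      )
    }
  }
  recs[["err"]] <- dplyr::bind_rows(err)
  d <- dplyr::bind_rows(recs)
  # one record per bulk x site; truth/natural take precedence over noise
  pri <- c(causal = 1, ems = 2, natural = 3, residual = 4, error = 5)
  d <- d %>%
    dplyr::arrange(pri[.data$origin]) %>%
    dplyr::distinct(.data$bulk_id, .data$chrom, .data$pos, .keep_all = TRUE)
  n <- nrow(d)
  d$total_reads <- rpois(n, config$depth)
  d$total_reads[d$total_reads == 0] <- 1L
  d$alt_reads <- rbinom(n, d$total_reads, d$freq)
  d$alt_reads_mq20 <- rbinom(n, d$alt_reads, config$mq20_pass)
  d <- dplyr::filter(d, .data$alt_reads > 0)
  dplyr::arrange(
    d[, c("bulk_id", "chrom", "pos", "ref", "alt", "total_reads",
          "alt_reads", "alt_reads_mq20", "origin")],
    .data$bulk_id, .data$chrom, .data$pos
  )
}
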