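# Natural-variation panel and chromatin/expression track generation.

#' Generate a natural-SNP panel with per-variety genotypes
#'
#' Stands in for a large germplasm resequencing panel. Sites are biallelic;
#' per-site minor (alt) allele frequency and missing rate are drawn from
#' `maf_dist` / `missing_dist`, and genotypes per variety are
#' Hardy-Weinberg draws at that frequency. A configurable fraction of sites
#' is placed at implanted EMS positions (with matching alt allele) to drive
#' the sharing analysis.
#'
#' @param genome An `ems_genome`.
#' @param truth EMS truth tibble (or NULL) used for overlapping sites.
#' @param config A [sim_config()].
#' @param maf_dist Either a single numeric (point mass) or `function(n)`
#'   returning alt-allele frequencies in (0, 0.5].
#' @param missing_dist Point mass or `function(n)` for per-site missing rate.
#' @return Object of class `ems_panel`: list with `sites` (tibble: chrom,
#'   pos, ref, alt, from_truth) and `geno` (sites x varieties integer matrix
#'   of alt-allele counts, NA = missing).
#' @export
sim_natural_panel <- function(genome, truth = NULL, config,
                              maf_dist = function(n) 0.5 * rbeta(n, 0.6, 1.6),
                              missing_dist = function(n) rbeta(n, 1, 9)) {
  set.seed(derive_seed(config$seed, 7L))
  lens <- chrom_lengths(genome)
  draw <- function(dist, n) {
    if (is.function(dist)) dist(n) else rep(dist, n)
  }
  n_new <- rpois(1, sum(lens) * config$panel_site_rate)
  sites <- purrr::map_dfr(names(lens), function(ch) {
    k <- round(n_new * lens[[ch]] / sum(lens))
    if (k == 0) return(tibble())
    pos <- sort(sample.int(lens[[ch]], k))
    ref <- genome_bases_chr(genome$seq[[ch]], pos)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1),
                  character(1), USE.NAMES = FALSE)
    tibble(chrom = ch, pos = pos, ref = ref, alt = alt, from_truth = FALSE)
  })
  if (!is.null(truth) && nrow(truth) > 0 && config$panel_overlap_fraction > 0) {
    k <- round(nrow(truth) * config$panel_overlap_fraction)
    if (k > 0) {
      idx <- sample.int(nrow(truth), k)
      ov <- tibble(
        chrom = truth$chrom[idx], pos = truth$pos[idx],
        ref = truth$ref[idx], alt = truth$alt[idx], from_truth = TRUE
      )
      sites <- dplyr::bind_rows(sites, ov)
    }
  }
  sites <- sites %>%
    dplyr::distinct(.data$chrom, .data$pos, .keep_all = TRUE) %>%
    dplyr::arrange(.data$chrom, .data$pos)
  n <- nrow(sites)
  maf <- pmin(pmax(draw(maf_dist, n), 1e-4), 0.5)
  miss <- pmin(pmax(draw(missing_dist, n), 0), 1)
  nv <- config$n_varieties
  geno <- matrix(NA_integer_, nrow = n, ncol = nv,
                 dimnames = list(NULL, sprintf("var%03d", seq_len(nv))))
  for (i in seq_len(n)) {
    g <- rbinom(nv, 2, maf[i])
    g[runif(nv) < miss[i]] <- NA_integer_
    geno[i, ] <- g
  }
  structure(list(sites = sites, geno = geno), class = "ems_panel")
}

#' Summarise panel sites (typed count, MAF, missing rate)
#'
#' @param panel An `ems_panel`.
#' @return Tibble: chrom, pos, ref, alt, n_typed, maf, missing_rate.
#' @export
panel_site_stats <- function(panel) {
  stopifnot(inherits(panel, "ems_panel"))
  g <- panel$geno
  n_typed <- rowSums(!is.na(g))
  af <- rowSums(g, na.rm = TRUE) / (2 * pmax(n_typed, 1))
  maf <- pmin(af, 1 - af)
  maf[n_typed == 0] <- NA_real_
  dplyr::mutate(
    panel$sites,
    n_typed = n_typed,
    maf = maf,
    missing_rate = 1 - n_typed / ncol(g)
  )
}

#' Generate DH sites, epigenetic signal tracks, and an FPKM matrix
#'
#' DNase I hypersensitive (DH) sites are placed as a per-domain Poisson
#' process, denser in euchromatin. Signal tracks (one BedGraph-like tibble
#' per experiment) tile the genome in 200-bp intervals with partial
#' coverage; repressive marks (DNA methylation, MNase) have
#' `signal_contrast`-fold higher means in heterochromatin, active marks
#' (histone acetylation, H2A.Z) the reverse. Gene expression is log-normal
#' with heterochromatin and TE genes biased toward mean FPKM < 1.
#'
#' @param genome An `ems_genome`.
#' @param genes Gene tibble from [sim_genes()].
#' @param config A [sim_config()].
#' @return List with `dh` (tibble: chrom, start, end), `signals` (tibble:
#'   modification, experiment, chrom, start, end, value), `fpkm` (tibble:
#'   gene_id + one column per dataset).
#' @export
sim_tracks <- function(genome, genes, config) {
  set.seed(derive_seed(config$seed, 8L))
  lens <- chrom_lengths(genome)
  repressive <- c("DNA_methylation", "MNase")
  # DH sites
  dh <- purrr::map_dfr(seq_len(nrow(genome$domains)), function(j) {
    dom <- genome$domains[j, ]
    rate <- if (dom$kind == "heterochromatin") config$dh_rate_het else config$dh_rate_eu
    n <- rpois(1, (dom$end - dom$start + 1) * rate)
    if (n == 0) return(tibble())
    start <- sort(sample(dom$start:dom$end, n))
    width <- sample(50:300, n, replace = TRUE)
    tibble(chrom = dom$chrom, start = start,
           end = pmin(start + width - 1, dom$end))
  }) %>% dplyr::arrange(.data$chrom, .data$start)
  # signal tracks: 200-bp tiles, 80% coverage per experiment
  tile <- 200L
  tiles <- purrr::map_dfr(names(lens), function(ch) {
    s <- seq(1, lens[[ch]], by = tile)
    tibble(chrom = ch, start = s, end = pmin(s + tile - 1, lens[[ch]]))
  })
  tiles$het <- FALSE
  for (j in seq_len(nrow(genome$domains))) {
    dom <- genome$domains[j, ]
    if (dom$kind != "heterochromatin") next
    mid <- interval_midpoint(tiles$start, tiles$end)
    tiles$het <- tiles$het |
      (tiles$chrom == dom$chrom & mid >= dom$start & mid <= dom$end)
  }
  signals <- purrr::map_dfr(names(config$n_experiments), function(mod) {
    purrr::map_dfr(seq_len(config$n_experiments[[mod]]), function(e) {
      keep <- runif(nrow(tiles)) < 0.8
      d <- tiles[keep, c("chrom", "start", "end")]
      hi_in_het <- mod %in% repressive
      mu <- ifelse(tiles$het[keep] == hi_in_het, config$signal_contrast, 1)
      d$modification <- mod
      d$experiment <- paste0(mod, "_exp", e)
      d$value <- rgamma(nrow(d), shape = 4, rate = 4 / mu)
      d[, c("modification", "experiment", "chrom", "start", "end", "value")]
    })
  })
  # expression
  fpkm <- NULL
  if (!is.null(genes) && nrow(genes) > 0) {
    mid <- interval_midpoint(genes$start, genes$end)
    in_het <- rep(FALSE, nrow(genes))
    for (j in seq_len(nrow(genome$domains))) {
      dom <- genome$domains[j, ]
      if (dom$kind != "heterochromatin") next
      in_het <- in_het |
        (genes$chrom == dom$chrom & mid >= dom$start & mid <= dom$end)
    }
    low <- in_het | genes$biotype == "TE"
    meanlog <- ifelse(low, -1.5, 1.0)
    base <- exp(rnorm(nrow(genes), meanlog, 1))
    m <- vapply(seq_len(config$n_expr_datasets), function(d) {
      base * exp(rnorm(nrow(genes), 0, 0.3))
    }, numeric(nrow(genes)))
    m <- matrix(m, nrow = nrow(genes))
    colnames(m) <- sprintf("dataset%03d", seq_len(config$n_expr_datasets))
    fpkm <- dplyr::bind_cols(tibble(gene_id = genes$gene_id), as_tibble(m))
  }
  list(dh = dh, signals = signals, fpkm = fpkm)
}

#' Simulate a complete EMS mutagenesis study
#'
#' Runs the full generator: genome with chromatin domains, gene models,
#' implanted EMS mutations with ground truth, shared natural sites,
#' residual heterozygous fragments, per-bulk variant tables, a natural-SNP
#' panel, and chromatin/expression tracks. All randomness derives from
#' `config$seed`; identical configs give identical output.
#'
#' @param config A [sim_config()].
#' @return Object of class `ems_simulation`: list with `config`, `genome`,
#'   `genes`, `exons`, `truth` (list: ems, natural, fragments,
#'   fragment_sites), `bulk_variants`, `panel`, `tracks`.
#' @export
simulate_ems_study <- function(config = sim_config()) {
  genome <- sim_genome(config)
  gm <- sim_genes(genome, config)
  genome <- gm$genome
  truth <- implant_ems_mutations(genome, config$ems_rate_model,
                                 config$n_bulks, seed = config$seed)
  natural <- sim_natural_sites(genome, config)
  residual <- sim_residual_fragments(genome, config)
  bulk_variants <- sim_bulk_variants(genome, truth, natural, residual, config)
  panel <- sim_natural_panel(genome, truth, config)
  tracks <- sim_tracks(genome, gm$genes, config)
  structure(
    list(
      config = config, genome = genome, genes = gm$genes, exons = gm$exons,
      truth = list(ems = truth, natural = natural,
                   fragments = residual$fragments,
                   fragment_sites = residual$sites),
      bulk_variants = bulk_variants, panel = panel, tracks = tracks
    ),
    class = "ems_simulation"
  )
}
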