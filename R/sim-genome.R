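# Synthetic genome and gene-model generation.

default_domain_layout <- function(config) {
  purrr::map_dfr(seq_len(config$n_chrom), function(i) {
    L <- config$chrom_len[i]
    het_len <- round(L * config$het_fraction)
    arm <- floor((L - het_len) / 2)
    ch <- paste0("chr", i)
    if (het_len == 0) {
      return(tibble(chrom = ch, start = 1, end = L, kind = "euchromatin"))
    }
    tibble(
      chrom = ch,
      start = c(1, arm + 1, arm + het_len + 1),
      end = c(arm, arm + het_len, L),
      kind = c("euchromatin", "heterochromatin", "euchromatin")
    ) %>% dplyr::filter(.data$end >= .data$start)
  })
}

# Background base composition needed so that, after CpG depletion with
# probability d and mixing with planted islands covering an expected
# fraction f at island_gc, the realized domain GC hits its target.
background_gc <- function(gc_target, d, f, island_gc) {
  g_bg <- (gc_target - island_gc * f) / (1 - f)
  g_bg <- min(max(g_bg, 0.05), 0.95)
  if (d <= 0) return(g_bg)
  # depletion removes the G of a CpG (freq (g'/2)^2 per position) w.p. d:
  # solve g' - d * g'^2 / 4 = g_bg
  (1 - sqrt(1 - d * g_bg)) * 2 / d
}

#' Generate a synthetic genome with chromatin domains and CpG islands
#'
#' Each chromosome is tiled by non-overlapping euchromatin/heterochromatin
#' domains (by default a centromeric heterochromatin block flanked by two
#' euchromatic arms). Background bases are drawn i.i.d. per domain and
#' CpG-depleted (the G of a background CpG decays to A/T with probability
#' `cpg_depletion`, as in methylated plant genomes); discrete GC-rich CpG
#' islands are planted on top, denser in heterochromatin. Base frequencies
#' are compensated so the realized domain GC matches its target.
#'
#' @param config A [sim_config()].
#' @param layout Optional domain layout tibble (chrom, start, end, kind);
#'   defaults to the centromeric layout implied by `config$het_fraction`.
#' @return An object of class `ems_genome`: list with `seq` (named character
#'   vector of chromosome sequences), `domains` (tibble) and
#'   `planted_islands` (tibble: chrom, start, end).
#' @export
sim_genome <- function(config, layout = NULL) {
  set.seed(derive_seed(config$seed, 1L))
  layout <- layout %||% default_domain_layout(config)
  stopifnot(all(c("chrom", "start", "end", "kind") %in% names(layout)))
  if (any(layout$end < layout$start) || any(layout$start < 1)) {
    abort("invalid domain layout: need 1 <= start <= end")
  }
  chroms <- paste0("chr", seq_len(config$n_chrom))
  seqs <- setNames(vector("character", length(chroms)), chroms)
  planted <- list()
  d <- config$cpg_depletion
  igc <- config$cpg_island_gc
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    L <- config$chrom_len[i]
    dom <- dplyr::filter(layout, .data$chrom == ch) %>%
      dplyr::arrange(.data$start)
    if (nrow(dom) == 0 || dom$start[1] != 1 || dom$end[nrow(dom)] != L ||
        (nrow(dom) > 1 && any(dom$start[-1] != dom$end[-nrow(dom)] + 1))) {
      abort(paste0("domain layout must tile ", ch, " without gaps/overlap"))
    }
    v <- character(L)
    mean_ilen <- mean(config$cpg_island_len)
    for (j in seq_len(nrow(dom))) {
      het <- dom$kind[j] == "heterochromatin"
      gc <- if (het) config$gc_het else config$gc_eu
      irate <- if (het) config$cpg_island_rate_het else config$cpg_island_rate_eu
      g_bg <- background_gc(gc, d, min(irate * mean_ilen, 0.9), igc)
      p <- c((1 - g_bg) / 2, g_bg / 2, g_bg / 2, (1 - g_bg) / 2)
      idx <- dom$start[j]:dom$end[j]
      v[idx] <- sample(DNA_BASES, length(idx), replace = TRUE, prob = p)
    }
    # genome-wide CpG decay of the background
    if (d > 0) {
      cpg_c <- which(v[-L] == "C" & v[-1] == "G")
      hit <- cpg_c[runif(length(cpg_c)) < d]
      if (length(hit) > 0) {
        v[hit + 1] <- sample(c("A", "T"), length(hit), replace = TRUE)
      }
    }
    # plant discrete CpG islands (undepleted, GC-rich)
    p_isl <- c((1 - igc) / 2, igc / 2, igc / 2, (1 - igc) / 2)
    isl_rows <- list()
    for (j in seq_len(nrow(dom))) {
      het <- dom$kind[j] == "heterochromatin"
      irate <- if (het) config$cpg_island_rate_het else config$cpg_island_rate_eu
      dl <- dom$end[j] - dom$start[j] + 1
      n_isl <- rpois(1, dl * irate)
      if (n_isl == 0) next
      ilen <- sample(config$cpg_island_len[1]:config$cpg_island_len[2],
                     n_isl, replace = TRUE)
      istart <- dom$start[j] +
        floor(runif(n_isl) * pmax(dl - ilen, 1))
      iend <- pmin(istart + ilen - 1, dom$end[j])
      for (k in seq_len(n_isl)) {
        v[istart[k]:iend[k]] <- sample(DNA_BASES, iend[k] - istart[k] + 1,
                                       replace = TRUE, prob = p_isl)
      }
      isl_rows[[j]] <- tibble(chrom = ch, start = istart, end = iend)
    }
    planted[[ch]] <- dplyr::bind_rows(isl_rows)
    seqs[[ch]] <- paste(v, collapse = "")
  }
  structure(
    list(seq = seqs, domains = layout,
         planted_islands = dplyr::bind_rows(planted)),
    class = "ems_genome"
  )
}

# Logical mask of heterochromatin positions for one chromosome.
het_mask <- function(genome, chrom) {
  L <- nchar(genome$seq[[chrom]])
  m <- logical(L)
  dom <- dplyr::filter(
    genome$domains, .data$chrom == !!chrom, .data$kind == "heterochromatin"
  )
  for (j in seq_len(nrow(dom))) m[dom$start[j]:dom$end[j]] <- TRUE
  m
}

random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(
    matrix(sample(DNA_BASES, 3 * (n_codons - 2), replace = TRUE), ncol = 3),
    1, paste, collapse = ""
  )
  bad <- codons %in% stops
  while (any(bad)) {
    codons[bad] <- apply(
      matrix(sample(DNA_BASES, 3 * sum(bad), replace = TRUE), ncol = 3),
      1, paste, collapse = ""
    )
    bad <- codons %in% stops
  }
  paste0("ATG", paste(codons, collapse = ""), sample(stops, 1))
}

#' Place gene models (TE and non-TE) on a simulated genome
#'
#' Genes have 1-3 exons whose concatenation is a translatable CDS (ATG start,
#' single terminal stop, length a multiple of 3); the CDS sequence is written
#' into the genome so translation-based analyses are exact. TE genes are
#' preferentially placed in heterochromatin (weight `config$te_het_weight`).
#'
#' @param genome An `ems_genome`.
#' @param config A [sim_config()].
#' @param n_genes Number of genes (defaults to `config$n_genes`).
#' @return List with `genome` (sequences updated in place), `genes` (tibble:
#'   gene_id, chrom, start, end, strand, biotype) and `exons` (tibble:
#'   gene_id, exon_rank, start, end) where exons are CDS segments in genomic
#'   coordinates.
#' @export
sim_genes <- function(genome, config, n_genes = config$n_genes) {
  set.seed(derive_seed(config$seed, 2L))
  lens <- chrom_lengths(genome)
  te <- runif(n_genes) < config$te_fraction
  genes <- list()
  exons <- list()
  occupied <- lapply(lens, function(L) integer(0))
  # per-chromosome position weights by domain kind for TE placement
  for (g in seq_len(n_genes)) {
    n_ex <- sample(1:3, 1)
    cds_codons <- sample(50:300, 1)
    cds_len <- cds_codons * 3
    # split CDS length into n_ex chunks, each a positive multiple of 3
    cuts <- sort(sample(seq_len(cds_codons - 1), n_ex - 1))
    ex_lens <- diff(c(0, cuts, cds_codons)) * 3
    intron_lens <- if (n_ex > 1) sample(60:200, n_ex - 1, replace = TRUE) else integer(0)
    span <- sum(ex_lens) + sum(intron_lens)
    placed <- FALSE
    for (try in 1:50) {
      ch <- sample(names(lens), 1)
      L <- lens[[ch]]
      if (L < span + 2) next
      start <- sample.int(L - span, 1)
      if (te[g]) {
        # accept euchromatin placements with prob 1/weight
        in_het <- het_mask(genome, ch)[start]
        if (!in_het && runif(1) > 1 / config$te_het_weight) next
      }
      hit <- any(occupied[[ch]] >= start & occupied[[ch]] <= start + span - 1)
      if (hit) next
      occupied[[ch]] <- c(occupied[[ch]], start:(start + span - 1))
      strand <- sample(c("+", "-"), 1)
      cds <- random_cds(cds_codons)
      gseq <- if (strand == "+") cds else reverse_complement(cds)
      # exon genomic coordinates
      ex_start <- start + cumsum(c(0, head(ex_lens, -1) + intron_lens))
      ex_end <- ex_start + ex_lens - 1
      # write CDS bases into genome (genomic-strand sequence)
      off <- 1
      s <- genome$seq[[ch]]
      for (k in seq_len(n_ex)) {
        piece <- substr(gseq, off, off + ex_lens[k] - 1)
        substr(s, ex_start[k], ex_end[k]) <- piece
        off <- off + ex_lens[k]
      }
      genome$seq[[ch]] <- s
      gid <- sprintf("gene%04d", g)
      genes[[g]] <- tibble(
        gene_id = gid, chrom = ch, start = start, end = start + span - 1,
        strand = strand, biotype = if (te[g]) "TE" else "non-TE"
      )
      rank <- seq_len(n_ex)
      if (strand == "-") rank <- rev(rank)
      exons[[g]] <- tibble(
        gene_id = gid, exon_rank = rank, start = ex_start, end = ex_end
      )
      placed <- TRUE
      break
    }
    if (!placed) next
  }
  list(
    genome = genome,
    genes = dplyr::bind_rows(genes),
    exons = dplyr::arrange(dplyr::bind_rows(exons), .data$gene_id, .data$start)
  )
}
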