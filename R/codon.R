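# Codon and amino-acid usage of EMS mutations in coding sequence.

# Genetic-code lookup (standard code) via Biostrings.
codon_to_aa <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}

# CDS sequence (coding strand) of one gene from its exon table.
cds_sequence <- function(gene, exons, genome) {
  ex <- exons %>%
    dplyr::filter(.data$gene_id == gene$gene_id) %>%
    dplyr::arrange(.data$start)
  pieces <- substring(genome$seq[[gene$chrom]], ex$start, ex$end)
  s <- paste(pieces, collapse = "")
  if (gene$strand == "-") s <- reverse_complement(s)
  s
}

# Map a genomic position inside a gene's exons to its CDS coordinate
# (1-based, coding strand); NA if intronic.
cds_position <- function(gene, exons, pos) {
  ex <- exons %>%
    dplyr::filter(.data$gene_id == gene$gene_id) %>%
    dplyr::arrange(.data$start)
  cum <- cumsum(c(0, ex$end - ex$start + 1))
  total <- cum[length(cum)]
  for (k in seq_len(nrow(ex))) {
    if (pos >= ex$start[k] && pos <= ex$end[k]) {
      plus_coord <- cum[k] + (pos - ex$start[k] + 1)
      return(if (gene$strand == "+") plus_coord else total - plus_coord + 1)
    }
  }
  NA_integer_
}

#' Codon and amino-acid usage of EMS mutations in CDS
#'
#' For every SNP falling in coding sequence, identifies the affected codon
#' and position-in-codon on the coding strand, the before/after codon and
#' amino acid (standard genetic code), and whether the change is
#' synonymous. The genome-wide codon composition is tabulated from the
#' (longest-isoform) CDS models; CDS models whose length is not a multiple
#' of 3 are skipped with a warning.
#'
#' @param snps Tibble with chrom, pos, ref, alt.
#' @param genes,exons Gene-model tibbles (one longest isoform per gene).
#' @param genome An `ems_genome`.
#' @return List of class `ems_codon_usage`: `changes` (per-CDS-SNP tibble
#'   with codon/aa before and after and `synonymous`), `codon_genome`
#'   (tibble: codon, aa, n, fraction), `aa_targeted` (per-amino-acid
#'   fraction among non-synonymous changes, before and after), and
#'   `n_skipped_genes`.
#' @export
codon_usage <- function(snps, genes, exons, genome) {
  # genome codon composition
  skipped <- 0L
  codon_counts <- integer(0)
  cds_cache <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    s <- cds_sequence(g, exons, genome)
    if (nchar(s) %% 3 != 0) {
      skipped <- skipped + 1L
      next
    }
    cds_cache[[g$gene_id]] <- s
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    tab <- table(cod)
    codon_counts <- c(codon_counts, tab)
  }
  if (skipped > 0) {
    warn(paste0("skipped ", skipped, " gene(s) with CDS length not divisible by 3"))
  }
  cc <- tapply(codon_counts, names(codon_counts), sum)
  all_codons <- names(Biostrings::GENETIC_CODE)
  n_cod <- setNames(rep(0L, length(all_codons)), all_codons)
  n_cod[names(cc)] <- as.integer(cc)
  codon_genome <- tibble(
    codon = all_codons,
    aa = codon_to_aa(all_codons),
    n = as.integer(n_cod),
    fraction = as.integer(n_cod) / sum(n_cod)
  )
  # per-SNP codon changes
  rows <- list()
  for (j in seq_len(nrow(snps))) {
    sn <- snps[j, ]
    hit <- genes %>%
      dplyr::filter(.data$chrom == sn$chrom, .data$start <= sn$pos,
                    .data$end >= sn$pos)
    if (nrow(hit) == 0) next
    for (i in seq_len(nrow(hit))) {
      g <- hit[i, ]
      if (is.null(cds_cache[[g$gene_id]])) next
      cpos <- cds_position(g, exons, sn$pos)
      if (is.na(cpos)) next
      s <- cds_cache[[g$gene_id]]
      codon_idx <- ceiling(cpos / 3)
      in_codon <- cpos - (codon_idx - 1) * 3
      before <- substr(s, (codon_idx - 1) * 3 + 1, codon_idx * 3)
      ref_c <- if (g$strand == "+") sn$ref else COMPLEMENT[[sn$ref]]
      alt_c <- if (g$strand == "+") sn$alt else COMPLEMENT[[sn$alt]]
      if (substr(before, in_codon, in_codon) != ref_c) {
        abort(sprintf("CDS/ref inconsistency at %s:%d in %s",
                      sn$chrom, sn$pos, g$gene_id))
      }
      after <- before
      substr(after, in_codon, in_codon) <- alt_c
      aa_b <- codon_to_aa(before)
      aa_a <- codon_to_aa(after)
      rows[[length(rows) + 1]] <- tibble(
        chrom = sn$chrom, pos = sn$pos, gene_id = g$gene_id,
        codon_index = codon_idx, position_in_codon = in_codon,
        codon_before = before, codon_after = after,
        aa_before = aa_b, aa_after = aa_a,
        synonymous = aa_b == aa_a
      )
      break # one (deterministically first) gene per SNP
    }
  }
  changes <- dplyr::bind_rows(rows)
  ns <- if (nrow(changes) > 0) dplyr::filter(changes, !.data$synonymous) else changes
  aa_targeted <- if (nrow(ns) > 0) {
    tibble(aa = sort(unique(c(ns$aa_before, ns$aa_after)))) %>%
      dplyr::mutate(
        n_before = vapply(.data$aa, function(a) sum(ns$aa_before == a), numeric(1)),
        n_after = vapply(.data$aa, function(a) sum(ns$aa_after == a), numeric(1)),
        fraction_before = .data$n_before / nrow(ns),
        fraction_after = .data$n_after / nrow(ns)
      )
  } else {
    tibble(aa = character(), n_before = numeric(), n_after = numeric(),
           fraction_before = numeric(), fraction_after = numeric())
  }
  structure(
    list(changes = changes, codon_genome = codon_genome,
         aa_targeted = aa_targeted, n_skipped_genes = skipped),
    class = "ems_codon_usage"
  )
}
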