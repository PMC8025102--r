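# Genic-context classification of SNPs and natural-panel cross-reference.

#' Annotate SNPs by genic context
#'
#' Categories in precedence order: gene body (exon before intron; exonic
#' CDS SNPs are split into non-synonymous and synonymous by strand-aware
#' translation, exonic non-CDS SNPs are reported as `exon_noncoding`),
#' then `upstream3k` (within `flank` bp 5' of a gene, strand-aware), then
#' `downstream3k`, then `intergenic`. A SNP upstream of one gene and
#' downstream of another is upstream (upstream priority). Among genes
#' giving the same category, the lexicographically smallest gene id wins.
#'
#' @param snps Tibble with chrom, pos, ref, alt.
#' @param genes,exons Gene-model tibbles (longest isoform per gene).
#' @param genome An `ems_genome` (ref alleles are verified).
#' @param flank Upstream/downstream window (bp).
#' @return Tibble: snp columns + category, gene_id, aa_before, aa_after,
#'   aa_change.
#' @export
annotate_snps <- function(snps, genes, exons, genome, flank = 3000) {
  if (nrow(snps) > 0) check_ref_match(snps, genome)
  cu <- suppressWarnings(codon_usage(snps, genes, exons, genome))
  changes <- cu$changes
  category <- rep("intergenic", nrow(snps))
  gene_id <- rep(NA_character_, nrow(snps))
  aa_b <- rep(NA_character_, nrow(snps))
  aa_a <- rep(NA_character_, nrow(snps))
  genes_o <- dplyr::arrange(genes, .data$gene_id)
  for (j in seq_len(nrow(snps))) {
    ch <- snps$chrom[j]
    p <- snps$pos[j]
    cand <- genes_o[genes_o$chrom == ch, ]
    if (nrow(cand) == 0) next
    # gene body
    body <- cand[cand$start <= p & cand$end >= p, ]
    if (nrow(body) > 0) {
      assigned <- FALSE
      # exon beats intron; among exon genes, smallest id (cand is sorted)
      for (i in seq_len(nrow(body))) {
        ex <- exons[exons$gene_id == body$gene_id[i], ]
        if (any(ex$start <= p & ex$end >= p)) {
          gene_id[j] <- body$gene_id[i]
          hit <- changes[changes$chrom == ch & changes$pos == p, ]
          if (nrow(hit) > 0) {
            category[j] <- if (hit$synonymous[1]) "exon_synonymous" else
              "exon_nonsynonymous"
            aa_b[j] <- hit$aa_before[1]
            aa_a[j] <- hit$aa_after[1]
          } else {
            category[j] <- "exon_noncoding"
          }
          assigned <- TRUE
          break
        }
      }
      if (!assigned) {
        category[j] <- "intron"
        gene_id[j] <- body$gene_id[1]
      }
      next
    }
    # upstream (strand-aware), then downstream
    up <- cand[(cand$strand == "+" & p < cand$start & p >= cand$start - flank) |
                 (cand$strand == "-" & p > cand$end & p <= cand$end + flank), ]
    if (nrow(up) > 0) {
      category[j] <- "upstream3k"
      gene_id[j] <- up$gene_id[1]
      next
    }
    down <- cand[(cand$strand == "+" & p > cand$end & p <= cand$end + flank) |
                   (cand$strand == "-" & p < cand$start &
                      p >= cand$start - flank), ]
    if (nrow(down) > 0) {
      category[j] <- "downstream3k"
      gene_id[j] <- down$gene_id[1]
    }
  }
  dplyr::bind_cols(
    snps,
    tibble(
      category = factor(category, levels = c(
        "exon_nonsynonymous", "exon_synonymous", "exon_noncoding", "intron",
        "upstream3k", "downstream3k", "intergenic"
      )),
      gene_id = gene_id, aa_before = aa_b, aa_after = aa_a,
      aa_change = ifelse(!is.na(aa_b) & aa_b != aa_a,
                         paste0(aa_b, ">", aa_a), NA_character_)
    )
  )
}

#' Category summary of annotated SNPs
#'
#' Reports per-category fractions of all SNPs; exon subcategories are also
#' folded into an `exon` total and a `gene_body` total (exon + intron).
#' The upstream fraction is reported both as a fraction of all SNPs and of
#' non-genic (intergenic in the broad sense) SNPs.
#'
#' @param annotated Tibble from [annotate_snps()].
#' @return List: `by_category` tibble, `rollup` one-row tibble.
#' @export
annotation_summary <- function(annotated) {
  n <- nrow(annotated)
  by_cat <- annotated %>%
    dplyr::count(.data$category, .drop = FALSE, name = "n") %>%
    dplyr::mutate(fraction = .data$n / !!n)
  exon_cats <- c("exon_nonsynonymous", "exon_synonymous", "exon_noncoding")
  n_exon <- sum(annotated$category %in% exon_cats)
  n_intron <- sum(annotated$category == "intron")
  n_up <- sum(annotated$category == "upstream3k")
  n_nongenic <- n - n_exon - n_intron
  list(
    by_category = by_cat,
    rollup = tibble(
      n_snps = n,
      fraction_exon = n_exon / n,
      fraction_intron = n_intron / n,
      fraction_gene_body = (n_exon + n_intron) / n,
      fraction_upstream_of_total = n_up / n,
      fraction_upstream_of_nongenic = if (n_nongenic > 0) n_up / n_nongenic
        else NA_real_
    )
  )
}

#' Cross-reference EMS SNPs with a natural-variation panel
#'
#' A SNP is shared when the panel holds a site with the same chromosome,
#' position and alt allele. The summary reports the shared fraction and,
#' among shared SNPs, the fraction with panel MAF below `maf_cutoff`.
#'
#' @param snps EMS SNP tibble (chrom, pos, alt).
#' @param panel_sites Filtered panel tibble (from [filter_natural_panel()]).
#' @param maf_cutoff MAF threshold for the rare-allele summary.
#' @return List: `per_snp` (snps + panel_shared, panel_maf), `summary`
#'   (one-row tibble: n_snps, n_shared, fraction_shared,
#'   fraction_shared_maf_lt_cutoff).
#' @export
shared_with_panel <- function(snps, panel_sites, maf_cutoff = 0.10) {
  p <- dplyr::select(panel_sites, "chrom", "pos", "alt", panel_maf = "maf")
  d <- dplyr::left_join(as_tibble(snps), p, by = c("chrom", "pos", "alt")) %>%
    dplyr::mutate(panel_shared = !is.na(.data$panel_maf))
  n_shared <- sum(d$panel_shared)
  list(
    per_snp = d,
    summary = tibble(
      n_snps = nrow(d),
      n_shared = n_shared,
      fraction_shared = if (nrow(d) > 0) n_shared / nrow(d) else NA_real_,
      fraction_shared_maf_lt_cutoff = if (n_shared > 0) {
        mean(d$panel_maf[d$panel_shared] < maf_cutoff)
      } else NA_real_
    )
  )
}
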